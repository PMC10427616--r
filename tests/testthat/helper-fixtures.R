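# Shared fixtures, built once per test run (cached in this environment).

.fx <- new.env()

fxC3 <- function() {
  if (is.null(.fx$c3)) .fx$c3 <- makeToyComplex(3, 30, seed = 101)
  .fx$c3
}

fxC2 <- function() {
  if (is.null(.fx$c2)) .fx$c2 <- makeToyComplex(2, 26, seed = 102)
  .fx$c2
}

fxMsa <- function() {
  if (is.null(.fx$msa))
    .fx$msa <- makeSyntheticMsa(fxC3(), depth = 120, seed = 103)
  .fx$msa
}

# two-residue, two-chain structure with the nearest heavy atoms at a
# prescribed distance (for contact-cutoff boundary checks)
fxTwoResidue <- function(gap) {
  atoms <- data.frame(
    chain = c("A", "B"),
    resno = c(1L, 1L),
    resname = "ALA",
    atom = "CA",
    element = "C",
    x = c(0, gap), y = 0, z = 0,
    stringsAsFactors = FALSE)
  new("ComplexStructure", atoms = atoms, chains = c("A", "B"),
      symmetryOrder = 2L)
}

# minimal feature bundle around given tensors (manifest bookkeeping only)
fxBundle <- function(rec, cplx) {
  L <- dim(rec)[1L]
  new("FeatureBundle", receptor = rec, ligand = rec, complex = cplx,
      manifestReceptor = data.frame(block = "all", start = 1L,
                                    end = dim(rec)[3L]),
      manifestComplex = data.frame(block = "all", start = 1L,
                                   end = dim(cplx)[3L]),
      L = as.integer(L))
}

# a complete small training target built through the real feature pipeline
fxTarget <- function() {
  if (!is.null(.fx$target)) return(.fx$target)
  cx <- makeToyComplex(3, 32, seed = 104, regime = "tmp")
  truth <- interchainContactMap(cx)
  dm <- unclass(intrachainDistanceMap(cx))
  msa <- makeSyntheticMsa(cx, depth = 80, seed = 105)
  w <- sequenceWeights(msa)
  bundle <- assembleFeatures(computePssm(msa, weights = w),
                             meanFieldDca(msa, weights = w),
                             makeSurrogateLmFeatures(cx, truth, seed = 106),
                             encodeDistanceRBF(dm))
  .fx$target <- new("TrainingTarget", id = "fx", bundle = bundle, dmap = dm,
                    surface = computeSasa(cx, chains = "A")$surface,
                    truth = truth, L = 32L, cropOffset = c(0L, 0L))
  .fx$target
}
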