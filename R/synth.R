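## Synthetic Cn-symmetric benchmark generator.
##
## Toy complexes are ideal alpha-helical bundles: each chain is an ideal
## helix (rise 1.5 A per residue, 100 degrees per residue) parallel to the
## global z axis, and the n chains are exact Cn rotations of chain A about
## z.  The ring radius controls the inter-helix separation and thereby the
## interface size.  The "tmp" (membrane-like) regime packs tighter, uses a
## hydrophobic-biased sequence composition, and is paired with its own
## language-model surrogate signal channels; the "soluble" regime is
## looser, polar-biased, and carries a partially different channel set.

# per-atom cylinder parameters of an ideal alpha helix
.HELIX_ATOMS <- data.frame(
  atom = c("N", "CA", "C", "O", "CB"),
  element = c("N", "C", "C", "O", "C"),
  r = c(1.46, 2.27, 1.66, 1.95, 3.24),
  dtheta = c(-28, 0, 26, 22, -38) * pi / 180,
  dz = c(-0.95, 0, 1.05, 2.05, -0.55))

# regime-specific amino-acid sampling weights (hydrophobic bias for tmp)
.regimeAAWeights <- function(regime) {
  w <- stats::setNames(rep(1, 20), AA1)
  if (regime == "tmp") {
    w[c("A", "F", "I", "L", "M", "V", "W")] <- 4
    w[c("G", "S", "T")] <- 2
    w[c("D", "E", "K", "R", "N", "Q", "H")] <- 0.4
  } else {
    w[c("D", "E", "K", "R", "N", "Q", "S", "T")] <- 2.5
    w[c("A", "L", "V", "I", "G")] <- 1.5
  }
  w / sum(w)
}

#' Generate a toy Cn-symmetric helical-bundle complex
#'
#' @param nChains number of chains (>= 1); the declared symmetry order.
#' @param L residues per chain (>= 20).
#' @param seed RNG seed; generation is deterministic per seed.
#' @param regime "soluble" (looser packing, polar-biased sequence) or
#'   "tmp" (tighter packing, hydrophobic-biased sequence).
#' @param separation inter-helix axis separation in Angstrom; default
#'   10.0 for the soluble regime, 9.0 for tmp.
#' @return a \linkS4class{ComplexStructure} with `symmetryOrder = nChains`.
#' @export
makeToyComplex <- function(nChains, L, seed = 1L,
                           regime = c("soluble", "tmp"),
                           separation = NULL) {
  regime <- match.arg(regime)
  if (nChains < 1L) stop("nChains must be >= 1")
  if (L < 20L) stop("L must be >= 20")
  sep <- separation %||% if (regime == "tmp") 9.0 else 10.0
  aa <- withSeed(seed, sample(AA1, L, replace = TRUE,
                              prob = .regimeAAWeights(regime)))
  R <- if (nChains == 1L) 0 else sep / (2 * sin(pi / nChains))
  rows <- vector("list", nChains)
  for (c in seq_len(nChains)) {
    phi <- 2 * pi * (c - 1L) / max(nChains, 1L)
    loc <- .helixAtoms(aa)
    # place the helix on the ring, then rotate the whole chain about z
    xyz <- cbind(loc$x + R, loc$y, loc$z)
    rot <- cbind(c(cos(phi), sin(phi), 0), c(-sin(phi), cos(phi), 0),
                 c(0, 0, 1))
    xyz <- xyz %*% t(rot)
    rows[[c]] <- data.frame(chain = LETTERS[c], resno = loc$resno,
                            resname = loc$resname, atom = loc$atom,
                            element = loc$element,
                            x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                            stringsAsFactors = FALSE)
  }
  new("ComplexStructure", atoms = do.call(rbind, rows),
      chains = LETTERS[seq_len(nChains)],
      symmetryOrder = as.integer(nChains))
}

# local-frame atom table of one ideal helix over sequence aa
.helixAtoms <- function(aa) {
  L <- length(aa)
  out <- vector("list", L)
  for (i in seq_len(L)) {
    at <- .HELIX_ATOMS
    if (aa[i] == "G") at <- at[at$atom != "CB", , drop = FALSE]
    theta <- (i - 1L) * 100 * pi / 180 + at$dtheta
    out[[i]] <- data.frame(resno = i, resname = AA3[[aa[i]]], atom = at$atom,
                           element = at$element,
                           x = at$r * cos(theta), y = at$r * sin(theta),
                           z = (i - 1L) * 1.5 + at$dz,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic MSA with interface covariation
#'
#' Rows are sampled from the native (query) sequence by independent
#' per-column mutation, except that true inter-chain interface pairs
#' mutate jointly: with probability `couplingStrength` a coupled pair is
#' resampled into a compatible state pair (a fixed per-pair bijection of
#' the 20 amino acids), which creates the pairwise covariation signal that
#' coupling analysis is meant to detect.  Coupled pairs form a greedy
#' matching of the interface contact pairs (each residue in at most one
#' pair).  The query is row 1.
#'
#' @param x a \linkS4class{ComplexStructure} (the interface is taken from
#'   its inter-chain contact union map; a monomer yields no coupled pairs).
#' @param depth number of rows (>= 2).
#' @param mutationRate per-column mutation probability (default 0.3).
#' @param couplingStrength joint-mutation probability for interface pairs
#'   (default 0.7).
#' @param seed RNG seed.
#' @param cutoff contact cutoff used to define the interface (default 8).
#' @return an \linkS4class{MSAProfile}; attribute "coupledPairs" carries
#'   the 2-column matrix of coupled position pairs.
#' @export
makeSyntheticMsa <- function(x, depth = 150L, mutationRate = 0.3,
                             couplingStrength = 0.7, seed = 1L,
                             cutoff = 8.0) {
  if (depth < 2L) stop("depth must be >= 2")
  qseq <- strsplit(chainSequence(x), "")[[1L]]
  L <- length(qseq)
  qint <- match(qseq, AA1)
  pairs <- matrix(integer(0), 0L, 2L)
  if (nChains(x) >= 2L) {
    U <- interchainContactMap(x, cutoff = cutoff)@union
    cand <- which(upper.tri(U) & U, arr.ind = TRUE)
    used <- logical(L)
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!used[i] && !used[j] && i != j) {
        keep[k] <- TRUE; used[i] <- TRUE; used[j] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
  }
  msa <- withSeed(seed, {
    perms <- lapply(seq_len(nrow(pairs)), function(k) sample.int(20L))
    M <- matrix(rep(qint, each = depth), depth, L)
    if (depth > 1L) {
      body <- 2:depth
      mut <- matrix(stats::runif(length(body) * L) < mutationRate,
                    length(body), L)
      ran <- matrix(sample.int(20L, length(body) * L, replace = TRUE),
                    length(body), L)
      M[body, ][mut] <- ran[mut]
      if (nrow(pairs)) for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1L]; j <- pairs[k, 2L]
        co <- stats::runif(length(body)) < couplingStrength
        a <- sample.int(20L, sum(co), replace = TRUE)
        M[body, i][co] <- a
        M[body, j][co] <- perms[[k]][a]
      }
    }
    M
  })
  seqs <- matrix(AA1[msa], nrow(msa), ncol(msa))
  prof <- new("MSAProfile", seqs = seqs,
              ids = c("query", sprintf("syn%04d", seq_len(depth - 1L))))
  attr(prof, "coupledPairs") <- pairs
  prof
}

#' Generate surrogate language-model features carrying the interface signal
#'
#' The embedding is pure seeded noise (L x 768).  The pair attentions
#' (L x L x 144) are noise except for the channels in `signalChannels`,
#' which carry the 0/1 ground-truth contact map plus Gaussian noise of
#' standard deviation `noise`.  This emulates the property that a protein
#' language model's attention maps contain a learnable - but noisy and
#' channel-distributed - copy of the contact pattern.
#'
#' @param x a \linkS4class{ComplexStructure} (only L is used).
#' @param truth a \linkS4class{ContactMap} or logical L x L matrix.
#' @param noise Gaussian noise standard deviation (default 1.0).
#' @param seed RNG seed.
#' @param signalChannels integer channel indices carrying the signal
#'   (default 1:8).
#' @return an \linkS4class{LMFeatures}.
#' @export
makeSurrogateLmFeatures <- function(x, truth, noise = 1.0, seed = 1L,
                                    signalChannels = 1:8) {
  Y <- if (methods::is(truth, "ContactMap")) truth@union else truth
  L <- nrow(Y)
  if (chainLength(x) != L) stop("truth dimension does not match chain length")
  if (any(signalChannels < 1L | signalChannels > 144L))
    stop("signal channels must lie in 1..144")
  withSeed(seed, {
    emb <- matrix(stats::rnorm(L * 768L), L, 768L)
    att <- array(stats::rnorm(L * L * 144L), c(L, L, 144L))
    for (ch in signalChannels)
      att[, , ch] <- (Y + 0) + if (noise > 0)
        matrix(stats::rnorm(L * L, sd = noise), L, L) else 0
    new("LMFeatures", embedding = emb, attentions = att)
  })
}

.defaultBenchmarkConfig <- function() {
  list(nSolTrain = 60L, nSolValid = 12L,
       nTmpTrain = 12L, nTmpValid = 4L, nTmpTest = 8L,
       Lmin = 48L, Lmax = 64L,
       solChains = 2L, tmpChainChoices = c(3L, 4L),
       sepSoluble = 10.0, sepTmp = 9.0,
       msaDepth = 120L, mutationRate = 0.3, couplingStrength = 0.3,
       lmNoise = 4.0,
       sharedChannels = 1:4, solOnlyChannels = 5:8, tmpOnlyChannels = 9:12,
       dcaShrinkage = 0.5, contactCutoff = 8.0)
}

#' Build the synthetic transfer-learning benchmark
#'
#' Generates disjoint soluble-like (train/valid) and membrane-like
#' (train/valid/test) splits of toy Cn-symmetric complexes, each packaged
#' as a \linkS4class{TrainingTarget} with assembled features and
#' ground-truth contacts.  The two regimes differ in packing geometry,
#' sequence composition, symmetry orders and - crucially for the transfer
#' experiment - in which surrogate language-model channels carry the
#' contact signal: both regimes share `sharedChannels`, while
#' `solOnlyChannels` are informative only for soluble-like targets and
#' `tmpOnlyChannels` only for membrane-like targets.  Regeneration from
#' the same (config, seed) is byte-identical.
#'
#' @param config named list overriding \code{.defaultBenchmarkConfig()}:
#'   split sizes, length range `Lmin`/`Lmax`, chain counts, helix
#'   separations, MSA depth/mutation/coupling, surrogate noise and channel
#'   sets, DCA shrinkage.
#' @param seed master seed.
#' @param verbose print per-target progress.
#' @return a \linkS4class{SyntheticBenchmark}.
#' @export
buildTransferBenchmark <- function(config = list(), seed = 1L,
                                   verbose = FALSE) {
  cfg <- utils::modifyList(.defaultBenchmarkConfig(), config)
  for (nm in c("nSolTrain", "nSolValid", "nTmpTrain", "nTmpValid", "nTmpTest"))
    if (cfg[[nm]] < 1L) stop("split size must be >= 1: ", nm)
  counts <- c(sol_train = cfg$nSolTrain, sol_valid = cfg$nSolValid,
              tmp_train = cfg$nTmpTrain, tmp_valid = cfg$nTmpValid,
              tmp_test = cfg$nTmpTest)
  total <- sum(counts)
  seeds <- deriveSeeds(seed, total)
  splits <- rep(names(counts), counts)
  targets <- vector("list", total)
  for (t in seq_len(total)) {
    split <- splits[t]
    regime <- if (startsWith(split, "sol")) "soluble" else "tmp"
    targets[[t]] <- .makeBenchmarkTarget(
      id = sprintf("%s_%02d", split, sum(splits[seq_len(t)] == split)),
      regime = regime, cfg = cfg, seed = seeds[t])
    if (verbose) message("built ", targets[[t]]@id)
  }
  manifest <- list(seed = as.integer(seed), config = cfg,
                   targetSeeds = seeds, splits = splits)
  new("SyntheticBenchmark",
      solubleTrain = targets[splits == "sol_train"],
      solubleValid = targets[splits == "sol_valid"],
      tmpTrain = targets[splits == "tmp_train"],
      tmpValid = targets[splits == "tmp_valid"],
      tmpTest = targets[splits == "tmp_test"],
      manifest = manifest)
}

.makeBenchmarkTarget <- function(id, regime, cfg, seed) {
  s <- deriveSeeds(seed, 5L)
  geom <- withSeed(s[1L], {
    L <- sample(cfg$Lmin:cfg$Lmax, 1L)
    n <- if (regime == "tmp")
      cfg$tmpChainChoices[sample.int(length(cfg$tmpChainChoices), 1L)]
    else cfg$solChains
    list(L = L, n = n)
  })
  sep <- if (regime == "tmp") cfg$sepTmp else cfg$sepSoluble
  cx <- makeToyComplex(geom$n, geom$L, seed = s[2L], regime = regime,
                       separation = sep)
  truth <- interchainContactMap(cx, cutoff = cfg$contactCutoff)
  dmap <- intrachainDistanceMap(cx, chain = "A")
  enc <- encodeDistanceRBF(dmap)
  surf <- computeSasa(cx, chains = "A")$surface
  msa <- makeSyntheticMsa(cx, depth = cfg$msaDepth,
                          mutationRate = cfg$mutationRate,
                          couplingStrength = cfg$couplingStrength,
                          seed = s[3L], cutoff = cfg$contactCutoff)
  msa <- diversityFilter(msa, cap = 512L)
  w <- sequenceWeights(msa)
  pssm <- computePssm(msa, weights = w)
  dca <- meanFieldDca(msa, shrinkage = cfg$dcaShrinkage, weights = w)
  chans <- if (regime == "tmp") c(cfg$sharedChannels, cfg$tmpOnlyChannels)
  else c(cfg$sharedChannels, cfg$solOnlyChannels)
  lm <- makeSurrogateLmFeatures(cx, truth, noise = cfg$lmNoise, seed = s[4L],
                                signalChannels = chans)
  bundle <- assembleFeatures(pssm, dca, lm, enc)
  new("TrainingTarget", id = id, bundle = bundle, dmap = unclass(dmap),
      surface = surf, truth = truth, L = as.integer(geom$L),
      cropOffset = c(0L, 0L))
}
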