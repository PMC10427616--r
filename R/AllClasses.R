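#' @import methods
NULL

#' ComplexStructure: a parsed multi-chain structure
#'
#' Holds the heavy-atom coordinates of a (possibly Cn-symmetric) protein
#' complex as a flat atom table plus chain bookkeeping.  Internal residue
#' indexing is 0-based and contiguous per chain; the author residue numbers
#' from the source file are kept in the `resno` column.
#'
#' @slot atoms data.frame with columns `chain`, `resno` (author numbering),
#'   `resname` (3-letter), `atom` (atom name), `element`, `x`, `y`, `z` (in
#'   Angstrom).  Hydrogens are never stored.
#' @slot chains character vector of chain identifiers, in file order.
#' @slot symmetryOrder integer declared symmetry order of the assembly
#'   (`NA` when unannotated).
#'
#' @export
setClass("ComplexStructure",
  representation(atoms = "data.frame", chains = "character",
                 symmetryOrder = "integer"),
  prototype(symmetryOrder = NA_integer_))

setValidity("ComplexStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("structure has zero atoms")
  if (length(object@chains) == 0L) return("structure has zero chains")
  if (!all(a$chain %in% object@chains)) return("atom chain not in chain list")
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
    return("non-finite coordinates")
  for (ch in object@chains) {
    rn <- unique(a$resno[a$chain == ch])
    if (length(rn) == 0L) return(sprintf("chain %s has zero residues", ch))
    if (any(diff(rn) <= 0)) return(sprintf(
      "residue numbers not strictly increasing in chain %s", ch))
  }
  TRUE
})

#' ContactMap: inter-chain residue contact map
#'
#' The union map ORs the contact indicators over all ordered chain pairs
#' after identifying residue indices across chains (homo-oligomer
#' convention), then symmetrizes over (i,j)/(j,i).
#'
#' @slot union logical L x L matrix (union over chain pairs, symmetric).
#' @slot pairMaps named list of logical L x L matrices, one per unordered
#'   chain pair, names like "A|B".
#' @slot cutoff numeric heavy-atom distance cutoff in Angstrom.
#' @export
setClass("ContactMap",
  representation(union = "matrix", pairMaps = "list", cutoff = "numeric"))

setValidity("ContactMap", function(object) {
  if (object@cutoff <= 0) return("cutoff must be > 0")
  u <- object@union
  if (!is.logical(u)) return("union map must be logical")
  if (nrow(u) != ncol(u)) return("union map must be square")
  if (!isTRUE(all(u == t(u)))) return("union map must be symmetric")
  TRUE
})

#' MSAProfile: a parsed multiple sequence alignment
#'
#' Match-state alignment over the 20 standard amino acids plus gap.  The
#' first row is always the query and is ungapped.  Derived statistics
#' (frequencies, weights, M_eff, entropy) are computed by accessor
#' functions, not stored.
#'
#' @slot seqs character matrix (rows = sequences, columns = alignment
#'   positions), uppercase, gaps as "-".
#' @slot ids character vector of row identifiers.
#' @export
setClass("MSAProfile", representation(seqs = "matrix", ids = "character"))

setValidity("MSAProfile", function(object) {
  s <- object@seqs
  if (!is.character(s)) return("seqs must be a character matrix")
  if (nrow(s) < 1L || ncol(s) < 1L) return("empty alignment")
  if (length(object@ids) != nrow(s)) return("ids length != number of rows")
  if (any(s[1L, ] == "-")) return("query row must be ungapped")
  TRUE
})

#' DCAResult: direct-coupling-analysis score matrices
#'
#' @slot di numeric L x L raw (Frobenius-norm) coupling scores, symmetric,
#'   zero diagonal.
#' @slot apc numeric L x L scores after average product correction.
#' @export
setClass("DCAResult", representation(di = "matrix", apc = "matrix"))

setValidity("DCAResult", function(object) {
  for (nm in c("di", "apc")) {
    m <- slot(object, nm)
    if (nrow(m) != ncol(m)) return(paste(nm, "must be square"))
    if (max(abs(m - t(m))) > 1e-8) return(paste(nm, "must be symmetric"))
    if (max(abs(diag(m))) > 1e-12) return(paste(nm, "must have zero diagonal"))
  }
  TRUE
})

#' LMFeatures: protein-language-model feature tensors
#'
#' Container for externally produced (or surrogate) language-model features:
#' a per-residue embedding of width 768 and pairwise row-attention maps with
#' 144 channels.
#'
#' @slot embedding numeric L x 768 matrix.
#' @slot attentions numeric L x L x 144 array.
#' @export
setClass("LMFeatures",
  representation(embedding = "matrix", attentions = "array"))

setValidity("LMFeatures", function(object) {
  e <- object@embedding; a <- object@attentions
  if (ncol(e) != 768L) return("embedding must have exactly 768 channels")
  if (length(dim(a)) != 3L || dim(a)[3L] != 144L)
    return("attentions must have exactly 144 channels")
  if (dim(a)[1L] != nrow(e) || dim(a)[2L] != nrow(e))
    return("attention leading dimensions must equal embedding rows")
  if (any(!is.finite(e))) return("non-finite values in embedding")
  if (any(!is.finite(a))) return("non-finite values in attentions")
  TRUE
})

#' FeatureBundle: assembled network input tensors
#'
#' Receptor and ligand tensors include the radial-basis distance encoding of
#' the monomer; the complex tensor excludes it.  The channel manifests
#' record every feature block and its channel span so blocks can be located,
#' swapped or zeroed.
#'
#' @slot receptor numeric L x L x C_r array.
#' @slot ligand numeric L x L x C_r array (identical to receptor for
#'   homo-oligomers).
#' @slot complex numeric L x L x C_z array.
#' @slot manifestReceptor data.frame(block, start, end).
#' @slot manifestComplex data.frame(block, start, end).
#' @slot L integer monomer length.
#' @export
setClass("FeatureBundle",
  representation(receptor = "array", ligand = "array", complex = "array",
                 manifestReceptor = "data.frame",
                 manifestComplex = "data.frame", L = "integer"))

setValidity("FeatureBundle", function(object) {
  L <- object@L
  for (nm in c("receptor", "ligand", "complex")) {
    d <- dim(slot(object, nm))
    if (length(d) != 3L || d[1L] != L || d[2L] != L)
      return(paste(nm, "tensor must be L x L x C"))
  }
  okManifest <- function(man, C) {
    if (nrow(man) == 0L) return("empty manifest")
    spans <- unlist(mapply(seq, man$start, man$end, SIMPLIFY = FALSE))
    if (anyDuplicated(spans)) return("manifest spans overlap")
    if (!identical(sort(spans), seq_len(C))) return("manifest spans not exhaustive")
    TRUE
  }
  v <- okManifest(object@manifestReceptor, dim(object@receptor)[3L])
  if (!isTRUE(v)) return(paste("receptor manifest:", v))
  v <- okManifest(object@manifestComplex, dim(object@complex)[3L])
  if (!isTRUE(v)) return(paste("complex manifest:", v))
  TRUE
})

#' ContactPrediction: an L x L contact probability map
#'
#' @slot probs numeric L x L matrix of probabilities in [0,1].
#' @slot symmetrized logical; TRUE once (P + t(P))/2 averaging was applied.
#' @slot cropOffset integer length-2 offset (0-based) of the crop window the
#'   prediction refers to; c(0L, 0L) for an uncropped target.
#' @export
setClass("ContactPrediction",
  representation(probs = "matrix", symmetrized = "logical",
                 cropOffset = "integer"),
  prototype(symmetrized = FALSE, cropOffset = c(0L, 0L)))

setValidity("ContactPrediction", function(object) {
  p <- object@probs
  if (nrow(p) != ncol(p)) return("probability map must be square")
  if (any(p < 0 | p > 1)) return("probabilities outside [0,1]")
  if (isTRUE(object@symmetrized) && max(abs(p - t(p))) > 1e-12)
    return("symmetrized flag set but map is not symmetric")
  TRUE
})

#' ContactModel: the triangle-aware contact prediction network
#'
#' Parameters are stored as a nested list of numeric arrays; `config`
#' carries the architecture hyperparameters (channel width d, block counts,
#' head count, distance-gate length scale lambda, focal-loss settings,
#' dropout, mask mode).
#'
#' @slot params list of parameter arrays (nested by block).
#' @slot config list of architecture hyperparameters.
#' @export
setClass("ContactModel", representation(params = "list", config = "list"))

#' TrainingTarget: one complex packaged for training/evaluation
#'
#' @slot id character target identifier.
#' @slot bundle FeatureBundle input tensors.
#' @slot dmap numeric L x L intra-chain (monomer) distance map.
#' @slot surface logical length-L surface flags of the monomer.
#' @slot truth ContactMap ground-truth inter-chain contacts.
#' @slot L integer monomer length (post-crop).
#' @slot cropOffset integer length-2, 0-based window offset applied.
#' @export
setClass("TrainingTarget",
  representation(id = "character", bundle = "FeatureBundle", dmap = "matrix",
                 surface = "logical", truth = "ContactMap", L = "integer",
                 cropOffset = "integer"),
  prototype(cropOffset = c(0L, 0L)))

setValidity("TrainingTarget", function(object) {
  L <- object@L
  if (object@bundle@L != L) return("bundle L mismatch")
  if (!all(dim(object@dmap) == c(L, L))) return("dmap dimension mismatch")
  if (length(object@surface) != L) return("surface length mismatch")
  if (!all(dim(object@truth@union) == c(L, L))) return("truth dimension mismatch")
  TRUE
})

#' CurationRule: dataset curation thresholds
#'
#' Mirrors the construction filters of the homo-oligomer benchmark sets: a
#' complex is kept only if its largest pairwise interface is at least
#' `minInterfaceArea`, that interface has at least `minInterfaceContacts`
#' contacts, the monomer is no longer than `maxMonomerLength`, all chain
#' pairs share at least `minChainIdentity` sequence identity, and (when
#' `requireSymmetryMatch`) the chain count equals the declared symmetry
#' order.
#'
#' @slot minInterfaceArea numeric, Angstrom^2 (default 500).
#' @slot minInterfaceContacts integer (default 10).
#' @slot maxMonomerLength integer (default 1024).
#' @slot minChainIdentity numeric fraction (default 0.99).
#' @slot requireSymmetryMatch logical (default TRUE).
#' @slot clusterIdentity numeric fraction used for redundancy clustering
#'   (default 0.30).
#' @export
setClass("CurationRule",
  representation(minInterfaceArea = "numeric", minInterfaceContacts = "integer",
                 maxMonomerLength = "integer", minChainIdentity = "numeric",
                 requireSymmetryMatch = "logical", clusterIdentity = "numeric"),
  prototype(minInterfaceArea = 500, minInterfaceContacts = 10L,
            maxMonomerLength = 1024L, minChainIdentity = 0.99,
            requireSymmetryMatch = TRUE, clusterIdentity = 0.30))

setValidity("CurationRule", function(object) {
  if (object@minInterfaceArea <= 0) return("minInterfaceArea must be > 0")
  if (object@minInterfaceContacts <= 0L) return("minInterfaceContacts must be > 0")
  if (object@maxMonomerLength <= 0L) return("maxMonomerLength must be > 0")
  if (object@minChainIdentity <= 0 || object@minChainIdentity > 1)
    return("minChainIdentity must be in (0,1]")
  if (object@clusterIdentity <= 0 || object@clusterIdentity > 1)
    return("clusterIdentity must be in (0,1]")
  TRUE
})

#' SyntheticBenchmark: the generated transfer-learning benchmark
#'
#' @slot solubleTrain,solubleValid lists of TrainingTarget (soluble-like regime).
#' @slot tmpTrain,tmpValid,tmpTest lists of TrainingTarget (membrane-like regime).
#' @slot manifest list recording the generation seed and all generator
#'   parameters; the benchmark regenerates byte-identically from it.
#' @export
setClass("SyntheticBenchmark",
  representation(solubleTrain = "list", solubleValid = "list",
                 tmpTrain = "list", tmpValid = "list", tmpTest = "list",
                 manifest = "list"))

## ---- show methods ----

setMethod("show", "ComplexStructure", function(object) {
  cat(sprintf("ComplexStructure: %d chain(s) [%s], %d atoms",
              length(object@chains), paste(object@chains, collapse = ","),
              nrow(object@atoms)))
  if (!is.na(object@symmetryOrder))
    cat(sprintf(", declared C%d symmetry", object@symmetryOrder))
  cat("\n")
  for (ch in object@chains)
    cat(sprintf("  chain %s: %d residues\n", ch,
                length(unique(object@atoms$resno[object@atoms$chain == ch]))))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap: L = %d, cutoff = %.2f A, %d contact pairs (union, i<=j)\n",
              nrow(object@union), object@cutoff,
              sum(object@union[upper.tri(object@union, diag = TRUE)])))
})

setMethod("show", "MSAProfile", function(object) {
  cat(sprintf("MSAProfile: %d sequences x %d columns (query: %s)\n",
              nrow(object@seqs), ncol(object@seqs), object@ids[1L]))
})

setMethod("show", "FeatureBundle", function(object) {
  cat(sprintf("FeatureBundle: L = %d; receptor %d ch, complex %d ch\n",
              object@L, dim(object@receptor)[3L], dim(object@complex)[3L]))
  man <- object@manifestReceptor
  cat(sprintf("  receptor blocks: %s\n",
              paste(sprintf("%s[%d-%d]", man$block, man$start, man$end),
                    collapse = " ")))
})

setMethod("show", "ContactPrediction", function(object) {
  cat(sprintf("ContactPrediction: %d x %d, max p = %.3f%s\n",
              nrow(object@probs), ncol(object@probs), max(object@probs),
              if (isTRUE(object@symmetrized)) ", symmetrized" else ""))
})

setMethod("show", "ContactModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(rapply(object@params, length, how = "unlist"),
                   identity, numeric(1)))
  cat(sprintf(paste0("ContactModel: d = %d, %d ResNet-Inception + %d ",
                     "triangle block(s), %d head(s), %d parameters\n"),
              cfg$d, cfg$nInception, cfg$nTriangle, cfg$nHeads, as.integer(np)))
})

setMethod("show", "SyntheticBenchmark", function(object) {
  cat(sprintf(paste0("SyntheticBenchmark: soluble-like %d train / %d valid; ",
                     "membrane-like %d train / %d valid / %d test (seed %d)\n"),
              length(object@solubleTrain), length(object@solubleValid),
              length(object@tmpTrain), length(object@tmpValid),
              length(object@tmpTest), object@manifest$seed))
})
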