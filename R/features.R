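#' Ingest externally computed language-model features
#'
#' Validates shape and finiteness of a per-residue embedding (L x 768) and
#' pairwise attention maps (L x L x 144) and packages them unchanged.
#' Inputs may be in-memory arrays or paths to RDS files holding them.
#'
#' @param embedding numeric L x 768 matrix, or path to an RDS file.
#' @param attentions numeric L x L x 144 array, or path to an RDS file.
#' @param L expected monomer length.
#' @return an \linkS4class{LMFeatures}.
#' @export
ingestLmFeatures <- function(embedding, attentions, L) {
  if (is.character(embedding)) embedding <- readRDS(embedding)
  if (is.character(attentions)) attentions <- readRDS(attentions)
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != L)
    stop(sprintf("embedding has %d rows; expected L = %d", nrow(embedding), L))
  if (ncol(embedding) != 768L)
    stop(sprintf("embedding has %d channels; expected 768", ncol(embedding)))
  d <- dim(attentions)
  if (length(d) != 3L || d[1L] != L || d[2L] != L)
    stop(sprintf("attentions have leading dims %s; expected %d x %d",
                 paste(d[1:2], collapse = " x "), L, L))
  if (d[3L] != 144L)
    stop(sprintf("attentions have %d channels; expected 144", d[3L]))
  if (any(!is.finite(embedding))) {
    bad <- which(!is.finite(embedding), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value in embedding at (%d, %d)", bad[1L], bad[2L]))
  }
  if (any(!is.finite(attentions))) {
    bad <- which(!is.finite(attentions), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value in attentions at (%d, %d, %d)",
                 bad[1L], bad[2L], bad[3L]))
  }
  new("LMFeatures", embedding = embedding, attentions = attentions)
}

# Fixed random projection of the 768-dim embedding to a compact width used
# for pair tiling.  Seeded with a package-level constant so every target
# and every session shares the same projection.
.LM_PROJ_SEED <- 104729L
.LM_PROJ_DIM <- 16L

.lmProjection <- function(width = .LM_PROJ_DIM) {
  withSeed(.LM_PROJ_SEED,
           matrix(stats::rnorm(768L * width, sd = 1 / sqrt(768)), 768L, width))
}

#' Assemble receptor/ligand/complex input tensors
#'
#' Builds the pair feature tensors fed to the network.  Channel layout
#' (recorded in the manifests): tiled PSSM of residue i (20) and residue j
#' (20), raw DCA (1), APC-corrected DCA (1), language-model pair attentions
#' (144), projected language-model embedding tiled for i (16) and j (16),
#' and -- for the receptor/ligand tensors only -- the radial-basis distance
#' encoding (64).  The complex tensor excludes the distance block, so its
#' channel count is exactly 64 below the receptor's.
#'
#' @param pssm numeric L x 20 profile.
#' @param dca a \linkS4class{DCAResult}.
#' @param lm an \linkS4class{LMFeatures}.
#' @param enc L x L x 64 distance encoding (from
#'   \code{\link{encodeDistanceRBF}}).
#' @return a \linkS4class{FeatureBundle}; for homo-oligomers the ligand
#'   tensor is the receptor tensor.
#' @export
assembleFeatures <- function(pssm, dca, lm, enc) {
  L <- nrow(pssm)
  stopifnot(ncol(pssm) == 20L)
  if (nrow(dca@di) != L) stop("DCA dimension mismatch with PSSM (L)")
  if (nrow(lm@embedding) != L) stop("LM feature dimension mismatch (L)")
  if (!(length(dim(enc)) == 3L && all(dim(enc)[1:2] == L)))
    stop("distance encoding dimension mismatch (L)")
  proj <- lm@embedding %*% .lmProjection()          # L x 16
  pe <- ncol(proj)
  blocks <- list(
    pssm_i  = .tileRows(pssm, L),
    pssm_j  = .tileCols(pssm, L),
    dca_di  = array(dca@di, dim = c(L, L, 1L)),
    dca_apc = array(dca@apc, dim = c(L, L, 1L)),
    lm_attn = lm@attentions,
    lm_emb_i = .tileRows(proj, L),
    lm_emb_j = .tileCols(proj, L))
  cplx <- .bindChannels(blocks)
  blocks$dist_rbf <- enc[, , , drop = FALSE]
  rec <- .bindChannels(blocks)
  new("FeatureBundle",
      receptor = rec$tensor, ligand = rec$tensor, complex = cplx$tensor,
      manifestReceptor = rec$manifest, manifestComplex = cplx$manifest,
      L = as.integer(L))
}

# tile an L x K per-residue feature along rows: out[i, j, k] = f[i, k]
.tileRows <- function(f, L) {
  K <- ncol(f)
  out <- array(0, dim = c(L, L, K))
  for (k in seq_len(K)) out[, , k] <- matrix(f[, k], L, L)
  out
}

# tile along columns: out[i, j, k] = f[j, k]
.tileCols <- function(f, L) {
  K <- ncol(f)
  out <- array(0, dim = c(L, L, K))
  for (k in seq_len(K)) out[, , k] <- matrix(f[, k], L, L, byrow = TRUE)
  out
}

.bindChannels <- function(blocks) {
  L <- dim(blocks[[1L]])[1L]
  widths <- vapply(blocks, function(b) dim(b)[3L], integer(1))
  total <- sum(widths)
  tensor <- array(0, dim = c(L, L, total))
  man <- data.frame(block = names(blocks), start = NA_integer_,
                    end = NA_integer_, stringsAsFactors = FALSE)
  at <- 1L
  for (b in seq_along(blocks)) {
    w <- widths[b]
    tensor[, , at:(at + w - 1L)] <- blocks[[b]]
    man$start[b] <- at; man$end[b] <- at + w - 1L
    at <- at + w
  }
  list(tensor = tensor, manifest = man)
}

#' Write a FeatureBundle to an RDS container
#' @param bundle a FeatureBundle.
#' @param path output path.
#' @export
writeFeatureBundle <- function(bundle, path) {
  saveRDS(bundle, path)
  invisible(path)
}

#' Read a FeatureBundle from an RDS container
#' @param path input path.
#' @export
readFeatureBundle <- function(path) {
  b <- readRDS(path)
  if (!methods::is(b, "FeatureBundle")) stop("not a FeatureBundle: ", path)
  b
}
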