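#' Mean-field direct coupling analysis with average product correction
#'
#' Estimates residue-residue couplings from column covariation: a
#' sequence-weighted one-hot covariance matrix over 20 amino-acid states
#' per column (the gap state is dropped to fix the gauge) is
#' shrinkage-regularized toward its diagonal and inverted; the coupling
#' score of a column pair is the Frobenius norm of the corresponding
#' 20 x 20 block of the negative inverse.  The average product correction
#' removes background coupling:
#' S_apc(i,j) = S(i,j) - S_mean(i) * S_mean(j) / S_mean, with means taken
#' off-diagonal.
#'
#' @param msa an \linkS4class{MSAProfile} with at least 2 effective rows.
#' @param shrinkage fraction in (0,1]: off-diagonal covariance entries are
#'   scaled by (1 - shrinkage) (default 0.5).
#' @param weights per-row weights; default 80%-identity clustering weights.
#' @param pseudocount relative pseudocount mixed into the one-hot
#'   frequencies before covariance estimation (default 0.1).
#' @return a \linkS4class{DCAResult} with raw (`di`) and APC-corrected
#'   (`apc`) score matrices.
#' @export
meanFieldDca <- function(msa, shrinkage = 0.5,
                         weights = sequenceWeights(msa),
                         pseudocount = 0.1) {
  X <- .msaInt(msa)
  M <- nrow(X); L <- ncol(X)
  if (M < 2L) stop("need at least 2 sequences for coupling analysis")
  if (shrinkage <= 0 || shrinkage > 1) stop("shrinkage must be in (0,1]")
  q <- 20L
  w <- weights / sum(weights)
  # one-hot design matrix M x (L*q), gap rows all-zero within a column block
  H <- matrix(0, M, L * q)
  for (s in seq_len(q)) {
    hit <- which(X == s, arr.ind = TRUE)
    H[cbind(hit[, 1L], (hit[, 2L] - 1L) * q + s)] <- 1
  }
  f1 <- colSums(w * H)
  f2 <- crossprod(H * sqrt(w))           # weighted E[x x^T]
  # pseudocount toward the uniform distribution
  lam <- pseudocount
  f1 <- (1 - lam) * f1 + lam / q
  f2 <- (1 - lam) * f2 + lam / q^2
  for (i in seq_len(L)) {                # within-column blocks get exact
    idx <- ((i - 1L) * q + 1L):(i * q)   # single-site pseudocount structure
    f2[idx, idx] <- 0
    f2[cbind(idx, idx)] <- f1[idx]
  }
  C <- f2 - tcrossprod(f1)
  # shrink off-diagonal entries toward zero (keeps the diagonal)
  Creg <- (1 - shrinkage) * C
  diag(Creg) <- diag(C)
  J <- tryCatch(-solve(Creg), error = function(e)
    stop("covariance inversion failed (singular after shrinkage ", shrinkage,
         "); increase the shrinkage fraction", call. = FALSE))
  S <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    ii <- ((i - 1L) * q + 1L):(i * q)
    for (j in (i + 1L):L) {
      jj <- ((j - 1L) * q + 1L):(j * q)
      B <- J[ii, jj]
      B <- B - rowMeans(B) %o% rep(1, q) - rep(1, q) %o% colMeans(B) + mean(B)
      S[i, j] <- S[j, i] <- sqrt(sum(B^2))
    }
  }
  new("DCAResult", di = S, apc = apcCorrect(S))
}

#' Average product correction of a symmetric score matrix
#'
#' S_apc(i,j) = S(i,j) - S_mean(i) S_mean(j) / S_mean, with full row and
#' grand means, so that any rank-one score structure u u^T is annihilated
#' exactly; the result's diagonal is set to zero.
#'
#' @param S symmetric numeric matrix.
#' @return corrected symmetric matrix with zero diagonal.
#' @export
apcCorrect <- function(S) {
  L <- nrow(S)
  if (L < 2L) return(S * 0)
  rowm <- rowMeans(S)
  grand <- mean(S)
  A <- if (abs(grand) < .Machine$double.eps) S else S - (rowm %o% rowm) / grand
  diag(A) <- 0
  A
}
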