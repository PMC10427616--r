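#' Symmetry-aware top-k precision of a contact prediction
#'
#' Predicted pairs are deduplicated over (i,j)/(j,i) (upper triangle
#' including the diagonal), ranked by probability (ties broken by (i,j)
#' lexicographic order), and scored against the ground-truth union map
#' over all chain pairs (or, optionally, the maximal interface only).
#' Precision at k = (number of true contacts among the top k) / k for
#' k in {1, 10, 25, 50, floor(L/10), floor(L/5), L} (floored k values are
#' clamped to >= 1).  If the truth contains no contact, precisions are
#' reported as NA (undefined), never 0.
#'
#' @param pred a \linkS4class{ContactPrediction} or probability matrix.
#' @param truth a \linkS4class{ContactMap} or logical matrix.
#' @param L monomer length (defaults to nrow of the map).
#' @param policy "union" (default) or "max_interface": which truth map the
#'   prediction is scored against.
#' @return named numeric vector: top1, top10, top25, top50, topL10, topL5,
#'   topL.
#' @export
topkPrecision <- function(pred, truth, L = NULL,
                          policy = c("union", "max_interface")) {
  policy <- match.arg(policy)
  P <- if (methods::is(pred, "ContactPrediction")) pred@probs else pred
  Y <- if (methods::is(truth, "ContactMap")) {
    if (policy == "union") truth@union else .maxInterfaceMap(truth)
  } else truth
  if (!all(dim(P) == dim(Y))) stop("prediction/truth shape mismatch")
  if (is.null(L)) L <- nrow(P)
  ks <- c(top1 = 1L, top10 = 10L, top25 = 25L, top50 = 50L,
          topL10 = max(1L, L %/% 10L), topL5 = max(1L, L %/% 5L), topL = L)
  # symmetry-aware deduplication: a pair counts once, as max over (i,j)/(j,i)
  Pm <- pmax(P, t(P)); Ym <- Y | t(Y)
  idx <- which(upper.tri(Pm, diag = TRUE), arr.ind = TRUE)
  p <- Pm[idx]; y <- Ym[idx]
  if (!any(y)) return(stats::setNames(rep(NA_real_, length(ks)), names(ks)))
  ord <- order(-p, idx[, 1L], idx[, 2L])
  yr <- y[ord]
  hits <- cumsum(yr)
  vapply(ks, function(k) {
    k <- min(k, length(yr))
    hits[k] / k
  }, numeric(1))
}

# union restricted to the chain pair with the most contacts
.maxInterfaceMap <- function(cm) {
  if (length(cm@pairMaps) == 0L) return(cm@union)
  counts <- vapply(cm@pairMaps, sum, numeric(1))
  m <- cm@pairMaps[[which.max(counts)]]
  m | t(m)
}

#' Inter-chain contact density of a complex
#'
#' The number of inter-chain contacts on the chain pair with the most
#' contacts (the maximal interface), divided by 2L.
#'
#' @param x a \linkS4class{ComplexStructure} (>= 2 chains) or a
#'   \linkS4class{ContactMap}.
#' @param L monomer length; required when `x` is a ContactMap without
#'   structure context, otherwise derived.
#' @param cutoff contact cutoff in Angstrom (default 8.0).
#' @return numeric contact density >= 0.
#' @export
contactDensity <- function(x, L = NULL, cutoff = 8.0) {
  cm <- if (methods::is(x, "ComplexStructure")) {
    if (nChains(x) < 2L) stop("contact density needs at least two chains")
    if (is.null(L)) L <- chainLength(x)
    interchainContactMap(x, cutoff = cutoff)
  } else x
  if (is.null(L)) L <- nrow(cm@union)
  counts <- vapply(cm@pairMaps, sum, numeric(1))
  if (length(counts) == 0L) stop("contact map carries no per-pair maps")
  max(counts) / (2 * L)
}

#' Classify the oligomeric state from the maximum contact probability
#'
#' maxp <= theta1: monomer; theta1 < maxp <= theta2: dimer;
#' maxp > theta2: higher-order oligomer.
#'
#' @param maxp maximum predicted contact probability (vectorized).
#' @param theta1 monomer/oligomer threshold (default 0.77).
#' @param theta2 dimer/higher-order threshold (default 0.97).
#' @return data.frame(maxp, state) with state in
#'   {"monomer", "dimer", "higher-order"}.
#' @export
classifyOligomericState <- function(maxp, theta1 = 0.77, theta2 = 0.97) {
  if (theta1 >= theta2) stop("theta1 must be < theta2")
  if (any(maxp < 0 | maxp > 1)) stop("probabilities must lie in [0,1]")
  state <- ifelse(maxp <= theta1, "monomer",
                  ifelse(maxp <= theta2, "dimer", "higher-order"))
  data.frame(maxp = maxp, state = state,
             theta1 = theta1, theta2 = theta2)
}

#' Success-rate curves for monomer/oligomer discrimination
#'
#' For each threshold t: the fraction of true monomers whose maximum
#' contact probability is below t (monomer success) and the fraction of
#' true oligomers whose maximum probability is at least t (oligomer
#' success).
#'
#' @param maxp numeric vector of per-target maximum contact probabilities.
#' @param labels character vector in {"monomer", "oligomer"}.
#' @param thresholds numeric grid (default seq(0, 1, 0.01)).
#' @return data.frame(threshold, monomerSuccess, oligomerSuccess).
#' @export
successRateCurve <- function(maxp, labels, thresholds = seq(0, 1, 0.01)) {
  if (length(maxp) == 0L) stop("empty input")
  if (!all(labels %in% c("monomer", "oligomer")))
    stop("labels must be 'monomer' or 'oligomer'")
  isMono <- labels == "monomer"
  mono <- vapply(thresholds, function(t)
    if (any(isMono)) mean(maxp[isMono] < t) else NA_real_, numeric(1))
  olig <- vapply(thresholds, function(t)
    if (any(!isMono)) mean(maxp[!isMono] >= t) else NA_real_, numeric(1))
  data.frame(threshold = thresholds, monomerSuccess = mono,
             oligomerSuccess = olig)
}

#' Write an evaluation report as TSV
#'
#' One row per target: the top-k precisions, contact density, maximum
#' predicted probability and the oligomeric-state call.
#'
#' @param rows data.frame as assembled by the caller.
#' @param path output path.
#' @export
writeEvalReport <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
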