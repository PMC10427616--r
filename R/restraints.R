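#' Piecewise distance-restraint energy for a predicted contact
#'
#' E(r) = E0 for r <= 8 A; E0 * (1 - (r - 8)/4) for 8 < r <= 12 A; 0
#' beyond 12 A.  E0 is an empirical per-contact constraint energy,
#' -100.0 kcal/mol by default.  Continuous in r and nondecreasing for
#' negative E0.  Vectorized over r.
#'
#' @param r residue-residue distance in Angstrom (>= 0).
#' @param E0 plateau energy in kcal/mol (default -100.0).
#' @return energy in kcal/mol.
#' @export
restraintEnergy <- function(r, E0 = -100.0) {
  if (any(r < 0)) stop("distance must be nonnegative")
  ifelse(r <= 8.0, E0,
         ifelse(r <= 12.0, E0 * (1 - (r - 8.0) / 4.0), 0.0))
}

#' Select high-confidence predicted contacts as docking restraints
#'
#' Deduplicated residue pairs are ranked by predicted probability (ties
#' broken by (i, j) lexicographic order); pairs with probability strictly
#' above `pmin` are kept, at most `top` of them.
#'
#' @param pred a \linkS4class{ContactPrediction} or probability matrix.
#' @param top maximum number of restraints (default 10).
#' @param pmin probability threshold, exclusive (default 0.65).
#' @param E0 restraint energy constant recorded per term (default -100.0).
#' @return data.frame(i, j, probability, E0), 1-based residue indices,
#'   sorted by descending probability; possibly zero rows.
#' @export
selectRestraints <- function(pred, top = 10L, pmin = 0.65, E0 = -100.0) {
  P <- if (methods::is(pred, "ContactPrediction")) pred@probs else pred
  Pm <- pmax(P, t(P))
  idx <- which(upper.tri(Pm, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L], probability = Pm[idx])
  df <- df[df$probability > pmin, , drop = FALSE]
  df <- df[order(-df$probability, df$i, df$j), , drop = FALSE]
  df <- utils::head(df, top)
  df$E0 <- rep(E0, nrow(df))
  rownames(df) <- NULL
  df
}

#' Write selected restraints as a TSV exchange file
#'
#' Columns: chain_i, res_i, chain_j, res_j, probability, E0.  For a
#' homo-oligomer the two chains are the receptor/ligand roles ("A"/"B" by
#' default); residue numbers are 1-based.
#'
#' @param restraints data.frame from \code{\link{selectRestraints}}.
#' @param path output path.
#' @param chainI,chainJ chain labels (defaults "A", "B").
#' @export
writeRestraints <- function(restraints, path, chainI = "A", chainJ = "B") {
  out <- data.frame(chain_i = rep(chainI, nrow(restraints)),
                    res_i = restraints$i,
                    chain_j = rep(chainJ, nrow(restraints)),
                    res_j = restraints$j,
                    probability = restraints$probability,
                    E0 = restraints$E0)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
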