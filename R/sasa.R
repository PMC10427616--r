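#' Solvent-accessible surface area by Shrake-Rupley sphere sampling
#'
#' Numerical SASA with a deterministic golden-spiral point lattice on each
#' atom's solvent-expanded sphere (radius = van der Waals radius + probe).
#' A lattice point is accessible if it lies outside every neighbouring
#' atom's expanded sphere; the atom's SASA is the accessible fraction of
#' its sphere area.  Deterministic for a fixed `nPoints`.
#'
#' @param x a ComplexStructure.
#' @param chains chain ids to include (default: all chains, computed
#'   together, so chains occlude each other).
#' @param probe probe radius in Angstrom (default 1.4).
#' @param nPoints lattice points per atom (default 92).
#' @param relSasaThreshold relative-SASA threshold for the surface flag
#'   (default 0.05 of the residue's Gly-X-Gly reference area).
#' @return data.frame with one row per residue: `chain`, `resno`, `resname`,
#'   `sasa` (Angstrom^2), `relSasa`, `surface` (logical); attribute
#'   "atomSasa" carries the per-atom values.
#' @export
computeSasa <- function(x, chains = chainIds(x), probe = 1.4, nPoints = 92L,
                        relSasaThreshold = 0.05) {
  a <- x@atoms[x@atoms$chain %in% chains, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms in selected chains")
  ele <- a$element
  known <- ele %in% names(VDW_RADII)
  if (any(!known))
    warning("unknown element(s) ", paste(unique(ele[!known]), collapse = ","),
            "; using default radius ", VDW_DEFAULT)
  rad <- ifelse(known, VDW_RADII[ele], VDW_DEFAULT)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- .spherePoints(nPoints)
  rExp <- rad + probe
  # neighbour lists via cutoff on pairwise distances
  maxR <- max(rExp)
  d2 <- .crossDist2(xyz, xyz)
  atomSasa <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] <= (rExp[i] + maxR)^2)
    nb <- nb[nb != i]
    nb <- nb[d2[i, nb] <= (rExp[i] + rExp[nb])^2]
    p <- sweep(pts * rExp[i], 2L, xyz[i, ], "+")
    if (length(nb)) {
      pd2 <- .crossDist2(p, xyz[nb, , drop = FALSE])
      occluded <- rowSums(pd2 < matrix(rExp[nb]^2, nrow(p), length(nb),
                                       byrow = TRUE)) > 0
      acc <- sum(!occluded)
    } else acc <- nrow(p)
    atomSasa[i] <- 4 * pi * rExp[i]^2 * acc / nrow(p)
  }
  key <- paste(a$chain, a$resno, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    resname = a$resname[first], stringsAsFactors = FALSE)
  res$sasa <- as.numeric(rowsum(atomSasa, factor(key, levels = key[first])))
  aa1 <- ifelse(res$resname %in% names(AA3TO1), AA3TO1[res$resname], NA)
  ref <- ifelse(!is.na(aa1) & aa1 %in% names(MAX_ASA), MAX_ASA[aa1], NA)
  res$relSasa <- ifelse(is.na(ref), NA, pmin(res$sasa / ref, Inf))
  res$surface <- !is.na(res$relSasa) & res$relSasa >= relSasaThreshold
  res$surface[is.na(res$relSasa)] <- res$sasa[is.na(res$relSasa)] > 0
  attr(res, "atomSasa") <- atomSasa
  res
}

# Deterministic golden-spiral lattice of n points on the unit sphere
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Buried interface area between two chains
#'
#' Half the solvent-accessible surface buried on complex formation:
#' (SASA_A,alone + SASA_B,alone - SASA_AB,together) / 2, clamped at zero.
#'
#' @param x a ComplexStructure containing both chains.
#' @param chainA,chainB chain ids.
#' @param probe,nPoints passed to \code{\link{computeSasa}}.
#' @return interface area in Angstrom^2.
#' @export
interfaceArea <- function(x, chainA, chainB, probe = 1.4, nPoints = 92L) {
  for (ch in c(chainA, chainB))
    if (!ch %in% chainIds(x)) stop("chain not found: ", ch)
  sA <- sum(computeSasa(x, chains = chainA, probe = probe,
                        nPoints = nPoints)$sasa)
  sB <- sum(computeSasa(x, chains = chainB, probe = probe,
                        nPoints = nPoints)$sasa)
  sAB <- sum(computeSasa(x, chains = c(chainA, chainB), probe = probe,
                         nPoints = nPoints)$sasa)
  max((sA + sB - sAB) / 2, 0)
}
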