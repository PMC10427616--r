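#' Parse a PDB or mmCIF structure into a ComplexStructure
#'
#' Reads all chains, keeps heavy atoms only (hydrogens and deuteriums are
#' dropped), resolves alternate locations to the highest-occupancy copy and
#' discards heteroatoms (waters, ligands).
#'
#' @param path path to a PDB or mmCIF file.
#' @param format one of "auto", "pdb", "mmcif"; "auto" decides by extension.
#' @param symmetryOrder optional declared symmetry order of the assembly.
#' @return a \linkS4class{ComplexStructure}.
#' @examples
#' cx <- makeToyComplex(nChains = 2, L = 24, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' writeStructurePdb(cx, f)
#' parseStructure(f)
#' @export
parseStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                           symmetryOrder = NA_integer_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  if (format == "pdb") .checkPdbLines(path)
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("unreadable structure file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no protein ATOM records in ", path)
  ele <- .atomElement(a$elesy, a$elety)
  keep <- !(ele %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]; ele <- ele[keep]
  if (nrow(a) == 0L) stop("no heavy atoms in ", path)
  # altloc: keep the highest-occupancy copy of each (chain, resno, atom name)
  alt <- a$alt; alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    occ <- a$o; occ[is.na(occ)] <- 1
    key <- paste(a$chain, a$insert %||% "", a$resno, a$elety, sep = "\r")
    ord <- order(key, -occ)
    a <- a[ord, , drop = FALSE]; ele <- ele[ord]; key <- key[ord]
    keep <- !duplicated(key)
    a <- a[keep, , drop = FALSE]; ele <- ele[keep]
  }
  chains <- unique(a$chain)
  atoms <- data.frame(chain = a$chain, resno = as.integer(a$resno),
                      resname = a$resid, atom = a$elety, element = ele,
                      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  new("ComplexStructure", atoms = atoms, chains = chains,
      symmetryOrder = as.integer(symmetryOrder))
}

# Minimal structural sanity check on raw PDB text so that truncated files
# fail with the offending line number rather than a downstream surprise.
.checkPdbLines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (any(rec)) {
    bad <- which(rec & nchar(lines) < 54L)
    if (length(bad))
      stop(sprintf("truncated ATOM record at line %d of %s", bad[1L], path),
           call. = FALSE)
  }
  invisible(TRUE)
}

.atomElement <- function(elesy, elety) {
  ele <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- ele == ""
  if (any(miss)) {
    # derive from the atom name: strip digits/primes, take leading letters
    nm <- gsub("[0-9']", "", toupper(trimws(elety[miss])))
    guess <- substr(nm, 1L, 1L)
    two <- substr(nm, 1L, 2L) %in% c("SE", "CL", "BR", "FE", "ZN", "MG")
    guess[two] <- substr(nm[two], 1L, 2L)
    ele[miss] <- guess
  }
  ele
}

#' Chain identifiers of a structure
#' @param x a ComplexStructure.
#' @return character vector.
#' @export
chainIds <- function(x) x@chains

#' Number of chains
#' @param x a ComplexStructure.
#' @export
nChains <- function(x) length(x@chains)

#' One-letter sequence of a chain
#' @param x a ComplexStructure.
#' @param chain chain id (default: first chain).
#' @return character scalar, unknown residues as "X".
#' @export
chainSequence <- function(x, chain = chainIds(x)[1L]) {
  a <- x@atoms[x@atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain not found: ", chain)
  res <- a$resname[!duplicated(a$resno)]
  paste(ifelse(res %in% names(AA3TO1), AA3TO1[res], "X"), collapse = "")
}

#' Residue count of a chain
#' @param x a ComplexStructure.
#' @param chain chain id (default: first chain).
#' @export
chainLength <- function(x, chain = chainIds(x)[1L]) {
  length(unique(x@atoms$resno[x@atoms$chain == chain]))
}

# Split a chain's atoms into a list of per-residue coordinate matrices
.residueAtoms <- function(x, chain) {
  a <- x@atoms[x@atoms$chain == chain, , drop = FALSE]
  split(a, factor(a$resno, levels = unique(a$resno)))
}

# Representative-atom coordinates per residue: C-beta, C-alpha for glycine
# (and for residues whose C-beta is absent).  Residues with neither are
# returned as NA rows and flagged.
.representativeCoords <- function(x, chain) {
  resl <- .residueAtoms(x, chain)
  L <- length(resl)
  xyz <- matrix(NA_real_, L, 3L)
  for (i in seq_len(L)) {
    r <- resl[[i]]
    j <- match("CB", r$atom)
    if (is.na(j)) j <- match("CA", r$atom)
    if (!is.na(j)) xyz[i, ] <- c(r$x[j], r$y[j], r$z[j])
  }
  list(xyz = xyz, flagged = which(is.na(xyz[, 1L])))
}

#' Inter-chain residue contact map at a heavy-atom distance cutoff
#'
#' Residue pair (i, j) of an ordered chain pair is in contact iff the
#' minimum distance over all heavy-atom pairs is at most `cutoff`
#' (inclusive).  For homo-oligomers, residues are identified across chains
#' by their position in the chain, the per-pair maps are OR-ed into a union
#' map, and the union is symmetrized over (i,j)/(j,i).
#'
#' @param x a ComplexStructure with at least two chains.
#' @param cutoff distance cutoff in Angstrom (default 8.0).
#' @return a \linkS4class{ContactMap}.
#' @export
interchainContactMap <- function(x, cutoff = 8.0) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  chs <- chainIds(x)
  if (length(chs) < 2L) stop("inter-chain contacts need at least two chains")
  lens <- vapply(chs, function(ch) chainLength(x, ch), integer(1))
  if (length(unique(lens)) != 1L)
    stop("chains have different lengths; homo-oligomer identification impossible")
  L <- lens[[1L]]
  coords <- lapply(chs, function(ch) {
    a <- x@atoms[x@atoms$chain == ch, , drop = FALSE]
    ridx <- match(a$resno, unique(a$resno))   # 1..L internal index
    list(xyz = cbind(a$x, a$y, a$z), ridx = ridx)
  })
  names(coords) <- chs
  union <- matrix(FALSE, L, L)
  pairMaps <- list()
  for (p in seq_len(length(chs) - 1L)) for (q in (p + 1L):length(chs)) {
    A <- coords[[p]]; B <- coords[[q]]
    d2 <- .crossDist2(A$xyz, B$xyz)
    close <- d2 <= cutoff^2
    # aggregate atom-level booleans to residue level (rowsum orders groups
    # by sorted index, i.e. 1..L)
    m <- rowsum(close + 0, A$ridx)
    m <- t(rowsum(t(m), B$ridx)) > 0
    dimnames(m) <- NULL
    pairMaps[[paste(chs[p], chs[q], sep = "|")]] <- m
    union <- union | m | t(m)
  }
  new("ContactMap", union = union, pairMaps = pairMaps, cutoff = cutoff)
}

# squared Euclidean cross-distance matrix
.crossDist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Intra-chain representative-atom distance map of one monomer
#'
#' Distances between representative atoms (C-beta; C-alpha for glycine).
#' Residues without a representative atom are flagged and their distances
#' imputed as +Inf.
#'
#' @param x a ComplexStructure.
#' @param chain chain id (default: first chain).
#' @return numeric L x L matrix with attribute "flagged" (integer indices).
#' @export
intrachainDistanceMap <- function(x, chain = chainIds(x)[1L]) {
  rep <- .representativeCoords(x, chain)
  L <- nrow(rep$xyz)
  if (length(rep$flagged) == L) stop("no representative atoms in chain ", chain)
  xyz <- rep$xyz
  ok <- setdiff(seq_len(L), rep$flagged)
  dm <- matrix(Inf, L, L)
  dm[ok, ok] <- sqrt(.crossDist2(xyz[ok, , drop = FALSE],
                                 xyz[ok, , drop = FALSE]))
  diag(dm) <- 0
  attr(dm, "flagged") <- rep$flagged
  dm
}

#' Radial-basis-function encoding of a distance map
#'
#' Each distance d is expanded over 64 Gaussian bins,
#' f_k(d) = exp(-((d - d_k)/sigma)^2), with bin centers d_k = 2 + sigma * k
#' (k = 0..63) spanning 2-22 Angstrom and sigma = 0.3125 Angstrom.
#' Distances of +Inf (flagged residues) encode to all-zero channels.
#'
#' @param dm numeric L1 x L2 distance matrix (Angstrom).
#' @param nBins number of bins (default 64).
#' @param dMin lower end of the bin range (default 2).
#' @param sigma Gaussian width = bin spacing (default 0.3125).
#' @return numeric L1 x L2 x nBins array with attributes "centers", "sigma".
#' @export
encodeDistanceRBF <- function(dm, nBins = 64L, dMin = 2, sigma = 0.3125) {
  stopifnot(is.matrix(dm), nBins >= 1L, sigma > 0)
  centers <- dMin + sigma * (seq_len(nBins) - 1L)
  out <- array(0, dim = c(nrow(dm), ncol(dm), nBins))
  finite <- is.finite(dm)
  dv <- dm[finite]
  for (k in seq_len(nBins)) {
    f <- exp(-((dv - centers[k]) / sigma)^2)
    slab <- matrix(0, nrow(dm), ncol(dm))
    slab[finite] <- f
    out[, , k] <- slab
  }
  attr(out, "centers") <- centers
  attr(out, "sigma") <- sigma
  out
}

#' Write a structure as a PDB file
#'
#' @param x a ComplexStructure.
#' @param path output path.
#' @export
writeStructurePdb <- function(x, path) {
  a <- x@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$atom, elesy = a$element)
  invisible(path)
}

#' Write a matrix as 3-column text (i, j, value; 1-based)
#'
#' The plain-text exchange format for contact and distance maps.
#' @param m matrix (logical or numeric).
#' @param path output path.
#' @param upperOnly write only i <= j entries (default TRUE).
#' @export
writeMapText <- function(m, path, upperOnly = TRUE) {
  idx <- which(if (upperOnly) upper.tri(m, diag = TRUE) else
    matrix(TRUE, nrow(m), ncol(m)), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L], value = as.numeric(m[idx]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
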