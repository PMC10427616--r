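#' Construct a CurationRule
#'
#' @param minInterfaceArea minimum buried area of the largest pairwise
#'   interface, Angstrom^2 (default 500).
#' @param minInterfaceContacts minimum contact count of the largest
#'   interface (default 10).
#' @param maxMonomerLength maximum monomer length (default 1024).
#' @param minChainIdentity minimum pairwise intra-complex sequence
#'   identity (default 0.99).
#' @param requireSymmetryMatch require chain count == declared symmetry
#'   order (default TRUE).
#' @param clusterIdentity redundancy-clustering identity (default 0.30).
#' @return a \linkS4class{CurationRule}.
#' @export
curationRule <- function(minInterfaceArea = 500, minInterfaceContacts = 10L,
                         maxMonomerLength = 1024L, minChainIdentity = 0.99,
                         requireSymmetryMatch = TRUE,
                         clusterIdentity = 0.30) {
  new("CurationRule", minInterfaceArea = minInterfaceArea,
      minInterfaceContacts = as.integer(minInterfaceContacts),
      maxMonomerLength = as.integer(maxMonomerLength),
      minChainIdentity = minChainIdentity,
      requireSymmetryMatch = requireSymmetryMatch,
      clusterIdentity = clusterIdentity)
}

# contact count between two chains at a heavy-atom cutoff (no length
# identification needed)
.pairContactCount <- function(x, chA, chB, cutoff = 8.0) {
  a <- x@atoms[x@atoms$chain == chA, , drop = FALSE]
  b <- x@atoms[x@atoms$chain == chB, , drop = FALSE]
  d2 <- .crossDist2(cbind(a$x, a$y, a$z), cbind(b$x, b$y, b$z))
  close <- d2 <= cutoff^2
  ra <- match(a$resno, unique(a$resno))
  rb <- match(b$resno, unique(b$resno))
  m <- rowsum(close + 0, ra)
  m <- t(rowsum(t(m), rb)) > 0
  sum(m)
}

# positional identity for equal-length sequences, global alignment
# percent identity otherwise
.seqIdentity <- function(s1, s2) {
  if (nchar(s1) == nchar(s2)) {
    a <- strsplit(s1, "")[[1L]]; b <- strsplit(s2, "")[[1L]]
    return(mean(a == b))
  }
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(s1),
                                      Biostrings::AAString(s2),
                                      substitutionMatrix = NULL,
                                      gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(al, type = "PID1") / 100
}

#' Apply curation filters to a complex
#'
#' Checks, in order: chain count equals the declared symmetry order (when
#' required), monomer length, pairwise intra-complex chain identity,
#' largest pairwise interface area, and largest-interface contact count.
#' All failed criteria are reported.
#'
#' @param x a \linkS4class{ComplexStructure}.
#' @param rule a \linkS4class{CurationRule}.
#' @param cutoff contact cutoff in Angstrom (default 8.0).
#' @return list(accept = logical, reasons = character vector of failed
#'   criteria among "symmetry_order", "monomer_length", "chain_identity",
#'   "interface_area", "contact_count").
#' @export
applyCuration <- function(x, rule = curationRule(), cutoff = 8.0) {
  reasons <- character(0)
  chs <- chainIds(x)
  if (rule@requireSymmetryMatch) {
    if (is.na(x@symmetryOrder))
      stop("symmetry annotation missing but the chain-count rule is enabled")
    if (length(chs) != x@symmetryOrder)
      reasons <- c(reasons, "symmetry_order")
  }
  if (max(vapply(chs, function(ch) chainLength(x, ch), integer(1))) >
      rule@maxMonomerLength)
    reasons <- c(reasons, "monomer_length")
  if (length(chs) >= 2L) {
    seqs <- vapply(chs, function(ch) chainSequence(x, ch), character(1))
    idOk <- TRUE
    for (p in seq_len(length(chs) - 1L)) for (q in (p + 1L):length(chs))
      if (.seqIdentity(seqs[p], seqs[q]) < rule@minChainIdentity)
        idOk <- FALSE
    if (!idOk) reasons <- c(reasons, "chain_identity")
    areas <- contacts <- numeric(0)
    for (p in seq_len(length(chs) - 1L)) for (q in (p + 1L):length(chs)) {
      areas <- c(areas, interfaceArea(x, chs[p], chs[q]))
      contacts <- c(contacts, .pairContactCount(x, chs[p], chs[q], cutoff))
    }
    if (max(areas) < rule@minInterfaceArea)
      reasons <- c(reasons, "interface_area")
    if (max(contacts) < rule@minInterfaceContacts)
      reasons <- c(reasons, "contact_count")
  } else {
    reasons <- c(reasons, "interface_area", "contact_count")
  }
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Greedy sequence clustering at an identity cutoff
#'
#' Deterministic greedy incremental clustering: sequences are visited in
#' input order; a sequence joins the first existing cluster whose
#' representative it matches at >= `identity` (a shared-3-mer prefilter
#' skips hopeless comparisons), otherwise it founds a new cluster and
#' becomes its representative.  Callers wanting resolution-ranked
#' representatives should sort the input accordingly first.
#'
#' @param seqs character vector of sequences.
#' @param identity identity cutoff as a fraction (default 0.30).
#' @return integer cluster assignment (1-based, in order of founding);
#'   attribute "representatives" gives the representative index of each
#'   cluster.
#' @export
greedyCluster <- function(seqs, identity = 0.30) {
  if (length(seqs) == 0L) stop("empty sequence list")
  if (any(nchar(seqs) == 0L)) stop("empty sequence in input")
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 3L) return(s)
    unique(substring(s, 1:(n - 2L), 3:n))
  })
  reps <- integer(0)
  assign <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      r <- reps[ci]
      shared <- length(intersect(kmers[[i]], kmers[[r]]))
      jac <- shared / length(union(kmers[[i]], kmers[[r]]))
      if (identity >= 0.3 && jac < 0.01) next
      if (.seqIdentity(seqs[i], seqs[r]) >= identity) {
        assign[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  attr(assign, "representatives") <- reps
  assign
}
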