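#' Read a multiple sequence alignment (A3M or aligned FASTA)
#'
#' The first record is taken as the query.  For A3M input, lowercase
#' letters and "." mark insert states relative to the query and are
#' removed; the remaining uppercase/gap columns must align to the query
#' length.  For aligned FASTA ("afa") all rows must already share one
#' length.
#'
#' @param path input file.
#' @param format "a3m" or "afa"; "auto" decides by extension.
#' @return an \linkS4class{MSAProfile}.
#' @export
readMsa <- function(path, format = c("auto", "a3m", "afa")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "afa"
  if (format == "afa") {
    ss <- Biostrings::readAAStringSet(path)
    if (length(ss) == 0L) stop("empty alignment file: ", path)
    ids <- names(ss)
    rows <- toupper(as.character(ss))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty alignment file: ", path)
    hdr <- grepl("^>", lines)
    if (!hdr[1L]) stop("A3M must start with a '>' header")
    grp <- cumsum(hdr)
    ids <- sub("^>", "", lines[hdr])
    rows <- vapply(split(lines[!hdr], grp[!hdr]),
                   function(x) paste(x, collapse = ""), character(1))
    # drop insert states (lowercase and '.'), keep match columns
    rows <- vapply(rows, function(s) gsub("[a-z.]", "", s), character(1),
                   USE.NAMES = FALSE)
  }
  L <- nchar(rows[1L])
  if (any(nchar(rows) != L))
    stop("ragged alignment: rows of unequal length after insert removal")
  m <- matrix(unlist(strsplit(rows, "", fixed = TRUE)), nrow = length(rows),
              byrow = TRUE)
  m[!(m %in% c(AA1, "-"))] <- "-"   # non-standard symbols treated as gaps
  new("MSAProfile", seqs = m, ids = ids)
}

#' Write an MSAProfile as aligned FASTA
#' @param msa an MSAProfile.
#' @param path output path.
#' @export
writeMsa <- function(msa, path) {
  rows <- apply(msa@seqs, 1L, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", msa@ids), rows)), path)
  invisible(path)
}

#' Alignment as a character matrix
#' @param msa an MSAProfile.
#' @export
msaMatrix <- function(msa) msa@seqs

#' Number of aligned sequences
#' @param msa an MSAProfile.
#' @export
nSequences <- function(msa) nrow(msa@seqs)

# integer encoding 1..20 = AA1, 21 = gap/other
.msaInt <- function(msa) {
  m <- match(msa@seqs, AA1)
  m[is.na(m)] <- 21L
  matrix(m, nrow(msa@seqs), ncol(msa@seqs))
}

#' Greedy maximum-diversity filtering of an MSA
#'
#' If the alignment has at most `cap` rows it is returned unchanged.
#' Otherwise rows are selected greedily, starting from the query, always
#' adding the row with the largest minimum Hamming distance to the rows
#' already selected (ties broken by lowest row index), until exactly `cap`
#' rows remain.  Deterministic.
#'
#' @param msa an MSAProfile.
#' @param cap maximum number of rows to keep (default 512).
#' @return an MSAProfile with at most `cap` rows, query first.
#' @export
diversityFilter <- function(msa, cap = 512L) {
  if (cap < 1L) stop("cap must be >= 1")
  M <- nrow(msa@seqs)
  if (M <= cap) return(msa)
  X <- .msaInt(msa)
  minDist <- rep(Inf, M)
  sel <- integer(cap)
  sel[1L] <- 1L
  last <- 1L
  for (k in 2L:cap) {
    d <- rowSums(X != matrix(X[last, ], M, ncol(X), byrow = TRUE))
    minDist <- pmin(minDist, d)
    minDist[sel[seq_len(k - 1L)]] <- -1
    last <- which.max(minDist)   # ties: lowest index
    sel[k] <- last
  }
  sel <- sort(sel)
  new("MSAProfile", seqs = msa@seqs[sel, , drop = FALSE], ids = msa@ids[sel])
}

#' Sequence weights by identity clustering
#'
#' Weight of row s is 1 / (number of rows, itself included, with pairwise
#' identity >= `identity`).  Identity is computed over positions where both
#' rows are non-gap; pairs sharing no non-gap position count as identity 0.
#'
#' @param msa an MSAProfile.
#' @param identity identity threshold as a fraction (default 0.80, the
#'   conventional weighting for profile/coupling estimation).
#' @return numeric vector of per-row weights.
#' @export
sequenceWeights <- function(msa, identity = 0.80) {
  X <- .msaInt(msa)
  M <- nrow(X)
  nongap <- X != 21L
  both <- tcrossprod(nongap + 0)               # shared non-gap positions
  matches <- matrix(0, M, M)
  for (s in 1:20) {
    B <- (X == s) + 0
    matches <- matches + tcrossprod(B)
  }
  idm <- ifelse(both > 0, matches / both, 0)
  nb <- rowSums(idm >= identity)
  1 / nb
}

#' Effective number of sequences (M_eff)
#'
#' M_eff = sum over rows of 1 / |{t : identity(s, t) >= threshold}|, the
#' row itself included.  The reporting convention uses a 70% identity
#' threshold.
#'
#' @param msa an MSAProfile.
#' @param identity identity threshold (default 0.70).
#' @return numeric scalar in [1, number of rows].
#' @export
computeMeff <- function(msa, identity = 0.70) {
  sum(sequenceWeights(msa, identity = identity))
}

#' Position-specific scoring matrix (weighted frequency profile)
#'
#' Sequence-weighted amino-acid frequencies per column with a pseudocount
#' per symbol; gaps are excluded from the denominator.  Rows sum to 1.
#' All-gap columns give a uniform row with a warning.
#'
#' @param msa an MSAProfile.
#' @param pseudocount pseudocount added per amino-acid symbol (default 1).
#' @param weights per-row weights; default \code{sequenceWeights(msa)}.
#'   Use \code{rep(1, nSequences(msa))} for unweighted counts.
#' @return numeric L x 20 matrix, columns in the package amino-acid order.
#' @export
computePssm <- function(msa, pseudocount = 1,
                        weights = sequenceWeights(msa)) {
  X <- .msaInt(msa)
  L <- ncol(X)
  counts <- matrix(0, L, 20L)
  for (s in 1:20)
    counts[, s] <- colSums(weights * (X == s))
  tot <- rowSums(counts)
  if (any(tot == 0))
    warning("all-gap column(s) ", paste(which(tot == 0), collapse = ","),
            ": uniform profile row")
  p <- (counts + pseudocount) / (tot + 20 * pseudocount)
  allGap <- tot == 0 & pseudocount == 0
  if (any(allGap)) p[allGap, ] <- 1 / 20
  colnames(p) <- AA1
  p
}

#' Average per-column entropy of an MSA
#'
#' H = -(1/N) * sum_i sum_j p_i^j log(p_i^j) with natural logarithm,
#' 0 log 0 := 0, where p_i^j is the observed (unweighted) frequency of
#' amino acid j at column i among non-gap symbols and N is the number of
#' columns.
#'
#' @param msa an MSAProfile.
#' @return numeric scalar >= 0.
#' @export
averageEntropy <- function(msa) {
  X <- .msaInt(msa)
  L <- ncol(X)
  H <- 0
  for (i in seq_len(L)) {
    col <- X[, i]
    col <- col[col != 21L]
    if (length(col) == 0L) next
    p <- tabulate(col, nbins = 20L) / length(col)
    p <- p[p > 0]
    H <- H - sum(p * log(p))
  }
  H / L
}
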