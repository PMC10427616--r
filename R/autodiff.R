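## Minimal reverse-mode automatic differentiation over numeric arrays.
##
## The network layers are compositions of a small set of array operations;
## each operation records itself on a global tape with a closure computing
## vector-Jacobian products.  adBackward() replays the tape in reverse.
## Everything is BLAS-backed base R; gradients are verified against
## numerical differentiation in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$tape <- vector("list", 256L)
.ad$n <- 0L

adReset <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  invisible(NULL)
}

adIsNode <- function(x) inherits(x, "adNode")

# leaf node: parameter or constant input; not on the tape
adLeaf <- function(value) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$leaf <- TRUE
  class(nd) <- "adNode"
  nd
}

asNode <- function(x) if (adIsNode(x)) x else adLeaf(x)

adValue <- function(x) if (adIsNode(x)) x$value else x

# interior node recorded on the tape; bw(g) returns a list of gradients
# aligned with `parents` (NULL entries allowed)
adOp <- function(value, parents, bw) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$leaf <- FALSE
  nd$parents <- parents
  nd$bw <- bw
  class(nd) <- "adNode"
  n <- .ad$n + 1L
  if (n > length(.ad$tape))
    .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  .ad$tape[[n]] <- nd
  .ad$n <- n
  nd
}

adZeroGrads <- function(nodes) {
  for (nd in nodes) nd$grad <- NULL
  invisible(NULL)
}

adBackward <- function(loss) {
  stopifnot(adIsNode(loss), !loss$leaf)
  loss$grad <- if (length(loss$value) == 1L) 1 else
    array(1, dim = dim(loss$value))
  for (k in .ad$n:1L) {
    nd <- .ad$tape[[k]]
    if (is.null(nd) || is.null(nd$grad)) next
    gs <- nd$bw(nd$grad)
    ps <- nd$parents
    for (i in seq_along(ps)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- ps[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

## ---- elementwise ----

adAdd <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  adOp(a$value + b$value, list(a, b), function(g) list(g, g))
}

adMul <- function(a, b) {
  a <- asNode(a); b <- asNode(b)
  av <- a$value; bv <- b$value
  adOp(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

# multiply / add by a constant (no gradient to the constant)
adScale <- function(a, s) {
  a <- asNode(a)
  adOp(a$value * s, list(a), function(g) list(g * s))
}

adMulConst <- function(a, K) {
  a <- asNode(a)
  adOp(a$value * K, list(a), function(g) list(g * K))
}

adSigmoid <- function(a) {
  a <- asNode(a)
  y <- 1 / (1 + exp(-a$value))
  adOp(y, list(a), function(g) list(g * y * (1 - y)))
}

adElu <- function(a, alpha = 1) {
  a <- asNode(a)
  v <- a$value
  neg <- v <= 0
  y <- v
  y[neg] <- alpha * (exp(v[neg]) - 1)
  adOp(y, list(a), function(g) {
    d <- g
    d[neg] <- g[neg] * (y[neg] + alpha)
    list(d)
  })
}

adDropout <- function(a, rate, train = FALSE) {
  if (!train || rate <= 0) return(a)
  a <- asNode(a)
  keep <- (stats::runif(length(a$value)) >= rate) / (1 - rate)
  dim(keep) <- dim(a$value)
  adMulConst(a, keep)
}

## ---- shape ----

adReshape <- function(a, newdim) {
  a <- asNode(a)
  olddim <- dim(a$value) %||% length(a$value)
  v <- a$value
  dim(v) <- newdim
  adOp(v, list(a), function(g) { dim(g) <- olddim; list(g) })
}

# swap the first two dimensions of a matrix or 3D array
adTranspose12 <- function(a) {
  a <- asNode(a)
  v <- a$value
  if (is.matrix(v)) {
    adOp(t(v), list(a), function(g) list(t(g)))
  } else {
    adOp(aperm(v, c(2L, 1L, 3L)), list(a),
         function(g) list(aperm(g, c(2L, 1L, 3L))))
  }
}

adConcatLast <- function(parts) {
  parts <- lapply(parts, asNode)
  d <- dim(parts[[1L]]$value)
  nd <- length(d)
  widths <- vapply(parts, function(p) dim(p$value)[nd], integer(1))
  lead <- prod(d[-nd])
  mats <- lapply(parts, function(p) { v <- p$value; dim(v) <- c(lead, length(v) %/% lead); v })
  v <- do.call(cbind, mats)
  dim(v) <- c(d[-nd], sum(widths))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  adOp(v, parts, function(g) {
    gm <- g
    dim(gm) <- c(lead, length(g) %/% lead)
    lapply(seq_along(parts), function(i) {
      gi <- gm[, starts[i]:ends[i], drop = FALSE]
      dim(gi) <- c(d[-nd], widths[i])
      gi
    })
  })
}

adSumAll <- function(a) {
  a <- asNode(a)
  d <- dim(a$value) %||% length(a$value)
  adOp(sum(a$value), list(a), function(g) list(array(g, dim = d)))
}

## ---- linear algebra ----

# position-wise linear map over the last dimension: y[..., ] = x[..., ] W + b
adLinear <- function(x, W, b = NULL) {
  x <- asNode(x); W <- asNode(W)
  xd <- dim(x$value)
  cin <- xd[length(xd)]
  lead <- prod(xd[-length(xd)])
  Xm <- x$value
  dim(Xm) <- c(lead, cin)
  Y <- Xm %*% W$value
  if (!is.null(b)) {
    b <- asNode(b)
    Y <- Y + rep(b$value, each = lead)
  }
  cout <- ncol(Y)
  dim(Y) <- c(xd[-length(xd)], cout)
  parents <- if (is.null(b)) list(x, W) else list(x, W, b)
  adOp(Y, parents, function(g) {
    Gm <- g
    dim(Gm) <- c(lead, cout)
    dX <- tcrossprod(Gm, W$value)
    dim(dX) <- xd
    out <- list(dX, crossprod(Xm, Gm))
    if (!is.null(b)) out <- c(out, list(colSums(Gm)))
    out
  })
}

# per-channel matrix multiply: out[,,c] = A[,,c] %*% B[,,c]
adChanMatmul <- function(A, B) {
  A <- asNode(A); B <- asNode(B)
  Av <- A$value; Bv <- B$value
  da <- dim(Av); db <- dim(Bv)
  stopifnot(length(da) == 3L, length(db) == 3L, da[2L] == db[1L],
            da[3L] == db[3L])
  C <- da[3L]
  out <- array(0, dim = c(da[1L], db[2L], C))
  for (c in seq_len(C)) out[, , c] <- Av[, , c] %*% Bv[, , c]
  adOp(out, list(A, B), function(g) {
    dA <- array(0, dim = da); dB <- array(0, dim = db)
    for (c in seq_len(C)) {
      dA[, , c] <- tcrossprod(g[, , c], Bv[, , c])
      dB[, , c] <- crossprod(Av[, , c], g[, , c])
    }
    list(dA, dB)
  })
}

# batched matmul over the first dimension:
# out[b,,] = A[b,,] %*% B[b,,]   (t(B[b,,]) when transposeB)
adBmm <- function(A, B, transposeB = FALSE) {
  A <- asNode(A); B <- asNode(B)
  da <- dim(A$value); db <- dim(B$value)
  stopifnot(length(da) == 3L, length(db) == 3L, da[1L] == db[1L])
  nb <- da[1L]
  m <- if (transposeB) db[2L] else db[3L]
  # batch-last copies make every slice contiguous
  Av <- aperm(A$value, c(2L, 3L, 1L))
  Bv <- aperm(B$value, c(2L, 3L, 1L))
  out <- array(0, dim = c(da[2L], m, nb))
  for (b in seq_len(nb)) {
    Ab <- Av[, , b]; Bb <- Bv[, , b]
    out[, , b] <- if (transposeB) tcrossprod(Ab, Bb) else Ab %*% Bb
  }
  val <- aperm(out, c(3L, 1L, 2L))
  adOp(val, list(A, B), function(g) {
    gp <- aperm(g, c(2L, 3L, 1L))
    dA <- array(0, dim = c(da[2L], da[3L], nb))
    dB <- array(0, dim = c(db[2L], db[3L], nb))
    for (b in seq_len(nb)) {
      Gb <- gp[, , b]; Ab <- Av[, , b]; Bb <- Bv[, , b]
      if (transposeB) {
        dA[, , b] <- Gb %*% Bb
        dB[, , b] <- crossprod(Gb, Ab)
      } else {
        dA[, , b] <- tcrossprod(Gb, Bb)
        dB[, , b] <- crossprod(Ab, Gb)
      }
    }
    list(aperm(dA, c(3L, 1L, 2L)), aperm(dB, c(3L, 1L, 2L)))
  })
}

## ---- normalization ----

# layer normalization over the last dimension with learned scale/shift
adLayerNorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- asNode(x); gamma <- asNode(gamma); beta <- asNode(beta)
  xd <- dim(x$value)
  C <- xd[length(xd)]
  lead <- prod(xd[-length(xd)])
  Xm <- x$value
  dim(Xm) <- c(lead, C)
  mu <- rowMeans(Xm)
  xc <- Xm - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  Y <- xhat * rep(gamma$value, each = lead) + rep(beta$value, each = lead)
  dim(Y) <- xd
  adOp(Y, list(x, gamma, beta), function(g) {
    Gm <- g
    dim(Gm) <- c(lead, C)
    dxhat <- Gm * rep(gamma$value, each = lead)
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dX <- inv * (dxhat - m1 - xhat * m2)
    dim(dX) <- xd
    list(dX, colSums(Gm * xhat), colSums(Gm))
  })
}

# instance normalization: normalize each channel over the two spatial dims
adInstanceNorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- asNode(x); gamma <- asNode(gamma); beta <- asNode(beta)
  xd <- dim(x$value)
  stopifnot(length(xd) == 3L)
  n <- xd[1L] * xd[2L]; C <- xd[3L]
  Xm <- x$value
  dim(Xm) <- c(n, C)
  mu <- colMeans(Xm)
  xc <- sweep(Xm, 2L, mu)
  va <- colMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv, "*")
  Y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  dim(Y) <- xd
  adOp(Y, list(x, gamma, beta), function(g) {
    Gm <- g
    dim(Gm) <- c(n, C)
    dxhat <- sweep(Gm, 2L, gamma$value, "*")
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dX <- sweep(sweep(dxhat, 2L, m1, "-") - sweep(xhat, 2L, m2, "*"),
                2L, inv, "*")
    dim(dX) <- xd
    list(dX, colSums(Gm * xhat), colSums(Gm))
  })
}

## ---- convolution ----

# cached gather/scatter indices for same-padded im2col
.convIdxCache <- new.env(parent = emptyenv())
.convIdx <- function(L1, L2, k) {
  key <- paste(L1, L2, k, sep = "x")
  v <- .convIdxCache[[key]]
  if (!is.null(v)) return(v)
  P <- (k - 1L) %/% 2L
  W1 <- L1 + 2L * P
  W2 <- L2 + 2L * P
  i <- rep(seq_len(L1), L2)
  j <- rep(seq_len(L2), each = L1)
  ridx <- matrix(0L, L1 * L2, k * k)
  blk <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    blk <- blk + 1L
    ridx[, blk] <- (i + di - 1L) + (j + dj - 2L) * W1
  }
  rv <- as.vector(ridx)
  v <- list(ridx = rv, uidx = sort(unique(rv)),
            cidx = (i + P) + (j + P - 1L) * W1, W1 = W1, W2 = W2)
  .convIdxCache[[key]] <- v
  v
}

# same-padded 2D convolution via im2col; W is a (k*k*Cin) x Cout matrix
# whose row r = o + (c-1)*k^2 pairs kernel offset o with input channel c.
# The unfolded input is cached on the input node so parallel branches with
# equal kernel size share the gather.
adConv2d <- function(x, W, b, k) {
  x <- asNode(x); W <- asNode(W); b <- asNode(b)
  xd <- dim(x$value)
  L1 <- xd[1L]; L2 <- xd[2L]; Cin <- xd[3L]
  n <- L1 * L2
  if (k == 1L) {
    Xcol <- x$value
    dim(Xcol) <- c(n, Cin)
    ci <- NULL
  } else {
    ci <- .convIdx(L1, L2, k)
    key <- paste0(".im2col", k)
    Xcol <- x[[key]]
    if (is.null(Xcol)) {
      xm <- x$value
      dim(xm) <- c(n, Cin)
      pad <- matrix(0, ci$W1 * ci$W2, Cin)
      pad[ci$cidx, ] <- xm
      Xcol <- pad[ci$ridx, , drop = FALSE]     # (k^2 n, Cin), offset-major
      dim(Xcol) <- c(n, k * k * Cin)
      x[[key]] <- Xcol
    }
  }
  Y <- Xcol %*% W$value + rep(b$value, each = n)
  Cout <- ncol(Y)
  dim(Y) <- c(L1, L2, Cout)
  adOp(Y, list(x, W, b), function(g) {
    Gm <- g
    dim(Gm) <- c(n, Cout)
    dW <- crossprod(Xcol, Gm)
    db <- colSums(Gm)
    dXcol <- tcrossprod(Gm, W$value)
    if (k == 1L) {
      dX <- dXcol
      dim(dX) <- xd
    } else {
      dim(dXcol) <- c(n * k * k, Cin)
      acc <- rowsum(dXcol, ci$ridx, reorder = TRUE)
      dpad <- matrix(0, ci$W1 * ci$W2, Cin)
      dpad[ci$uidx, ] <- acc
      dX <- dpad[ci$cidx, , drop = FALSE]
      dim(dX) <- xd
    }
    list(dX, dW, db)
  })
}

## ---- attention softmax ----

# softmax over the last dimension with a keep-mask on that dimension.
# Masked entries get weight exactly 0; if every entry of a row is masked
# the whole row is 0 (no renormalization), so downstream attention output
# vanishes and the residual path carries the signal.
adMaskedSoftmax <- function(x, keep = NULL) {
  x <- asNode(x)
  xd <- dim(x$value)
  C <- xd[length(xd)]
  lead <- prod(xd[-length(xd)])
  Xm <- x$value
  dim(Xm) <- c(lead, C)
  if (!is.null(keep)) {
    stopifnot(length(keep) == C)
    if (!any(keep)) {
      Y <- matrix(0, lead, C)
      dim(Y) <- xd
      return(adOp(Y, list(x), function(g) list(array(0, dim = xd))))
    }
    Xm[, !keep] <- -Inf
  }
  mx <- Xm[cbind(seq_len(lead), max.col(Xm, ties.method = "first"))]
  E <- exp(Xm - mx)
  E[is.na(E)] <- 0                       # rows that were all -Inf
  s <- rowSums(E)
  s[s == 0] <- 1
  Ym <- E / s
  Y <- Ym
  dim(Y) <- xd
  adOp(Y, list(x), function(g) {
    Gm <- g
    dim(Gm) <- c(lead, C)
    inner <- rowSums(Gm * Ym)
    dX <- Ym * (Gm - inner)
    dim(dX) <- xd
    list(dX)
  })
}

## ---- loss ----

# focal loss on probabilities: mean over entries of -alpha (1-p_t)^gamma log p_t
# with p_t = p for positives, 1-p for negatives; p clamped to [eps, 1-eps].
adFocalLossP <- function(p, truth, gamma = 2, alpha = 0.25, eps = 1e-7) {
  p <- asNode(p)
  y <- as.numeric(truth)
  pv <- as.numeric(p$value)
  n <- length(pv)
  stopifnot(length(y) == n)
  pc <- pmin(pmax(pv, eps), 1 - eps)
  pt <- ifelse(y > 0.5, pc, 1 - pc)
  term <- -alpha * (1 - pt)^gamma * log(pt)
  val <- sum(term) / n
  xd <- dim(p$value)
  adOp(val, list(p), function(g) {
    # d term / d pt, then chain through pt = p or 1-p and the clamp
    dpt <- -alpha * (-gamma * (1 - pt)^(gamma - 1) * log(pt) + (1 - pt)^gamma / pt)
    dp <- dpt * ifelse(y > 0.5, 1, -1)
    dp[pv < eps | pv > 1 - eps] <- 0     # clamped: zero gradient
    dp <- g * dp / n
    dim(dp) <- xd
    list(dp)
  })
}
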