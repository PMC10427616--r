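# Reference (explicit-loop) implementations of the network layers used as
# oracles in multiple test files.

refLinA <- function(x, W, b = NULL) {
  d <- dim(x)
  m <- matrix(x, ncol = d[length(d)]) %*% W
  if (!is.null(b)) m <- sweep(m, 2L, b, "+")
  dim(m) <- c(d[-length(d)], ncol(W))
  m
}

refLayerNormA <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- matrix(x, ncol = d[length(d)])
  out <- t(apply(m, 1L, function(r) {
    mu <- mean(r); v <- mean((r - mu)^2)
    (r - mu) / sqrt(v + eps) * gamma + beta
  }))
  dim(out) <- d
  out
}

refGatedProjA <- function(x, p, pre) {
  g <- 1 / (1 + exp(-refLinA(x, p[[paste0(pre, "_g_W")]],
                             p[[paste0(pre, "_g_b")]])))
  refLinA(g, p[[paste0(pre, "_W")]], p[[paste0(pre, "_b")]])
}

# multi-head row attention with distance gating and key masking
refRowAttentionA <- function(z, dmap, keep, p, nHeads, lambda = 8) {
  dz <- dim(z); L1 <- dz[1]; L2 <- dz[2]; d <- dz[3]
  dh <- d %/% nHeads
  g <- exp(-dmap^2 / (2 * lambda^2))
  att <- array(0, c(L1, L2, d))
  for (h in seq_len(nHeads)) {
    q <- refLinA(z, p[[sprintf("tri1_row_q%d_W", h)]])
    k <- refLinA(z, p[[sprintf("tri1_row_k%d_W", h)]])
    v <- refLinA(z, p[[sprintf("tri1_row_v%d_W", h)]])
    for (i in 1:L1) for (j in 1:L2) {
      logit <- vapply(1:L2, function(m)
        sum(q[i, j, ] * k[i, m, ]) / sqrt(dh), numeric(1))
      logit[!keep] <- -Inf
      e <- exp(logit - max(logit[keep]))
      e[!keep] <- 0
      w <- e / sum(e)
      w <- w * g[j, ]
      for (m in 1:L2)
        att[i, j, ((h - 1) * dh + 1):(h * dh)] <-
          att[i, j, ((h - 1) * dh + 1):(h * dh)] + w[m] * v[i, m, ]
    }
  }
  gate <- 1 / (1 + exp(-refLinA(z, p$tri1_row_gate_W, p$tri1_row_gate_b)))
  out <- refLinA(refLayerNormA(att * gate, p$tri1_row_ln_gamma,
                               p$tri1_row_ln_beta),
                 p$tri1_row_out_W, p$tri1_row_out_b)
  z + out
}
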