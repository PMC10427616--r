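# Explicit-loop oracles for the triangle-aware layers, evaluated on small
# seeded tensors, plus the structural contracts of the network.

test_that("triangle update matches a naive triple-loop oracle", {
  set.seed(21)
  L1 <- 3L; L2 <- 4L; d <- 4L
  z <- array(rnorm(L1 * L2 * d), c(L1, L2, d))
  r <- array(rnorm(L1 * L1 * d), c(L1, L1, d))
  l <- array(rnorm(L2 * L2 * d), c(L2, L2, d))
  p <- makeTriangleUpdateParams(d, seed = 22)
  out <- triangleUpdate(z, r, l, p)
  expect_equal(dim(out), c(L1, L2, d))
  zp <- refGatedProjA(z, p, "tri1_up_zp")
  zpp <- refGatedProjA(z, p, "tri1_up_zpp")
  rp <- refGatedProjA(r, p, "tri1_up_r")
  lp <- refGatedProjA(l, p, "tri1_up_l")
  s <- array(0, c(L1, L2, d))
  for (i in 1:L1) for (j in 1:L2) for (c in 1:d)
    s[i, j, c] <- sum(rp[i, , c] * zp[, j, c]) +
      sum(zpp[i, , c] * lp[, j, c])
  phi <- refLinA(refLayerNormA(s, p$tri1_up_ln_gamma, p$tri1_up_ln_beta),
                p$tri1_up_out_W, p$tri1_up_out_b)
  gate <- plogis(refLinA(z, p$tri1_up_gate_W, p$tri1_up_gate_b))
  expect_equal(out, z + phi * gate, tolerance = 1e-6)
})

test_that("triangle update masks drop buried residues from the sums", {
  set.seed(23)
  L <- 4L; d <- 4L
  z <- array(rnorm(L * L * d), c(L, L, d))
  r <- array(rnorm(L * L * d), c(L, L, d))
  l <- array(rnorm(L * L * d), c(L, L, d))
  p <- makeTriangleUpdateParams(d, seed = 24)
  mask <- c(TRUE, TRUE, FALSE, TRUE)
  out <- triangleUpdate(z, r, l, p, maskReceptor = mask, maskLigand = mask)
  # oracle: zero the corresponding rows/columns of the projections
  zp <- refGatedProjA(z, p, "tri1_up_zp")
  zpp <- refGatedProjA(z, p, "tri1_up_zpp")
  rp <- refGatedProjA(r, p, "tri1_up_r")
  lp <- refGatedProjA(l, p, "tri1_up_l")
  s <- array(0, c(L, L, d))
  for (i in 1:L) for (j in 1:L) for (c in 1:d)
    s[i, j, c] <- sum((rp[i, , c] * mask) * zp[, j, c]) +
      sum(zpp[i, , c] * (lp[, j, c] * mask))
  phi <- refLinA(refLayerNormA(s, p$tri1_up_ln_gamma, p$tri1_up_ln_beta),
                p$tri1_up_out_W, p$tri1_up_out_b)
  gate <- plogis(refLinA(z, p$tri1_up_gate_W, p$tri1_up_gate_b))
  expect_equal(out, z + phi * gate, tolerance = 1e-6)
})

test_that("zeroing the triangle-update output projection gives identity", {
  set.seed(25)
  L <- 3L; d <- 4L
  z <- array(rnorm(L * L * d), c(L, L, d))
  p <- makeTriangleUpdateParams(d, seed = 26)
  p$tri1_up_out_W[] <- 0
  p$tri1_up_out_b[] <- 0
  out <- triangleUpdate(z, z, z, p)
  expect_equal(out, z)
})

test_that("row triangle attention matches the explicit-loop oracle", {
  set.seed(31)
  L <- 5L; d <- 8L; H <- 4L
  z <- array(rnorm(L * L * d), c(L, L, d))
  dmap <- as.matrix(dist(matrix(rnorm(L * 3, sd = 6), L)))
  keep <- c(TRUE, TRUE, FALSE, TRUE, TRUE)
  p <- makeTriangleAttentionParams(d, nHeads = H, seed = 32)
  out <- triangleAttention(z, dmap, keep, axis = "row", p, nHeads = H)
  expect_equal(out, refRowAttentionA(z, dmap, keep, p, H), tolerance = 1e-5)
})

test_that("column triangle attention transposes the row roles", {
  set.seed(33)
  L <- 5L; d <- 8L; H <- 2L
  z <- array(rnorm(L * L * d), c(L, L, d))
  dmap <- as.matrix(dist(matrix(rnorm(L * 3, sd = 6), L)))
  keep <- rep(TRUE, L)
  p <- makeTriangleAttentionParams(d, nHeads = H, seed = 34)
  out <- triangleAttention(z, dmap, keep, axis = "column", p, nHeads = H)
  zt <- aperm(z, c(2, 1, 3))
  ref <- aperm(refRowAttentionA(zt, dmap, keep, p, H), c(2, 1, 3))
  expect_equal(out, ref, tolerance = 1e-5)
})

test_that("the distance gate has its closed-form values at 0 and 8 A", {
  g <- tmcontact:::.gaussGate(matrix(c(0, 8, Inf, 16), 2, 2), lambda = 8)
  expect_equal(g[1, 1], 1)
  expect_equal(g[2, 1], exp(-0.5))
  expect_equal(g[1, 2], 0)           # infinite (flagged) distance
  expect_equal(g[2, 2], exp(-2))
})

test_that("pre-gating softmax weights sum to 1 over unmasked keys", {
  set.seed(35)
  L <- 6L
  x <- array(rnorm(L * L * L), c(L, L, L))
  keep <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  tmcontact:::adReset()
  soft <- tmcontact:::adValue(
    tmcontact:::adMaskedSoftmax(tmcontact:::adLeaf(x), keep = keep))
  tmcontact:::adReset()
  sums <- apply(soft, c(1, 2), sum)
  expect_equal(unname(as.vector(sums)), rep(1, L * L), tolerance = 1e-12)
  expect_true(all(soft[, , !keep] == 0))
})

test_that("attention with every key masked returns the residual input", {
  set.seed(36)
  L <- 4L; d <- 4L
  z <- array(rnorm(L * L * d), c(L, L, d))
  dmap <- as.matrix(dist(matrix(rnorm(L * 3), L)))
  p <- makeTriangleAttentionParams(d, nHeads = 2L, seed = 37)
  # zero attention output feeds phi(0-gated) through LN + linear; with the
  # output projection zeroed the update vanishes and z is preserved
  p$tri1_row_out_W[] <- 0
  p$tri1_row_out_b[] <- 0
  out <- triangleAttention(z, dmap, rep(FALSE, L), axis = "row", p,
                           nHeads = 2L)
  expect_equal(out, z)
})

test_that("masking an already-buried residue changes nothing", {
  set.seed(38)
  L <- 6L; d <- 8L
  z <- array(rnorm(L * L * d), c(L, L, d))
  dmap <- as.matrix(dist(matrix(rnorm(L * 3, sd = 5), L)))
  p <- makeTriangleAttentionParams(d, nHeads = 2L, seed = 39)
  keep1 <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  out1 <- triangleAttention(z, dmap, keep1, axis = "row", p, nHeads = 2L)
  out2 <- triangleAttention(z, dmap, keep1 & keep1, axis = "row", p,
                            nHeads = 2L)
  expect_identical(out1, out2)
})

test_that("transition layer matches per-position matrix algebra and is the
           identity when its second layer is zeroed", {
  set.seed(41)
  L <- 4L; d <- 8L
  z <- array(rnorm(L * L * d), c(L, L, d))
  p <- makeTransitionParams(d, seed = 42)
  out <- transitionLayer(z, p)
  h <- refLinA(z, p$tri1_trans1_W, p$tri1_trans1_b)
  h <- ifelse(h > 0, h, exp(h) - 1)          # ELU
  ref <- z + refLinA(h, p$tri1_trans2_W, p$tri1_trans2_b)
  expect_equal(out, ref, tolerance = 1e-6)
  p$tri1_trans2_W[] <- 0; p$tri1_trans2_b[] <- 0
  expect_equal(transitionLayer(z, p), z)
})

test_that("ResNet-Inception block preserves shape and matches its
           branch-by-branch composition", {
  set.seed(43)
  L <- 7L; d <- 8L
  x <- array(rnorm(L * L * d), c(L, L, d))
  p <- makeInceptionParams(d, seed = 44)
  out <- resnetInceptionForward(x, p)
  expect_equal(dim(out), c(L, L, d))
  # branch-by-branch oracle through the same conv primitive
  convRef <- function(x, W, b, k) {
    tmcontact:::adReset()
    v <- tmcontact:::adValue(tmcontact:::adConv2d(
      tmcontact:::adLeaf(x), tmcontact:::adLeaf(W),
      tmcontact:::adLeaf(b), k))
    tmcontact:::adReset()
    v
  }
  elu <- function(v) ifelse(v > 0, v, exp(v) - 1)
  b1 <- elu(convRef(x, p$rec_inc1_b1_W, p$rec_inc1_b1_b, 1L))
  b2 <- elu(convRef(x, p$rec_inc1_b2_W, p$rec_inc1_b2_b, 3L))
  h <- elu(convRef(x, p$rec_inc1_b3a_W, p$rec_inc1_b3a_b, 3L))
  b3 <- elu(convRef(h, p$rec_inc1_b3b_W, p$rec_inc1_b3b_b, 3L))
  cat3 <- array(c(b1, b2, b3), c(L, L, d))
  f <- convRef(cat3, p$rec_inc1_fuse_W, p$rec_inc1_fuse_b, 1L)
  fm <- matrix(f, ncol = d)
  mu <- colMeans(fm); va <- colMeans(sweep(fm, 2, mu)^2)
  fn <- sweep(sweep(fm, 2, mu), 2, sqrt(va + 1e-5), "/")
  fn <- sweep(sweep(fn, 2, p$rec_inc1_norm_gamma, "*"), 2,
              p$rec_inc1_norm_beta, "+")
  dim(fn) <- c(L, L, d)
  expect_equal(out, x + fn, tolerance = 1e-6)
  expect_error(resnetInceptionForward(array(0, c(L, L, d + 4L)), p),
               "channel count")
})

test_that("a 3x3 convolution against a hand-rolled sliding-window oracle", {
  set.seed(45)
  L1 <- 5L; L2 <- 6L; cin <- 3L; cout <- 2L; k <- 3L
  x <- array(rnorm(L1 * L2 * cin), c(L1, L2, cin))
  W <- matrix(rnorm(k * k * cin * cout), k * k * cin, cout)
  b <- rnorm(cout)
  tmcontact:::adReset()
  out <- tmcontact:::adValue(tmcontact:::adConv2d(
    tmcontact:::adLeaf(x), tmcontact:::adLeaf(W), tmcontact:::adLeaf(b), k))
  tmcontact:::adReset()
  # W row r = o + (c-1)k^2; offset o enumerates (di, dj) column-major
  ref <- array(0, c(L1, L2, cout))
  for (i in 1:L1) for (j in 1:L2) for (co in 1:cout) {
    acc <- b[co]
    o <- 0L
    for (dj in 1:k) for (di in 1:k) {
      o <- o + 1L
      ii <- i + di - 2L; jj <- j + dj - 2L
      if (ii >= 1 && ii <= L1 && jj >= 1 && jj <= L2)
        for (c in 1:cin)
          acc <- acc + x[ii, jj, c] * W[o + (c - 1L) * k * k, co]
    }
    ref[i, j, co] <- acc
  }
  expect_equal(out, ref, tolerance = 1e-10)
})

test_that("contact head squashes, symmetrizes and bounds probabilities", {
  set.seed(46)
  L <- 6L; d <- 8L
  z <- array(rnorm(L * L * d), c(L, L, d))
  # all-zero projection puts every logit at 0, hence probability 0.5
  pred0 <- contactHead(z, W = matrix(0, d, 1), b = 0)
  expect_true(all(pred0@probs == 0.5))
  W <- matrix(rnorm(d), d, 1)
  pred <- contactHead(z, W, b = -1)
  expect_true(all(pred@probs >= 0 & pred@probs <= 1))
  expect_equal(max(abs(pred@probs - t(pred@probs))), 0)
  expect_true(pred@symmetrized)
  asym <- contactHead(z, W, b = -1, symmetrize = FALSE)
  expect_equal(pred@probs, (asym@probs + t(asym@probs)) / 2)
})

test_that("focal loss reduces to binary cross-entropy at gamma 0, alpha 1
           and matches a hand-computed 2x2 case", {
  set.seed(47)
  p <- matrix(runif(36, 0.05, 0.95), 6, 6)
  y <- matrix(runif(36) < 0.3, 6, 6)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focalLoss(p, y, gamma = 0, alpha = 1), bce,
               tolerance = 1e-10)
  # hand evaluation, gamma = 2, alpha = 0.25
  p2 <- matrix(c(0.9, 0.2, 0.2, 0.6), 2, 2)
  y2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  hand <- mean(c(-0.25 * (1 - 0.9)^2 * log(0.9),
                 -0.25 * (1 - 0.8)^2 * log(0.8),
                 -0.25 * (1 - 0.8)^2 * log(0.8),
                 -0.25 * (1 - 0.6)^2 * log(0.6)))
  expect_equal(focalLoss(p2, y2, gamma = 2, alpha = 0.25), hand,
               tolerance = 1e-12)
  # perfect prediction after clamping stays at the alpha * eps-order floor
  expect_lt(focalLoss(matrix(1, 2, 2), matrix(TRUE, 2, 2), gamma = 0,
                      alpha = 1), 1e-6)
  expect_error(focalLoss(p, y[1:3, 1:3]), "shape mismatch")
})

test_that("full forward yields a deterministic symmetric probability map of
           the right size", {
  tg <- fxTarget()
  m <- newContactModel(dim(tg@bundle@receptor)[3], dim(tg@bundle@complex)[3],
                       config = list(d = 8, nTriangle = 1, nHeads = 2),
                       seed = 51)
  pred <- predictContacts(m, tg@bundle, tg@dmap, tg@surface)
  expect_equal(dim(pred@probs), c(32L, 32L))
  expect_true(all(pred@probs >= 0 & pred@probs <= 1))
  expect_equal(max(abs(pred@probs - t(pred@probs))), 0)
  pred2 <- predictContacts(m, tg@bundle, tg@dmap, tg@surface)
  expect_identical(pred@probs, pred2@probs)
})

test_that("homodimer predictions are invariant to swapping the receptor and
           ligand inputs", {
  tg <- fxTarget()
  m <- newContactModel(dim(tg@bundle@receptor)[3], dim(tg@bundle@complex)[3],
                       config = list(d = 8, nTriangle = 1, nHeads = 2),
                       seed = 52)
  b <- tg@bundle
  swapped <- new("FeatureBundle", receptor = b@ligand, ligand = b@receptor,
                 complex = b@complex, manifestReceptor = b@manifestReceptor,
                 manifestComplex = b@manifestComplex, L = b@L)
  p1 <- predictContacts(m, b, tg@dmap, tg@surface)
  p2 <- predictContacts(m, swapped, tg@dmap, tg@surface)
  expect_identical(p1@probs, p2@probs)
})

test_that("gradients reach every parameter group", {
  tg <- fxTarget()
  m <- newContactModel(dim(tg@bundle@receptor)[3], dim(tg@bundle@complex)[3],
                       config = list(d = 8, nTriangle = 1, nHeads = 2,
                                     dropout = 0),
                       seed = 53)
  fw <- tmcontact:::.forwardNodes(m, tg@bundle, tg@dmap, tg@surface,
                                  train = FALSE)
  loss <- tmcontact:::adFocalLossP(fw$probs, tg@truth@union)
  tmcontact:::adBackward(loss)
  gnorm <- vapply(fw$PN, function(nd)
    if (is.null(nd$grad)) 0 else sqrt(sum(nd$grad^2)), numeric(1))
  tmcontact:::adReset()
  expect_true(all(gnorm > 0),
              info = paste("dead:", paste(names(gnorm)[gnorm == 0],
                                          collapse = ",")))
})

test_that("model checkpoints round-trip", {
  m <- newContactModel(10, 6, config = list(d = 8, nTriangle = 1,
                                            nHeads = 2), seed = 54)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(m2@params, m@params)
  expect_identical(m2@config, m@config)
  expect_equal(frozenParameterCount(m2), 0L)
  notCk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), notCk)
  expect_error(loadModel(notCk), "checkpoint")
})
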