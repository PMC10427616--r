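## The triangle-aware contact prediction network.
##
## Layer math follows the pair-representation formulation: a stack of
## ResNet-Inception blocks per input tensor, then k triangle-aware blocks
## (triangle multiplicative update, row and column triangle self-attention
## with a Gaussian distance gate g(d) = exp(-d^2 / (2 lambda^2)), lambda =
## 8 A, and a two-layer transition), and a logistic contact head with
## transpose-averaging.  Buried (non-surface) residues are excluded as
## attention keys/values and from the triangle-update sums.

.defaultNetConfig <- function() {
  list(d = 64L, nInception = 4L, nTriangle = 4L, nHeads = 4L,
       dropout = 0.1, gamma = 2, alpha = 0.25, lambda = 8,
       transitionMult = 2L, headBias = -2, maskMode = "exclude_buried",
       symmetrize = TRUE)
}

#' Create a triangle-aware contact prediction model
#'
#' @param inputChannelsReceptor channel count of the receptor/ligand input
#'   tensor.
#' @param inputChannelsComplex channel count of the complex input tensor.
#' @param config named list overriding the defaults: `d` (pair channel
#'   width, default 64), `nInception` (4), `nTriangle` (4), `nHeads` (4),
#'   `dropout` (0.1), focal-loss `gamma` (2) and `alpha` (0.25), distance
#'   gate length scale `lambda` (8 Angstrom), `transitionMult` (2),
#'   `headBias` (-2).
#' @param seed RNG seed for parameter initialization.
#' @return a \linkS4class{ContactModel}.
#' @export
newContactModel <- function(inputChannelsReceptor, inputChannelsComplex,
                            config = list(), seed = 1L) {
  cfg <- utils::modifyList(.defaultNetConfig(), config)
  cfg$d <- as.integer(cfg$d)
  if (cfg$d %% 4L != 0L) stop("d must be divisible by 4")
  if (cfg$d %% cfg$nHeads != 0L) stop("head count must divide d")
  if (cfg$nTriangle < 1L || cfg$nInception < 1L) stop("block counts must be >= 1")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0,1)")
  cfg$inputChannelsReceptor <- as.integer(inputChannelsReceptor)
  cfg$inputChannelsComplex <- as.integer(inputChannelsComplex)
  P <- withSeed(seed, .initParams(cfg))
  new("ContactModel", params = P, config = cfg)
}

.initParams <- function(cfg) {
  d <- cfg$d
  P <- list()
  lin <- function(name, cin, cout, bias = TRUE, biasInit = 0, sd = NULL) {
    sd <- sd %||% sqrt(1 / cin)
    P[[paste0(name, "_W")]] <<- matrix(stats::rnorm(cin * cout, sd = sd),
                                       cin, cout)
    if (bias) P[[paste0(name, "_b")]] <<- rep(biasInit, cout)
  }
  conv <- function(name, k, cin, cout) {
    sd <- sqrt(2 / (k * k * cin))
    P[[paste0(name, "_W")]] <<- matrix(stats::rnorm(k * k * cin * cout, sd = sd),
                                       k * k * cin, cout)
    P[[paste0(name, "_b")]] <<- rep(0, cout)
  }
  norm <- function(name, c) {
    P[[paste0(name, "_gamma")]] <<- rep(1, c)
    P[[paste0(name, "_beta")]] <<- rep(0, c)
  }
  lin("proj_rec", cfg$inputChannelsReceptor, d)
  lin("proj_cplx", cfg$inputChannelsComplex, d)
  d4 <- d %/% 4L; d2 <- d %/% 2L
  for (tw in c("rec", "cplx")) for (b in seq_len(cfg$nInception)) {
    pre <- sprintf("%s_inc%d", tw, b)
    conv(paste0(pre, "_b1"), 1L, d, d4)
    conv(paste0(pre, "_b2"), 3L, d, d2)
    conv(paste0(pre, "_b3a"), 3L, d, d4)
    conv(paste0(pre, "_b3b"), 3L, d4, d4)
    conv(paste0(pre, "_fuse"), 1L, d, d)
    norm(paste0(pre, "_norm"), d)
  }
  dh <- d %/% cfg$nHeads
  for (t in seq_len(cfg$nTriangle)) {
    up <- sprintf("tri%d_up", t)
    for (path in c("zp", "zpp", "r", "l")) {
      lin(paste0(up, "_", path, "_g"), d, d)
      lin(paste0(up, "_", path), d, d)
    }
    norm(paste0(up, "_ln"), d)
    lin(paste0(up, "_out"), d, d, sd = 0.02)
    lin(paste0(up, "_gate"), d, d)
    for (ax in c("row", "col")) {
      at <- sprintf("tri%d_%s", t, ax)
      for (h in seq_len(cfg$nHeads)) {
        lin(sprintf("%s_q%d", at, h), d, dh, bias = FALSE)
        lin(sprintf("%s_k%d", at, h), d, dh, bias = FALSE)
        lin(sprintf("%s_v%d", at, h), d, dh, bias = FALSE)
      }
      lin(paste0(at, "_gate"), d, d)
      norm(paste0(at, "_ln"), d)
      lin(paste0(at, "_out"), d, d, sd = 0.02)
    }
    tr <- sprintf("tri%d_trans", t)
    lin(paste0(tr, "1"), d, d * cfg$transitionMult)
    lin(paste0(tr, "2"), d * cfg$transitionMult, d, sd = 0.02)
  }
  lin("head", d, 1L, biasInit = cfg$headBias)
  P
}

# param-node accessor factory
.pget <- function(PN) {
  function(name) {
    nd <- PN[[name]]
    if (is.null(nd)) stop("unknown parameter: ", name)
    nd
  }
}

## ---- layer node functions (operate on adNodes) ----

# gated projection Linear(sigmoid(Linear(x))) used by the triangle update
.gatedProj <- function(x, p, pre) {
  g <- adSigmoid(adLinear(x, p(paste0(pre, "_g_W")), p(paste0(pre, "_g_b"))))
  adLinear(g, p(paste0(pre, "_W")), p(paste0(pre, "_b")))
}

# output map: Linear(LayerNorm(x))
.phiOut <- function(x, p, pre) {
  h <- adLayerNorm(x, p(paste0(pre, "_ln_gamma")), p(paste0(pre, "_ln_beta")))
  adLinear(h, p(paste0(pre, "_out_W")), p(paste0(pre, "_out_b")))
}

.nodeInception <- function(x, p, pre, dropout = 0, train = FALSE) {
  b1 <- adElu(adConv2d(x, p(paste0(pre, "_b1_W")), p(paste0(pre, "_b1_b")), 1L))
  b2 <- adElu(adConv2d(x, p(paste0(pre, "_b2_W")), p(paste0(pre, "_b2_b")), 3L))
  h <- adElu(adConv2d(x, p(paste0(pre, "_b3a_W")), p(paste0(pre, "_b3a_b")), 3L))
  b3 <- adElu(adConv2d(h, p(paste0(pre, "_b3b_W")), p(paste0(pre, "_b3b_b")), 3L))
  cat <- adConcatLast(list(b1, b2, b3))
  f <- adConv2d(cat, p(paste0(pre, "_fuse_W")), p(paste0(pre, "_fuse_b")), 1L)
  f <- adInstanceNorm(f, p(paste0(pre, "_norm_gamma")), p(paste0(pre, "_norm_beta")))
  f <- adDropout(f, dropout, train)
  adAdd(x, f)
}

.nodeTriUpdate <- function(z, r, l, p, pre, maskR = NULL, maskL = NULL) {
  dz <- dim(adValue(z)); L1 <- dz[1L]; L2 <- dz[2L]; d <- dz[3L]
  zp <- .gatedProj(z, p, paste0(pre, "_zp"))
  zpp <- .gatedProj(z, p, paste0(pre, "_zpp"))
  rp <- .gatedProj(r, p, paste0(pre, "_r"))
  lp <- .gatedProj(l, p, paste0(pre, "_l"))
  if (!is.null(maskR)) {
    K <- array(matrix(as.numeric(maskR), L1, L1, byrow = TRUE), c(L1, L1, d))
    rp <- adMulConst(rp, K)      # zero columns m of r'_im for buried m
  }
  if (!is.null(maskL)) {
    K <- array(matrix(as.numeric(maskL), L2, L2), c(L2, L2, d))
    lp <- adMulConst(lp, K)      # zero rows n of l'_nj for buried n
  }
  s <- adAdd(adChanMatmul(rp, zp), adChanMatmul(zpp, lp))
  out <- .phiOut(s, p, pre)
  gate <- adSigmoid(adLinear(z, p(paste0(pre, "_gate_W")),
                             p(paste0(pre, "_gate_b"))))
  adAdd(z, adMul(out, gate))
}

# row-axis triangle self-attention; `gmat` is the Gaussian distance gate
# over the attended monomer (g[j, m] = exp(-dmap[j,m]^2 / (2 lambda^2)))
# and `keep` its surface flags.
.nodeTriAttnRow <- function(z, gmat, keep, p, pre, nHeads) {
  dz <- dim(adValue(z)); L1 <- dz[1L]; L2 <- dz[2L]; d <- dz[3L]
  dh <- d %/% nHeads
  G3 <- array(rep(as.vector(gmat), each = L1), c(L1, L2, L2))
  heads <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    q <- adLinear(z, p(sprintf("%s_q%d_W", pre, h)))
    k <- adLinear(z, p(sprintf("%s_k%d_W", pre, h)))
    v <- adLinear(z, p(sprintf("%s_v%d_W", pre, h)))
    logits <- adScale(adBmm(q, k, transposeB = TRUE), 1 / sqrt(dh))
    soft <- adMaskedSoftmax(logits, keep = keep)
    w <- adMulConst(soft, G3)
    heads[[h]] <- adBmm(w, v)
  }
  att <- if (nHeads == 1L) heads[[1L]] else adConcatLast(heads)
  gate <- adSigmoid(adLinear(z, p(paste0(pre, "_gate_W")),
                             p(paste0(pre, "_gate_b"))))
  out <- .phiOut(adMul(att, gate), p, pre)
  adAdd(z, out)
}

.nodeTransition <- function(z, p, pre, dropout = 0, train = FALSE) {
  h <- adElu(adLinear(z, p(paste0(pre, "1_W")), p(paste0(pre, "1_b"))))
  h <- adDropout(h, dropout, train)
  out <- adLinear(h, p(paste0(pre, "2_W")), p(paste0(pre, "2_b")))
  adAdd(z, out)
}

.nodeHead <- function(z, p, symmetrize = TRUE) {
  dz <- dim(adValue(z))
  logits <- adReshape(adLinear(z, p("head_W"), p("head_b")), dz[1:2])
  probs <- adSigmoid(logits)
  if (symmetrize) probs <- adScale(adAdd(probs, adTranspose12(probs)), 0.5)
  probs
}

.gaussGate <- function(dmap, lambda) {
  g <- exp(-dmap^2 / (2 * lambda^2))
  g[!is.finite(dmap)] <- 0
  g
}

## ---- full forward ----

# returns list(probs = adNode, PN = param nodes)
.forwardNodes <- function(model, bundle, dmap, surface, train = FALSE) {
  adReset()
  cfg <- model@config
  PN <- lapply(model@params, adLeaf)
  p <- .pget(PN)
  keep <- if (identical(cfg$maskMode, "none")) rep(TRUE, bundle@L) else
    as.logical(surface)
  drop <- cfg$dropout
  tower <- function(x, tw, projPre) {
    h <- adConv2d(x, p(paste0(projPre, "_W")), p(paste0(projPre, "_b")), 1L)
    for (b in seq_len(cfg$nInception))
      h <- .nodeInception(h, p, sprintf("%s_inc%d", tw, b), drop, train)
    h
  }
  ligandShared <- identical(bundle@receptor, bundle@ligand)
  r <- tower(adLeaf(bundle@receptor), "rec", "proj_rec")
  l <- if (ligandShared) r else tower(adLeaf(bundle@ligand), "rec", "proj_rec")
  z <- tower(adLeaf(bundle@complex), "cplx", "proj_cplx")
  gmat <- .gaussGate(dmap, cfg$lambda)
  for (t in seq_len(cfg$nTriangle)) {
    z <- .nodeTriUpdate(z, r, l, p, sprintf("tri%d_up", t),
                        maskR = keep, maskL = keep)
    z <- .nodeTriAttnRow(z, gmat, keep, p, sprintf("tri%d_row", t), cfg$nHeads)
    z <- adTranspose12(.nodeTriAttnRow(adTranspose12(z), gmat, keep, p,
                                       sprintf("tri%d_col", t), cfg$nHeads))
    z <- .nodeTransition(z, p, sprintf("tri%d_trans", t), drop, train)
  }
  probs <- .nodeHead(z, p, cfg$symmetrize)
  list(probs = probs, PN = PN)
}

#' Predict inter-chain contacts for one target
#'
#' Runs the network in evaluation mode (no dropout); deterministic.
#'
#' @param model a \linkS4class{ContactModel}.
#' @param bundle a \linkS4class{FeatureBundle}.
#' @param dmap intra-chain distance map of the monomer.
#' @param surface logical surface flags of the monomer (attention mask).
#' @return a \linkS4class{ContactPrediction}.
#' @export
predictContacts <- function(model, bundle, dmap, surface) {
  fw <- .forwardNodes(model, bundle, dmap, surface, train = FALSE)
  probs <- adValue(fw$probs)
  adReset()
  new("ContactPrediction", probs = probs,
      symmetrized = isTRUE(model@config$symmetrize),
      cropOffset = c(0L, 0L))
}

#' Focal loss between a predicted probability map and a contact map
#'
#' mean over residue pairs of -alpha * (1 - p_t)^gamma * log(p_t), where
#' p_t is the predicted probability of the true class and probabilities are
#' clamped to [eps, 1 - eps].  With gamma = 0, alpha = 1 this is the mean
#' binary cross-entropy.
#'
#' @param pred ContactPrediction or numeric probability matrix.
#' @param truth ContactMap or logical matrix.
#' @param gamma focusing exponent (default 2).
#' @param alpha global loss scale (default 0.25).
#' @param eps clamping constant (default 1e-7).
#' @return numeric scalar.
#' @export
focalLoss <- function(pred, truth, gamma = 2, alpha = 0.25, eps = 1e-7) {
  p <- if (methods::is(pred, "ContactPrediction")) pred@probs else pred
  y <- if (methods::is(truth, "ContactMap")) truth@union else truth
  if (!all(dim(p) == dim(y))) stop("prediction/truth shape mismatch")
  adReset()
  v <- adValue(adFocalLossP(adLeaf(p), y, gamma = gamma, alpha = alpha,
                            eps = eps))
  adReset()
  v
}

## ---- standalone layer wrappers (plain arrays in, plain arrays out) ----

#' Parameters for a standalone triangle-update layer
#' @param d channel width.
#' @param seed RNG seed.
#' @return flat named list of arrays (the layer's parameter block).
#' @export
makeTriangleUpdateParams <- function(d, seed = 1L) {
  cfg <- utils::modifyList(.defaultNetConfig(),
                           list(d = d, nInception = 1L, nTriangle = 1L,
                                nHeads = 1L, inputChannelsReceptor = d,
                                inputChannelsComplex = d))
  P <- withSeed(seed, .initParams(cfg))
  P[grep("^tri1_up_", names(P))]
}

#' Parameters for a standalone triangle self-attention layer
#' @param d channel width.
#' @param nHeads head count (must divide d).
#' @param seed RNG seed.
#' @export
makeTriangleAttentionParams <- function(d, nHeads = 4L, seed = 1L) {
  if (d %% nHeads != 0L) stop("head count must divide d")
  cfg <- utils::modifyList(.defaultNetConfig(),
                           list(d = d, nInception = 1L, nTriangle = 1L,
                                nHeads = nHeads, inputChannelsReceptor = d,
                                inputChannelsComplex = d))
  P <- withSeed(seed, .initParams(cfg))
  P[grep("^tri1_row_", names(P))]
}

#' Parameters for a standalone transition layer
#' @param d channel width.
#' @param seed RNG seed.
#' @export
makeTransitionParams <- function(d, seed = 1L) {
  cfg <- utils::modifyList(.defaultNetConfig(),
                           list(d = d, nInception = 1L, nTriangle = 1L,
                                nHeads = 1L, inputChannelsReceptor = d,
                                inputChannelsComplex = d))
  P <- withSeed(seed, .initParams(cfg))
  P[grep("^tri1_trans", names(P))]
}

#' Parameters for a standalone ResNet-Inception block
#' @param d channel width (divisible by 4).
#' @param seed RNG seed.
#' @export
makeInceptionParams <- function(d, seed = 1L) {
  cfg <- utils::modifyList(.defaultNetConfig(),
                           list(d = d, nInception = 1L, nTriangle = 1L,
                                nHeads = 1L, inputChannelsReceptor = d,
                                inputChannelsComplex = d))
  P <- withSeed(seed, .initParams(cfg))
  P[grep("^rec_inc1_", names(P))]
}

# wrap a flat list of plain arrays as leaf nodes
.wrapParams <- function(params) .pget(lapply(params, adLeaf))

#' Triangle multiplicative update (standalone)
#'
#' z~_ij = z_ij + phi_out(sum_m r'_im z'_mj + sum_n z''_in l'_nj) * gate(z_ij)
#' where the primed tensors are gated linear projections of z, r, l, the
#' output map phi_out is layer-norm + linear, and the gate is
#' sigmoid(linear(z)); all products are elementwise over channels.  Buried
#' residues can be excluded from the sums via the masks.
#'
#' @param z complex pair tensor (L1 x L2 x d).
#' @param r receptor pair tensor (L1 x L1 x d).
#' @param l ligand pair tensor (L2 x L2 x d).
#' @param params parameter block from \code{\link{makeTriangleUpdateParams}}.
#' @param maskReceptor,maskLigand logical keep-flags (TRUE = surface).
#' @return updated L1 x L2 x d array.
#' @export
triangleUpdate <- function(z, r, l, params, maskReceptor = NULL,
                           maskLigand = NULL) {
  dz <- dim(z); dr <- dim(r); dl <- dim(l)
  if (length(dz) != 3L || length(dr) != 3L || length(dl) != 3L ||
      dr[1L] != dz[1L] || dr[2L] != dz[1L] || dl[1L] != dz[2L] ||
      dl[2L] != dz[2L] || dr[3L] != dz[3L] || dl[3L] != dz[3L])
    stop("shape mismatch among z (L1,L2,d), r (L1,L1,d), l (L2,L2,d)")
  adReset()
  p <- .wrapParams(params)
  out <- adValue(.nodeTriUpdate(adLeaf(z), adLeaf(r), adLeaf(l), p, "tri1_up",
                                maskR = maskReceptor, maskL = maskLigand))
  adReset()
  out
}

#' Triangle self-attention (standalone)
#'
#' Multi-head attention along one axis of the pair tensor.  For the row
#' axis, query (i, j) attends over keys (i, m), m running over the ligand;
#' pre-gating softmax weights are multiplied by the Gaussian distance gate
#' g(d) = exp(-d^2 / (2 lambda^2)) evaluated on the attended monomer's
#' distance map entry (j, m).  The column axis transposes the roles.
#' Buried residues are excluded as keys (zero weight).
#'
#' @param z pair tensor (L1 x L2 x d).
#' @param dmap intra-chain distance map of the attended monomer.
#' @param surface logical keep-flags for the attended monomer.
#' @param axis "row" or "column".
#' @param params parameter block from
#'   \code{\link{makeTriangleAttentionParams}}.
#' @param nHeads head count.
#' @param lambda distance-gate length scale in Angstrom (default 8).
#' @return updated L1 x L2 x d array.
#' @export
triangleAttention <- function(z, dmap, surface, axis = c("row", "column"),
                              params, nHeads = 4L, lambda = 8) {
  axis <- match.arg(axis)
  dz <- dim(z)
  Latt <- if (axis == "row") dz[2L] else dz[1L]
  if (!all(dim(dmap) == c(Latt, Latt)))
    stop("distance map must match the attended monomer's length")
  if (length(surface) != Latt) stop("surface mask length mismatch")
  adReset()
  p <- .wrapParams(params)
  gmat <- .gaussGate(dmap, lambda)
  zn <- adLeaf(z)
  out <- if (axis == "row") {
    .nodeTriAttnRow(zn, gmat, as.logical(surface), p, "tri1_row", nHeads)
  } else {
    adTranspose12(.nodeTriAttnRow(adTranspose12(zn), gmat,
                                  as.logical(surface), p, "tri1_row", nHeads))
  }
  out <- adValue(out)
  adReset()
  out
}

#' Transition layer (standalone)
#'
#' Position-wise two-layer map with an ELU between, plus residual:
#' z + W2 elu(W1 z + b1) + b2.
#'
#' @param z pair tensor (L1 x L2 x d).
#' @param params parameter block from \code{\link{makeTransitionParams}}.
#' @return updated array, same shape.
#' @export
transitionLayer <- function(z, params) {
  adReset()
  p <- .wrapParams(params)
  out <- adValue(.nodeTransition(adLeaf(z), p, "tri1_trans"))
  adReset()
  out
}

#' ResNet-Inception block (standalone)
#'
#' Three parallel convolution branches (1x1 to d/4; 3x3 to d/2; two
#' stacked 3x3 to d/4, an effective 5x5), ELU activations, channel
#' concatenation, 1x1 fusion, instance normalization, residual add.
#' Shape-preserving.
#'
#' @param x pair tensor (L1 x L2 x d), d divisible by 4.
#' @param params parameter block from \code{\link{makeInceptionParams}}.
#' @return array of the same shape.
#' @export
resnetInceptionForward <- function(x, params) {
  if (dim(x)[3L] != nrow(params$rec_inc1_b1_W))
    stop("channel count mismatch with parameters")
  adReset()
  p <- .wrapParams(params)
  out <- adValue(.nodeInception(adLeaf(x), p, "rec_inc1"))
  adReset()
  out
}

#' Contact head (standalone)
#'
#' Linear projection of the pair tensor to one channel, logistic
#' squashing, and transpose-averaging P <- (P + t(P))/2.
#'
#' @param z pair tensor (L x L x d).
#' @param W numeric d x 1 projection matrix.
#' @param b numeric length-1 bias.
#' @param symmetrize apply transpose-averaging (default TRUE).
#' @return a \linkS4class{ContactPrediction}.
#' @export
contactHead <- function(z, W, b = 0, symmetrize = TRUE) {
  adReset()
  PN <- list(head_W = adLeaf(as.matrix(W)), head_b = adLeaf(b))
  probs <- adValue(.nodeHead(adLeaf(z), .pget(PN), symmetrize))
  adReset()
  new("ContactPrediction", probs = probs, symmetrized = symmetrize)
}

## ---- checkpoints ----

#' Save a model checkpoint
#' @param model a ContactModel.
#' @param path output path (RDS container: parameter arrays + config).
#' @export
saveModel <- function(model, path) {
  saveRDS(list(params = model@params, config = model@config,
               format = "tmcontact-checkpoint-1"), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path checkpoint path.
#' @return a ContactModel.
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "tmcontact-checkpoint-1"))
    stop("not a model checkpoint: ", path)
  new("ContactModel", params = ck$params, config = ck$config)
}

#' Number of frozen (non-trainable) parameters of a model
#'
#' Every parameter of the model is trainable; the transfer-learning
#' protocol fine-tunes with no frozen layers.  Reported for protocol
#' audits.
#' @param model a ContactModel.
#' @return integer, always 0 for this architecture.
#' @export
frozenParameterCount <- function(model) 0L

#' Ranked contact list from a prediction
#'
#' Deduplicated (upper triangle including the diagonal) residue pairs
#' ranked by probability, ties broken by (i, j) lexicographic order.
#'
#' @param pred a ContactPrediction.
#' @return data.frame(i, j, probability), 1-based indices.
#' @export
rankedContacts <- function(pred) {
  P <- pred@probs
  idx <- which(upper.tri(P, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L], probability = P[idx])
  df[order(-df$probability, df$i, df$j), , drop = FALSE]
}
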