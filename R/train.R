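#' Training configuration
#'
#' @param epochs number of passes over the training targets.
#' @param lr Adam learning rate (default 0.001).
#' @param dropout dropout rate used during training (default 0.1).
#' @param cropLength maximum sequence length; longer targets are cropped to
#'   the max-contact window (default 256).
#' @param patience early-stopping patience on validation focal loss
#'   (default 5; `Inf` disables early stopping).
#' @param clipGrad optional global gradient-norm clip (default NULL: off).
#' @param checkpointDir optional directory; when set, the final and the
#'   best-validation checkpoints are written there as
#'   `final.rds` / `best.rds`.
#' @param seed RNG seed controlling shuffling, dropout and crop
#'   tie-breaking.
#' @return list of class "trainConfig".
#' @export
trainConfig <- function(epochs = 30L, lr = 0.001, dropout = 0.1,
                        cropLength = 256L, patience = 5L, clipGrad = NULL,
                        checkpointDir = NULL, seed = 1L) {
  if (cropLength < 1L) stop("cropLength must be >= 1")
  if (lr < 0) stop("lr must be >= 0")
  structure(list(epochs = as.integer(epochs), lr = lr, dropout = dropout,
                 cropLength = as.integer(cropLength),
                 patience = patience, clipGrad = clipGrad,
                 checkpointDir = checkpointDir,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

#' Crop a training target to its maximum-contact window
#'
#' Targets longer than `window` are cropped: all diagonal windows
#' [w, w + window) are scanned with the given stride, the windows whose
#' diagonal block of the ground-truth inter-chain map contains the maximum
#' number of contacts are collected, and one of them is chosen uniformly at
#' random under `seed`.  All tensors (features, distance map, surface
#' flags, truth) are sliced consistently.
#'
#' @param target a \linkS4class{TrainingTarget}.
#' @param window maximum length (default 256).
#' @param stride scan stride (default 1).
#' @param seed RNG seed for the uniform tie-break.
#' @return a TrainingTarget of length <= window with `cropOffset` set.
#' @export
cropToWindow <- function(target, window = 256L, stride = 1L, seed = 1L) {
  if (window < 1L) stop("window must be >= 1")
  L <- target@L
  if (L <= window) return(target)
  U <- target@truth@union
  starts <- seq.int(1L, L - window + 1L, by = stride)
  counts <- vapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    sum(U[idx, idx])
  }, numeric(1))
  best <- starts[counts == max(counts)]
  s <- withSeed(seed, best[sample.int(length(best), 1L)])
  idx <- s:(s + window - 1L)
  bun <- target@bundle
  sub3 <- function(a) a[idx, idx, , drop = FALSE]
  newBundle <- new("FeatureBundle",
                   receptor = sub3(bun@receptor), ligand = sub3(bun@ligand),
                   complex = sub3(bun@complex),
                   manifestReceptor = bun@manifestReceptor,
                   manifestComplex = bun@manifestComplex,
                   L = as.integer(window))
  pm <- lapply(target@truth@pairMaps, function(m) m[idx, idx, drop = FALSE])
  newTruth <- new("ContactMap", union = U[idx, idx, drop = FALSE],
                  pairMaps = pm, cutoff = target@truth@cutoff)
  new("TrainingTarget", id = target@id, bundle = newBundle,
      dmap = target@dmap[idx, idx, drop = FALSE],
      surface = target@surface[idx], truth = newTruth,
      L = as.integer(window), cropOffset = c(s - 1L, s - 1L))
}

# one forward + loss on a target (train or eval mode); returns node list
.targetLoss <- function(model, target, train = FALSE) {
  fw <- .forwardNodes(model, target@bundle, target@dmap, target@surface,
                      train = train)
  cfg <- model@config
  loss <- adFocalLossP(fw$probs, target@truth@union, gamma = cfg$gamma,
                       alpha = cfg$alpha)
  list(loss = loss, PN = fw$PN)
}

# mean eval-mode focal loss over a list of targets
.meanLoss <- function(model, targets) {
  if (length(targets) == 0L) return(NA_real_)
  mean(vapply(targets, function(tg) {
    v <- adValue(.targetLoss(model, tg, train = FALSE)$loss)
    adReset()
    v
  }, numeric(1)))
}

#' Train a model on a list of targets (mini-batch size 1, Adam)
#'
#' Per-target focal-loss optimization with the Adam optimizer at the
#' configured learning rate, shuffled each epoch, with optional validation
#' based early stopping (patience on the mean validation focal loss).
#' Deterministic for fixed seeds.  The input model is not mutated; the
#' returned model carries the best-validation parameters (final parameters
#' when no validation set is given) and a training log.
#'
#' @param model a \linkS4class{ContactModel}.
#' @param data list of \linkS4class{TrainingTarget}.
#' @param cfg a \code{\link{trainConfig}}.
#' @param validData optional list of TrainingTarget for validation.
#' @param verbose print per-epoch losses.
#' @return a ContactModel with attribute "log" (data.frame of per-epoch
#'   training/validation loss).
#' @export
trainStage <- function(model, data, cfg = trainConfig(), validData = NULL,
                       verbose = FALSE) {
  if (length(data) == 0L) stop("empty training set")
  data <- lapply(data, function(tg)
    if (tg@L > cfg$cropLength)
      cropToWindow(tg, cfg$cropLength, seed = cfg$seed) else tg)
  P <- model@params
  cfg0 <- model@config
  cfg0$dropout <- cfg$dropout
  mAdam <- lapply(P, function(x) x * 0)
  vAdam <- lapply(P, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  tstep <- 0L
  seeds <- deriveSeeds(cfg$seed, cfg$epochs * (length(data) + 1L))
  si <- 0L
  bestLoss <- Inf; bestP <- P; bad <- 0L
  log <- data.frame(epoch = integer(), trainLoss = numeric(),
                    validLoss = numeric())
  for (ep in seq_len(cfg$epochs)) {
    si <- si + 1L
    ord <- withSeed(seeds[si], sample.int(length(data)))
    epLoss <- 0
    for (ix in ord) {
      si <- si + 1L
      tg <- data[[ix]]
      mdl <- new("ContactModel", params = P, config = cfg0)
      res <- withSeed(seeds[si], .targetLoss(mdl, tg, train = TRUE))
      lv <- adValue(res$loss)
      if (!is.finite(lv))
        stop(sprintf("non-finite loss at epoch %d target %s: %g",
                     ep, tg@id, lv))
      adBackward(res$loss)
      grads <- lapply(res$PN, function(nd) nd$grad)
      adReset()
      epLoss <- epLoss + lv
      if (cfg$lr > 0) {
        if (!is.null(cfg$clipGrad)) {
          gn <- sqrt(sum(vapply(grads, function(g)
            if (is.null(g)) 0 else sum(g^2), numeric(1))))
          if (gn > cfg$clipGrad)
            grads <- lapply(grads, function(g)
              if (is.null(g)) g else g * (cfg$clipGrad / gn))
        }
        tstep <- tstep + 1L
        c1 <- 1 - b1^tstep; c2 <- 1 - b2^tstep
        for (nm in names(P)) {
          g <- grads[[nm]]
          if (is.null(g)) next
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g^2
          P[[nm]] <- P[[nm]] - cfg$lr * (mAdam[[nm]] / c1) /
            (sqrt(vAdam[[nm]] / c2) + epsA)
        }
      }
    }
    epLoss <- epLoss / length(data)
    vLoss <- if (is.null(validData)) NA_real_ else
      .meanLoss(new("ContactModel", params = P, config = cfg0), validData)
    log <- rbind(log, data.frame(epoch = ep, trainLoss = epLoss,
                                 validLoss = vLoss))
    if (verbose)
      message(sprintf("epoch %d: train %.5f valid %s", ep, epLoss,
                      ifelse(is.na(vLoss), "-", sprintf("%.5f", vLoss))))
    if (!is.na(vLoss)) {
      if (vLoss < bestLoss - 1e-12) {
        bestLoss <- vLoss; bestP <- P; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience) break
      }
    }
  }
  out <- new("ContactModel",
             params = if (is.null(validData)) P else bestP, config = cfg0)
  attr(out, "log") <- log
  if (!is.null(cfg$checkpointDir)) {
    dir.create(cfg$checkpointDir, showWarnings = FALSE, recursive = TRUE)
    saveModel(new("ContactModel", params = P, config = cfg0),
              file.path(cfg$checkpointDir, "final.rds"))
    saveModel(out, file.path(cfg$checkpointDir, "best.rds"))
  }
  out
}

#' Fine-tune a pretrained model with no frozen layers
#'
#' Transfer-learning stage: starts from the pretrained parameters and
#' re-trains every parameter group (frozen-parameter count is asserted to
#' be zero) on the membrane-protein-like targets.  The pretrained model
#' object is left untouched.
#'
#' @param pretrained a \linkS4class{ContactModel}.
#' @param tmpData list of TrainingTarget in the target regime.
#' @param cfg a \code{\link{trainConfig}}.
#' @param validData optional validation targets.
#' @param verbose print per-epoch losses.
#' @return the fine-tuned ContactModel (attribute "frozenParams" = 0).
#' @export
transferFinetune <- function(pretrained, tmpData, cfg = trainConfig(epochs = 20L),
                             validData = NULL, verbose = FALSE) {
  stopifnot(methods::is(pretrained, "ContactModel"))
  nFrozen <- frozenParameterCount(pretrained)
  if (nFrozen != 0L) stop("transfer protocol requires no frozen layers")
  if (cfg$epochs == 0L) {
    out <- new("ContactModel", params = pretrained@params,
               config = pretrained@config)
    attr(out, "frozenParams") <- 0L
    attr(out, "log") <- data.frame(epoch = integer(), trainLoss = numeric(),
                                   validLoss = numeric())
    return(out)
  }
  out <- trainStage(pretrained, tmpData, cfg, validData = validData,
                    verbose = verbose)
  attr(out, "frozenParams") <- 0L
  out
}

#' Run the full two-stage transfer protocol on a benchmark
#'
#' Trains three models and evaluates them on the membrane-like test split:
#' \itemize{
#'   \item IT: initial training on the soluble-like train/valid splits;
#'   \item DT: direct training from scratch on the membrane-like splits;
#'   \item transfer: IT fine-tuned on the membrane-like splits with no
#'     frozen layers.
#' }
#'
#' @param benchmark a \linkS4class{SyntheticBenchmark}.
#' @param modelConfig named list of architecture overrides passed to
#'   \code{\link{newContactModel}}.
#' @param epochsInitial,epochsDirect,epochsFinetune epoch budgets.
#' @param lr Adam learning rate.
#' @param seed master seed (model init, shuffling, dropout).
#' @param verbose print progress.
#' @return list with elements `IT`, `DT`, `transfer` (ContactModel) and
#'   `report` (data.frame: one row per model, mean top-k precision columns
#'   over the test split).
#' @export
runProtocol <- function(benchmark, modelConfig = list(),
                        epochsInitial = 4L, epochsDirect = 4L,
                        epochsFinetune = 4L, lr = 0.001, seed = 1L,
                        verbose = FALSE) {
  for (sl in c("solubleTrain", "solubleValid", "tmpTrain", "tmpValid",
               "tmpTest"))
    if (length(slot(benchmark, sl)) == 0L) stop("empty benchmark split: ", sl)
  b0 <- benchmark@solubleTrain[[1L]]@bundle
  seeds <- deriveSeeds(seed, 4L)
  mk <- function(s) newContactModel(dim(b0@receptor)[3L],
                                    dim(b0@complex)[3L],
                                    config = modelConfig, seed = s)
  itModel <- trainStage(mk(seeds[1L]), benchmark@solubleTrain,
                        trainConfig(epochs = epochsInitial, lr = lr,
                                    seed = seeds[2L]),
                        validData = benchmark@solubleValid, verbose = verbose)
  dtModel <- trainStage(mk(seeds[1L]), benchmark@tmpTrain,
                        trainConfig(epochs = epochsDirect, lr = lr,
                                    seed = seeds[3L]),
                        validData = benchmark@tmpValid, verbose = verbose)
  tlModel <- transferFinetune(itModel, benchmark@tmpTrain,
                              trainConfig(epochs = epochsFinetune, lr = lr,
                                          seed = seeds[4L]),
                              validData = benchmark@tmpValid,
                              verbose = verbose)
  evalOne <- function(model) {
    reps <- lapply(benchmark@tmpTest, function(tg) {
      pred <- predictContacts(model, tg@bundle, tg@dmap, tg@surface)
      topkPrecision(pred, tg@truth, L = tg@L)
    })
    colMeans(do.call(rbind, reps), na.rm = TRUE)
  }
  rep <- rbind(IT = evalOne(itModel), DT = evalOne(dtModel),
               transfer = evalOne(tlModel))
  report <- data.frame(model = rownames(rep), rep, row.names = NULL,
                       check.names = FALSE)
  list(IT = itModel, DT = dtModel, transfer = tlModel, report = report)
}
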