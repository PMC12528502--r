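# Training protocol: Kaiming-He uniform initialization, AdamW with decoupled
# weight decay, plateau learning-rate decay gated by the validation loss,
# best-checkpoint selection, and the four-way loss-ablation harness.
#
# An epoch is one pass over all (fraction, pCT) training pairs in a seeded
# shuffled order; augmentation is resampled online every epoch and applied
# to the training split only. Validation uses un-augmented data. A non-finite
# loss aborts with the offending component named (reproducibility over
# robustness at desk scale).

#' Training configuration
#'
#' Defaults follow the reference protocol: AdamW with beta1 = 0.9,
#' beta2 = 0.999, eps = 1e-8, weight decay 1e-2, initial learning rate 1e-3,
#' batch size one, 40 epochs, plateau decay by a factor of 10 after 5
#' non-improving epochs (relative threshold 1e-4) with floor 1e-6.
#'
#' @param epochs training epochs.
#' @param lr0 initial learning rate.
#' @param betas AdamW (beta1, beta2).
#' @param eps AdamW epsilon.
#' @param weightDecay decoupled weight decay.
#' @param plateauFactor learning-rate division factor on plateau.
#' @param plateauPatience consecutive non-improving epochs before decay.
#' @param plateauThreshold relative improvement threshold.
#' @param lrMin learning-rate floor.
#' @param augment apply online augmentation to training pairs.
#' @param seed master seed (weight init, data order, augmentation).
#' @return A list of class \code{"trainConfig"}.
#' @export
trainConfig <- function(epochs = 40L, lr0 = 1e-3, betas = c(0.9, 0.999),
                        eps = 1e-8, weightDecay = 1e-2, plateauFactor = 10,
                        plateauPatience = 5L, plateauThreshold = 1e-4,
                        lrMin = 1e-6, augment = TRUE, seed = 1L) {
  stopifnot(lrMin <= lr0, plateauPatience >= 1L, epochs >= 1L)
  structure(list(epochs = as.integer(epochs), batchSize = 1L, lr0 = lr0,
                 betas = betas, eps = eps, weightDecay = weightDecay,
                 plateauFactor = plateauFactor,
                 plateauPatience = as.integer(plateauPatience),
                 plateauThreshold = plateauThreshold, lrMin = lrMin,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "trainConfig")
}

#' Initialize model weights (Kaiming-He uniform)
#'
#' Every convolution weight is drawn uniformly within
#' \eqn{\pm\sqrt{6/fan_{in}}} (gain \eqn{\sqrt{2}} for ReLU networks);
#' biases within \eqn{\pm 1/\sqrt{fan_{in}}}. Deterministic given the seed;
#' optimizer state is reset.
#'
#' @param model a \code{"fusionModel"}.
#' @param seed integer.
#' @return The model, initialized (parameters are mutated in place).
#' @export
initWeights <- function(model, seed = 1L) {
  stopifnot(inherits(model, "fusionModel"))
  withSeed(seed, {
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      if (grepl("_w$", nm)) {
        bound <- sqrt(2) * sqrt(3 / p$fanIn)
        p$value <- array(runif(length(p$value), -bound, bound),
                         dim = dim(p$value))
      } else {
        bound <- 1 / sqrt(p$fanIn)
        p$value <- array(runif(length(p$value), -bound, bound),
                         dim = dim(p$value))
      }
      p$grad <- array(0, dim = dim(p$value))
      p$m <- array(0, dim = dim(p$value))
      p$v <- array(0, dim = dim(p$value))
    }
  })
  model
}

.zeroGrads <- function(model) {
  for (p in model$params) p$grad <- array(0, dim = dim(p$value))
  invisible(NULL)
}

# One AdamW update over all parameters (decoupled weight decay).
.adamwStep <- function(model, opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$betas[1]; b2 <- opt$betas[2]
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (p in model$params) {
    p$m <- b1 * p$m + (1 - b1) * p$grad
    p$v <- b2 * p$v + (1 - b2) * p$grad^2
    p$value <- p$value - opt$lr * ((p$m / c1) / (sqrt(p$v / c2) + opt$eps)) -
      opt$lr * opt$weightDecay * p$value
  }
  invisible(NULL)
}

#' Plateau learning-rate scheduler
#'
#' Divides the learning rate by \code{plateauFactor} once the validation
#' loss has not improved (relative threshold \code{plateauThreshold}) for
#' \code{plateauPatience} consecutive epochs, never going below
#' \code{lrMin}. \code{lrScheduleStep} feeds one validation loss and returns
#' the learning rate in force afterwards.
#'
#' @param cfg a \code{\link{trainConfig}}.
#' @return \code{plateauScheduler}: a mutable scheduler state.
#' @examples
#' s <- plateauScheduler(trainConfig())
#' for (i in 1:6) lr <- lrScheduleStep(s, 1.0)
#' lr  # 1e-4 after six flat epochs
#' @export
plateauScheduler <- function(cfg) {
  s <- new.env(parent = emptyenv())
  s$lr <- cfg$lr0
  s$best <- Inf
  s$bad <- 0L
  s$factor <- cfg$plateauFactor
  s$patience <- cfg$plateauPatience
  s$threshold <- cfg$plateauThreshold
  s$lrMin <- cfg$lrMin
  s
}

#' @rdname plateauScheduler
#' @param state a scheduler state.
#' @param validationLoss the epoch's validation loss.
#' @export
lrScheduleStep <- function(state, validationLoss) {
  if (validationLoss < state$best * (1 - state$threshold)) {
    state$best <- validationLoss
    state$bad <- 0L
  } else {
    state$bad <- state$bad + 1L
    if (state$bad >= state$patience) {
      state$lr <- max(state$lr / state$factor, state$lrMin)
      state$bad <- 0L
    }
  }
  state$lr
}

# Assemble the preprocessed tensors for one (case, fraction) pair.
# Augmentation (training only) happens in the HU domain before
# normalization; DRRs are rendered from the augmented, normalized,
# core-masked CBCT so they reflect the augmented anatomy.
.preparePair <- function(case, fraction, core, raster, augment = NULL) {
  cbct <- fraction$cbct
  masks <- fraction$masks
  if (!is.null(augment)) {
    ap <- augmentPair(cbct, masks, augment)
    cbct <- ap$cbct
    masks <- ap$masks
  }
  cbctN <- truncateNormalize(cbct)
  pctN <- truncateNormalize(planningVolume(case))
  target <- volData(cbctN) * core
  pctIn <- volData(pctN) * core
  drrs <- renderPair(target, raster = c(raster, raster))
  umask <- buildUnifiedMask(masks)
  list(target = target, pctIn = pctIn, drrs = drrs, umask = umask,
       masks = masks, normRange = normRange(cbctN))
}

.lossComponentsFinite <- function(comp, total) {
  if (is.finite(total)) return(invisible(NULL))
  badc <- names(comp)[is.nan(comp) | is.infinite(comp)]
  stop("non-finite training loss; offending component(s): ",
       if (length(badc)) paste(badc, collapse = ", ") else "total")
}

#' Train a model on a phantom cohort
#'
#' Runs the full protocol: seeded Kaiming initialization, AdamW updates (one
#' pair per step), per-epoch validation loss and masked validation metrics,
#' plateau learning-rate decay gated by the validation loss, and retention
#' of the checkpoint with the lowest validation loss.
#'
#' @param model a \code{"fusionModel"} (freshly built; it is re-initialized
#'   from \code{trainCfg$seed} unless \code{reinit = FALSE}).
#' @param cohort a \code{"phantomCohort"} with nonempty train and val splits.
#' @param weights a \linkS4class{LossWeights}.
#' @param trainCfg a \code{\link{trainConfig}}.
#' @param featSpec a \code{\link{featureExtractorSpec}}.
#' @param reinit re-initialize weights from the seed before training.
#' @param maxSteps optional cap on total optimization steps (for smoke runs).
#' @param valEvery validate (and step the scheduler) every this many epochs;
#'   the final epoch always validates so a best checkpoint always exists.
#' @return List with \code{history} (one row per epoch: train loss,
#'   validation loss, validation mMAE/mSSIM/mPSNR, lr), \code{best}
#'   (checkpoint record: epoch, validationLoss, lr, weights, cfg) and the
#'   trained \code{model}.
#' @export
trainModel <- function(model, cohort, weights = lossPreset("ALF"),
                       trainCfg = trainConfig(), featSpec = featureExtractorSpec(),
                       reinit = TRUE, maxSteps = Inf, valEvery = 1L) {
  stopifnot(inherits(model, "fusionModel"), inherits(cohort, "phantomCohort"))
  trainIds <- cohortSplit(cohort, "train")
  valIds <- cohortSplit(cohort, "val")
  if (length(trainIds) == 0L || length(valIds) == 0L)
    stop("cohort needs nonempty train and val splits")
  if (reinit) initWeights(model, trainCfg$seed)

  cfg <- model$cfg
  core <- centralRegionMask(cfg$inShape3d)
  raster <- cfg$inRaster2d
  caseOf <- setNames(cohort$cases, vapply(cohort$cases, caseId, ""))
  pairs <- do.call(rbind, lapply(trainIds, function(id)
    data.frame(id = id, k = seq_along(fractions(caseOf[[id]])))))

  opt <- new.env(parent = emptyenv())
  opt$lr <- trainCfg$lr0; opt$betas <- trainCfg$betas; opt$eps <- trainCfg$eps
  opt$weightDecay <- trainCfg$weightDecay; opt$t <- 0L
  sched <- plateauScheduler(trainCfg)

  history <- NULL
  best <- NULL
  step <- 0L
  for (epoch in seq_len(trainCfg$epochs)) {
    ord <- withSeed(trainCfg$seed + 131L * epoch, sample(nrow(pairs)))
    epochLosses <- c()
    for (j in ord) {
      if (step >= maxSteps) break
      id <- pairs$id[j]; k <- pairs$k[j]
      aug <- if (trainCfg$augment)
        sampleAugmentParams((trainCfg$seed * 7919L + epoch * 613L + j) %%
                              .Machine$integer.max) else NULL
      pr <- .preparePair(caseOf[[id]], fractions(caseOf[[id]])[[k]], core,
                         raster, aug)
      adTapeBegin()
      s <- .adForward(model, projectionImage(pr$drrs, 0),
                      projectionImage(pr$drrs, 270), pr$pctIn)
      lo <- adAlfLoss(s, pr$target, projectionImage(pr$drrs, 0),
                      projectionImage(pr$drrs, 270), pr$umask, weights,
                      featSpec)
      .lossComponentsFinite(lo$components, lo$node$value)
      .zeroGrads(model)
      adBackward(lo$node)
      .adamwStep(model, opt)
      epochLosses <- c(epochLosses, lo$node$value)
      step <- step + 1L
    }
    adTapeBegin()

    lastEpoch <- epoch == trainCfg$epochs || step >= maxSteps
    if (epoch %% valEvery == 0L || lastEpoch) {
      val <- .validateEpoch(model, cohort, valIds, weights, featSpec, core,
                            raster)
      newLr <- lrScheduleStep(sched, val$loss)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(epochLosses),
        val_loss = val$loss, val_mmae = val$mmae, val_mssim = val$mssim,
        val_mpsnr = val$mpsnr, lr = opt$lr))
      if (is.null(best) || val$loss < best$validationLoss)
        best <- list(epoch = epoch, validationLoss = val$loss, lr = opt$lr,
                     weights = lapply(model$params, function(p) p$value),
                     cfg = cfg, lossWeights = weightVector(weights))
      opt$lr <- newLr
    } else {
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(epochLosses),
        val_loss = NA_real_, val_mmae = NA_real_, val_mssim = NA_real_,
        val_mpsnr = NA_real_, lr = opt$lr))
    }
    if (step >= maxSteps) break
  }
  list(history = history, best = best, model = model)
}

# Validation pass: un-augmented pairs; loss plus HU-domain masked metrics.
.validateEpoch <- function(model, cohort, valIds, weights, featSpec, core,
                           raster) {
  caseOf <- setNames(cohort$cases, vapply(cohort$cases, caseId, ""))
  losses <- mm <- ms <- mp <- c()
  for (id in valIds) {
    case <- caseOf[[id]]
    for (fr in fractions(case)) {
      pr <- .preparePair(case, fr, core, raster, augment = NULL)
      adTapeBegin()
      s <- .adForward(model, projectionImage(pr$drrs, 0),
                      projectionImage(pr$drrs, 270), pr$pctIn)
      lo <- adAlfLoss(s, pr$target, projectionImage(pr$drrs, 0),
                      projectionImage(pr$drrs, 270), pr$umask, weights,
                      featSpec)
      losses <- c(losses, lo$node$value)
      sHU <- s$value * (pr$normRange[2] - pr$normRange[1]) + pr$normRange[1]
      tHU <- pr$target * (pr$normRange[2] - pr$normRange[1]) + pr$normRange[1]
      body <- structureMask(pr$masks, "body")
      mm <- c(mm, mMAE(sHU, tHU, body))
      ms <- c(ms, mSSIM(sHU, tHU, body))
      mp <- c(mp, mPSNR(sHU, tHU, body))
    }
  }
  adTapeBegin()
  list(loss = mean(losses), mmae = mean(mm), mssim = mean(ms),
       mpsnr = mean(mp))
}

#' Restore a model from a checkpoint record
#'
#' @param ckpt the \code{best} element returned by \code{\link{trainModel}}.
#' @return A \code{"fusionModel"} with the checkpointed weights.
#' @export
restoreModel <- function(ckpt) {
  model <- buildModel(ckpt$cfg, seed = 1L)
  for (nm in names(ckpt$weights))
    model$params[[nm]]$value <- ckpt$weights[[nm]]
  model
}

#' Save / load a checkpoint as an R data source file
#'
#' Checkpoints are serialized with \code{dput}-style R source (text, no
#' binary formats), containing weights, configuration, loss weights and the
#' package version.
#'
#' @param ckpt a checkpoint record.
#' @param path file path.
#' @return \code{saveCheckpoint}: the path, invisibly; \code{loadCheckpoint}:
#'   the checkpoint record.
#' @export
saveCheckpoint <- function(ckpt, path) {
  ckpt$version <- as.character(utils::packageVersion("OrthoCBCT"))
  dput(ckpt, file = path,
       control = c("showAttributes", "keepInteger", "keepNA", "digits17"))
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ckpt <- dget(path)
  ckpt$cfg <- do.call(modelConfig,
                      ckpt$cfg[setdiff(names(ckpt$cfg), NULL)])
  ckpt
}

#' Loss-ablation harness
#'
#' Trains the same architecture from identical initial weights (one seed)
#' under the four published loss configurations (onlyMAE, onlyPL, MAE&PL,
#' ALF), evaluates each trained model on the test split, and returns a tidy
#' results table.
#'
#' @param cohort a \code{"phantomCohort"}.
#' @param cfg a \code{\link{modelConfig}}.
#' @param trainCfg a \code{\link{trainConfig}}.
#' @param featSpec a \code{\link{featureExtractorSpec}}.
#' @return List with \code{summary} (4 rows x one column per masked metric),
#'   \code{perCase} (named list of per-fraction metric tables), \code{runs}
#'   (the four train results).
#' @export
runAblation <- function(cohort, cfg, trainCfg = trainConfig(),
                        featSpec = featureExtractorSpec()) {
  configs <- c("onlyMAE", "onlyPL", "MAE&PL", "ALF")
  runs <- perCase <- list()
  for (nm in configs) {
    model <- buildModel(cfg, seed = trainCfg$seed)
    fit <- trainModel(model, cohort, weights = lossPreset(nm),
                      trainCfg = trainCfg, featSpec = featSpec)
    ev <- evaluateCohort(restoreModel(fit$best), cohort, split = "test",
                         featSpec = featSpec)
    runs[[nm]] <- fit
    perCase[[nm]] <- ev$reports
  }
  summary <- do.call(rbind, lapply(configs, function(nm) {
    s <- colMeans(perCase[[nm]][, c("mmae", "mssim", "mpsnr", "clpips")])
    data.frame(loss_config = nm, mmae = s[["mmae"]], mssim = s[["mssim"]],
               mpsnr = s[["mpsnr"]], clpips = s[["clpips"]])
  }))
  rownames(summary) <- NULL
  list(summary = summary, perCase = perCase, runs = runs)
}
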