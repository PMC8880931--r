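## Contrastive pre-training (and the supervised from-scratch baseline).
##
## Pre-training minimizes the batch NT-Xent loss with Adam; the learning rate
## starts at `initialLr` and is decayed once per epoch along a half-period
## cosine, reaching zero at `schedulePeriod`. Patients (never records) are
## split into train/validation sets, and the checkpoint with the best
## validation loss is the one returned.

#' Pre-training configuration
#'
#' @param epochs Training epochs (default 50).
#' @param initialLr Starting learning rate (default 0.1).
#' @param schedulePeriod Cosine period in epochs (default 50); the rate
#'   reaches zero at this epoch.
#' @param validationFraction Fraction of *patients* held out for checkpoint
#'   selection (default 0.1).
#' @param seed Integer seed governing the split, weight init and batch stream.
#' @return Validated config list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 50L, initialLr = 0.1, schedulePeriod = 50L,
                        validationFraction = 0.1, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), initialLr = initialLr,
              schedulePeriod = as.integer(schedulePeriod),
              validationFraction = validationFraction, seed = as.integer(seed))
  if (cfg$epochs < 1 || cfg$initialLr <= 0 || cfg$schedulePeriod < 1 ||
      cfg$validationFraction <= 0 || cfg$validationFraction >= 1) {
    pclrError("train config: epochs >= 1, initialLr > 0, 0 < validationFraction < 1",
              "pclr_config_error")
  }
  structure(cfg, class = c("trainConfig", "list"))
}

#' From-scratch baseline configuration
#'
#' Grid-searched supervised training of the same encoder plus a linear head:
#' learning rates crossed with convolutional dropout rates, Adam, early
#' stopping after `patience` non-improving validation epochs, best-validation
#' checkpoint restored per cell, best cell returned.
#'
#' @param lrGrid Learning-rate grid (default `c(1e-2, 1e-3, 1e-4)`).
#' @param dropoutGrid Dropout-rate grid (default `c(0, 0.1, 0.2)`).
#' @param patience Early-stopping patience in epochs (default 5).
#' @param maxEpochs Hard epoch cap per cell (default 50).
#' @param batchSize Minibatch size (default 32).
#' @param validationFraction Fraction of labeled records held out (default 0.25).
#' @return Validated config list of class `scratchConfig`.
#' @export
scratchConfig <- function(lrGrid = c(1e-2, 1e-3, 1e-4),
                          dropoutGrid = c(0, 0.1, 0.2),
                          patience = 5L, maxEpochs = 50L, batchSize = 32L,
                          validationFraction = 0.25) {
  cfg <- list(lrGrid = lrGrid, dropoutGrid = dropoutGrid,
              patience = as.integer(patience), maxEpochs = as.integer(maxEpochs),
              batchSize = as.integer(batchSize),
              validationFraction = validationFraction)
  if (!length(cfg$lrGrid) || !length(cfg$dropoutGrid)) {
    pclrError("scratch config: grids must be non-empty", "pclr_config_error")
  }
  structure(cfg, class = c("scratchConfig", "list"))
}

#' Learning rate at an epoch
#'
#' Half-period cosine decay: `initialLr * (1 + cos(pi * epoch / period)) / 2`,
#' so the rate is `initialLr` at epoch 0, half of it at the period midpoint,
#' and exactly zero at the period's end. Epochs beyond the period clamp to
#' the final value (with a message).
#'
#' @param epoch Epoch index, `0 <= epoch` (0 = before any decay).
#' @param config A [trainConfig()].
#' @return The learning rate.
#' @examples
#' lrAtEpoch(0, trainConfig())   # 0.1
#' lrAtEpoch(25, trainConfig())  # 0.05
#' lrAtEpoch(50, trainConfig())  # 0
#' @export
lrAtEpoch <- function(epoch, config = trainConfig()) {
  stopifnot(epoch >= 0)
  if (epoch > config$schedulePeriod) {
    message(sprintf("epoch %d beyond schedule period %d; clamping to final rate",
                    epoch, config$schedulePeriod))
    epoch <- config$schedulePeriod
  }
  config$initialLr * (1 + cos(pi * epoch / config$schedulePeriod)) / 2
}

## Split unique patients into train/validation id sets (by patient, never by
## record, so identity cannot leak into checkpoint selection).
splitPatients <- function(patientIds, fraction, seed) {
  ids <- unique(patientIds)
  nVal <- round(fraction * length(ids))
  if (nVal < 1 || nVal >= length(ids)) {
    pclrError(sprintf(
      "validation split empty or degenerate: %d of %d patients", nVal, length(ids)),
      "pclr_validation_error")
  }
  withSeed(deriveSeed(seed, 21), {
    val <- sample(ids, nVal)
    list(train = setdiff(ids, val), val = val)
  })
}

#' Subset a tensor set
#'
#' @param ts An [ECGTensorSet-class].
#' @param keep Logical or integer index over records.
#' @return The subsetted [ECGTensorSet-class].
#' @export
subsetTensorSet <- function(ts, keep) {
  new("ECGTensorSet", tensors = ts@tensors[, , keep, drop = FALSE],
      recordIds = ts@recordIds[keep], patientIds = ts@patientIds[keep])
}

#' PCLR pre-training
#'
#' Runs patient-contrastive pre-training on a preprocessed, eligibility-
#' filtered tensor set: per epoch, seeded contrastive batches (two records
#' per patient) are pushed through encoder and projection head, the NT-Xent
#' batch loss is minimized by Adam at the epoch's cosine-scheduled rate, the
#' validation loss is computed on held-out patients, and the checkpoint with
#' the best validation loss is retained. Fully reproducible from the config
#' seed.
#'
#' @param tensorSet An [ECGTensorSet-class] in which every patient has at
#'   least two records.
#' @param encoderCfg An [encoderConfig()] whose `inputLength` matches the
#'   tensor set.
#' @param projectionCfg A [projectionConfig()]; its `inputDim` must equal the
#'   encoder's representation width.
#' @param lossCfg A [lossConfig()].
#' @param trainCfg A [trainConfig()].
#' @param nPatientsPerBatch Patients per contrastive batch (default 512,
#'   i.e. 1,024 ECGs); capped by the training-split size at call time is an
#'   error, not a silent shrink.
#' @return A [PCLRFit-class].
#' @export
pretrainPCLR <- function(tensorSet, encoderCfg, projectionCfg = NULL,
                         lossCfg = lossConfig(), trainCfg = trainConfig(),
                         nPatientsPerBatch = 512L) {
  stopifnot(is(tensorSet, "ECGTensorSet"))
  if (is.null(projectionCfg)) {
    projectionCfg <- projectionConfig(inputDim = encoderCfg$representationDim,
                                      hiddenUnits = encoderCfg$representationDim,
                                      outputUnits = encoderCfg$representationDim)
  }
  if (projectionCfg$inputDim != encoderCfg$representationDim) {
    pclrError("projection head input width must equal the representation width",
              "pclr_width_mismatch")
  }
  seed <- trainCfg$seed
  sp <- splitPatients(tensorSet@patientIds, trainCfg$validationFraction, seed)
  trainTs <- subsetTensorSet(tensorSet, tensorSet@patientIds %in% sp$train)
  valTs <- subsetTensorSet(tensorSet, tensorSet@patientIds %in% sp$val)

  encoder <- buildEncoder(encoderCfg, seed = seed)
  head <- buildProjectionHead(projectionCfg, seed = seed)
  encNet <- encoder@net
  headNet <- head@net
  encState <- NULL
  headState <- NULL
  stepT <- 0L

  nValBatch <- min(nPatientsPerBatch, length(sp$val))
  log <- data.frame(epoch = integer(), lr = numeric(),
                    trainLoss = numeric(), valLoss = numeric())
  best <- list(valLoss = Inf, encNet = NULL, headNet = NULL, epoch = NA_integer_)

  for (epoch in seq_len(trainCfg$epochs)) {
    lr <- lrAtEpoch(epoch - 1, trainCfg)
    batches <- sampleBatches(trainTs, nPatientsPerBatch, seed = seed, epoch = epoch)
    epochLoss <- 0
    epochPairs <- 0L
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      X <- materializeBatch(trainTs, b)
      withSeed(deriveSeed(seed, 7000 + epoch * 131 + bi), {
        fe <- seqForward(encNet, X, training = TRUE, needGrad = TRUE)
        encNet <- fe$layers # batch-norm running stats advance
        fh <- seqForward(headNet, fe$out, training = TRUE, needGrad = TRUE)
        headNet <- fh$layers
        bl <- batchLoss(fh$out, b@pairIndex, lossCfg, gradient = TRUE)
        if (!is.finite(bl$loss)) {
          stop(sprintf("non-finite contrastive loss at epoch %d batch %d (lr %.4g)",
                       epoch, bi, lr))
        }
        bh <- seqBackward(headNet, fh$caches, bl$grad)
        be <- seqBackward(encNet, fe$caches, bh$dX)
        stepT <- stepT + 1L
        ah <- adamStep(headNet, bh$grads, headState, lr, stepT)
        headNet <- ah$layers; headState <- ah$state
        ae <- adamStep(encNet, be$grads, encState, lr, stepT)
        encNet <- ae$layers; encState <- ae$state
        epochLoss <- epochLoss + bl$loss
        epochPairs <- epochPairs + nrow(b@pairIndex)
      })
    }
    ## validation on held-out patients (inference mode, running BN stats)
    valBatches <- sampleBatches(valTs, nValBatch, seed = deriveSeed(seed, 501),
                                epoch = epoch)
    valLoss <- 0
    valPairs <- 0L
    for (b in valBatches) {
      X <- materializeBatch(valTs, b)
      h <- seqForward(encNet, X, training = FALSE, needGrad = FALSE)$out
      z <- seqForward(headNet, h, training = FALSE, needGrad = FALSE)$out
      valLoss <- valLoss + batchLoss(z, b@pairIndex, lossCfg)
      valPairs <- valPairs + nrow(b@pairIndex)
    }
    valLoss <- valLoss / valPairs
    trainLoss <- epochLoss / epochPairs
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 trainLoss = trainLoss, valLoss = valLoss))
    if (valLoss < best$valLoss) {
      best <- list(valLoss = valLoss, encNet = encNet, headNet = headNet,
                   epoch = epoch)
    }
  }
  encoder@net <- best$encNet
  head@net <- best$headNet
  new("PCLRFit", encoder = encoder, head = head, log = log,
      bestEpoch = as.integer(best$epoch),
      configs = list(encoder = unclass(encoderCfg),
                     projection = unclass(projectionCfg),
                     loss = unclass(lossCfg), train = unclass(trainCfg),
                     nPatientsPerBatch = nPatientsPerBatch,
                     validationPatients = sp$val))
}

## ---- supervised from-scratch baseline --------------------------------------

softmaxCE <- function(logits, yIdx) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), yIdx)], 1e-300)))
  d <- p
  d[cbind(seq_len(n), yIdx)] <- d[cbind(seq_len(n), yIdx)] - 1
  list(loss = loss, grad = d / n, prob = p)
}

mseLoss <- function(pred, y) {
  n <- length(y)
  r <- as.vector(pred) - y
  list(loss = mean(r^2), grad = matrix(2 * r / n, n, 1))
}

#' ScratchFit: supervised baseline trained from random initialization
#'
#' @slot encoder The trained [ECGEncoder-class] (best grid cell, best
#'   validation checkpoint).
#' @slot head List with the linear output layer.
#' @slot task `"classification"` or `"regression"`.
#' @slot grid `data.frame` with one row per (learning rate, dropout) cell:
#'   epochs run and best validation loss.
#' @slot selected List with the winning cell's `lr` and `dropout`.
#' @slot levels Class levels (classification) or `NULL`.
#' @export
setClass("ScratchFit",
  representation(encoder = "ECGEncoder", head = "list", task = "character",
                 grid = "data.frame", selected = "list", levels = "ANY"))

setMethod("show", "ScratchFit", function(object) {
  cat(sprintf("ScratchFit (%s): lr %.4g, dropout %.2f, val loss %.4f\n",
              object@task, object@selected$lr, object@selected$dropout,
              min(object@grid$bestValLoss)))
})

#' Train the same encoder from scratch on a labeled task
#'
#' The supervised baseline: the contrastive encoder architecture with a
#' linear output head (two softmax outputs and categorical cross-entropy for
#' classification; one output and mean squared error for regression),
#' trained with Adam for every cell of the (learning rate x dropout) grid,
#' early-stopping when the validation loss has not improved for `patience`
#' epochs and restoring each cell's best-validation checkpoint; the cell with
#' the lowest validation loss wins.
#'
#' @param tensorSet Labeled records as an [ECGTensorSet-class].
#' @param labels Vector aligned with the records: two-class factor/level
#'   vector for classification, numeric for regression.
#' @param task `"classification"` or `"regression"`.
#' @param encoderCfg An [encoderConfig()].
#' @param config A [scratchConfig()].
#' @param seed Integer seed.
#' @return A [ScratchFit-class].
#' @export
trainScratch <- function(tensorSet, labels, task = c("classification", "regression"),
                         encoderCfg, config = scratchConfig(), seed = 1L) {
  task <- match.arg(task)
  stopifnot(is(tensorSet, "ECGTensorSet"), length(labels) == nRecords(tensorSet))
  lv <- NULL
  if (task == "classification") {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) < 2) {
      pclrError("degenerate labels: a single class cannot be trained",
                "pclr_degenerate_labels")
    }
    if (length(lv) != 2) pclrError("classification head is binary (2 outputs)",
                                   "pclr_config_error")
    yIdx <- match(as.character(labels), lv)
  } else {
    labels <- as.numeric(labels)
  }
  n <- nRecords(tensorSet)
  nVal <- max(1L, round(config$validationFraction * n))
  if (nVal >= n) pclrError("not enough records for a train/validation split",
                           "pclr_validation_error")
  valIdx <- withSeed(deriveSeed(seed, 31), sample(n, nVal))
  trIdx <- setdiff(seq_len(n), valIdx)
  Xall <- aperm(tensorSet@tensors, c(3, 1, 2))

  cells <- expand.grid(lr = config$lrGrid, dropout = config$dropoutGrid)
  gridLog <- data.frame()
  best <- list(valLoss = Inf)

  for (ci in seq_len(nrow(cells))) {
    lr <- cells$lr[ci]
    dropout <- cells$dropout[ci]
    encoder <- buildEncoder(encoderCfg, seed = deriveSeed(seed, 40 + ci),
                            dropoutRate = dropout)
    encNet <- encoder@net
    headNet <- withSeed(deriveSeed(seed, 60 + ci), list(
      layerDense(encoderCfg$representationDim,
                 if (task == "classification") 2L else 1L)))
    encState <- NULL; headState <- NULL; stepT <- 0L
    cellBest <- list(valLoss = Inf, encNet = encNet, headNet = headNet)
    sinceImprove <- 0L
    epochsRun <- 0L
    for (epoch in seq_len(config$maxEpochs)) {
      epochsRun <- epoch
      ord <- withSeed(deriveSeed(seed, 1000 * ci + epoch), sample(trIdx))
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + config$batchSize - 1L, length(ord))
        idx <- ord[i:j]
        withSeed(deriveSeed(seed, 90000 + 997 * ci + 31 * epoch + i), {
          fe <- seqForward(encNet, Xall[idx, , , drop = FALSE],
                           training = TRUE, needGrad = TRUE)
          encNet <- fe$layers
          fh <- seqForward(headNet, fe$out, training = TRUE, needGrad = TRUE)
          headNet <- fh$layers
          lres <- if (task == "classification") softmaxCE(fh$out, yIdx[idx])
                  else mseLoss(fh$out, labels[idx])
          if (!is.finite(lres$loss)) {
            stop(sprintf("non-finite supervised loss (cell %d, epoch %d)", ci, epoch))
          }
          bh <- seqBackward(headNet, fh$caches, lres$grad)
          be <- seqBackward(encNet, fe$caches, bh$dX)
          stepT <- stepT + 1L
          ah <- adamStep(headNet, bh$grads, headState, lr, stepT)
          headNet <- ah$layers; headState <- ah$state
          ae <- adamStep(encNet, be$grads, encState, lr, stepT)
          encNet <- ae$layers; encState <- ae$state
        })
        i <- j + 1L
      }
      ## validation loss (inference mode)
      hv <- seqForward(encNet, Xall[valIdx, , , drop = FALSE],
                       training = FALSE, needGrad = FALSE)$out
      ov <- seqForward(headNet, hv, training = FALSE, needGrad = FALSE)$out
      vloss <- if (task == "classification") softmaxCE(ov, yIdx[valIdx])$loss
               else mseLoss(ov, labels[valIdx])$loss
      if (vloss < cellBest$valLoss - 1e-12) {
        cellBest <- list(valLoss = vloss, encNet = encNet, headNet = headNet)
        sinceImprove <- 0L
      } else {
        sinceImprove <- sinceImprove + 1L
        if (sinceImprove >= config$patience) break
      }
    }
    gridLog <- rbind(gridLog, data.frame(lr = lr, dropout = dropout,
                                         epochs = epochsRun,
                                         bestValLoss = cellBest$valLoss))
    if (cellBest$valLoss < best$valLoss) {
      best <- list(valLoss = cellBest$valLoss, encNet = cellBest$encNet,
                   headNet = cellBest$headNet, lr = lr, dropout = dropout)
    }
  }
  encoder <- buildEncoder(encoderCfg, seed = seed)
  encoder@net <- best$encNet
  new("ScratchFit", encoder = encoder, head = best$headNet, task = task,
      grid = gridLog, selected = list(lr = best$lr, dropout = best$dropout),
      levels = lv)
}

#' Predict with a from-scratch model
#'
#' @param fit A [ScratchFit-class].
#' @param tensorSet Records to predict.
#' @param batchSize Records per forward chunk.
#' @return Classification: character vector of predicted class levels;
#'   regression: numeric predictions.
#' @export
predictScratch <- function(fit, tensorSet, batchSize = 64L) {
  stopifnot(is(fit, "ScratchFit"))
  h <- encode(fit@encoder, tensorSet, batchSize = batchSize)
  out <- seqForward(fit@head, h, training = FALSE, needGrad = FALSE)$out
  if (fit@task == "classification") fit@levels[max.col(out)] else as.vector(out)
}

#' Projection alignment on held-out data
#'
#' Mean cosine similarity of projections within same-patient record pairs
#' versus across different-patient pairs; after pre-training the former
#' should exceed the latter.
#'
#' @param fit A [PCLRFit-class].
#' @param tensorSet Held-out records (>= 2 patients, some with >= 2 records).
#' @return `list(within =, between =)` mean cosine similarities.
#' @export
alignmentStats <- function(fit, tensorSet) {
  stopifnot(is(fit, "PCLRFit"))
  h <- encode(fit@encoder, tensorSet)
  z <- project(fit@head, h)
  U <- normalizeRows(z)
  S <- tcrossprod(U)
  same <- outer(tensorSet@patientIds, tensorSet@patientIds, "==")
  diag(same) <- NA
  ut <- upper.tri(S)
  list(within = mean(S[ut & !is.na(same) & same]),
       between = mean(S[ut & !is.na(same) & !same]))
}
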