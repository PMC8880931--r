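## Linear-evaluation protocol on frozen representations:
##   1. encode records into an n x representation_dim feature table and
##      normalize each column with the TRAINING mean/sd;
##   2. fit a linear (regression) or logistic (classification) ridge model,
##      selecting the l2 penalty from 10 log-evenly spaced values between
##      1e-6 and 1e5 by seeded 4-fold cross-validation on the task metric;
##   3. evaluate on holdout rows normalized with the training statistics,
##      reporting the point estimate +/- the SD over seeded bootstrap
##      resamples of the holdout set.

SD_FLOOR <- 1e-12

#' The l2 penalty grid
#'
#' Ten values logarithmically evenly spaced between 1e-6 and 1e5 (both
#' endpoints included), i.e. `10^(-6 + 11k/9)` for `k = 0 ... 9`; consecutive
#' values are a factor `10^(11/9) ~ 16.68` apart.
#'
#' @return Numeric vector of length 10.
#' @export
penaltyGrid <- function() {
  10^seq(-6, 5, length.out = 10)
}

#' Extract a feature table from an encoder
#'
#' Applies the (typically pre-trained) encoder to preprocessed records and
#' returns one feature row per record, in input order, with
#' `representationDim` columns. The table is unnormalized; see
#' [normalizeFeatures()].
#'
#' @param encoder An [ECGEncoder-class].
#' @param tensorSet An [ECGTensorSet-class].
#' @param batchSize Records per forward chunk.
#' @return A [FeatureTable-class].
#' @export
extractFeatures <- function(encoder, tensorSet, batchSize = 64L) {
  stopifnot(is(encoder, "ECGEncoder"), is(tensorSet, "ECGTensorSet"))
  n <- nRecords(tensorSet)
  f <- if (n == 0) {
    matrix(0, 0, encoder@config$representationDim)
  } else {
    encode(encoder, tensorSet, batchSize = batchSize)
  }
  new("FeatureTable", features = f, recordIds = recordIds(tensorSet),
      normStats = list(), normalized = FALSE)
}

#' Normalize feature columns
#'
#' `normalizeFeatures()` learns per-column mean and standard deviation on a
#' *training* table and applies them; `normalizeWith()` applies a training
#' table's statistics to a holdout table (holdout rows are never normalized
#' with their own statistics). Constant columns get a standard-deviation
#' floor of 1e-12.
#'
#' @param x The [FeatureTable-class] to normalize.
#' @param train A normalized training [FeatureTable-class] carrying
#'   statistics.
#' @return A normalized [FeatureTable-class] carrying the training
#'   statistics.
#' @export
normalizeFeatures <- function(x) {
  stopifnot(is(x, "FeatureTable"))
  mu <- colMeans(x@features)
  sdv <- apply(x@features, 2, sd)
  if (any(!is.finite(sdv)) || nrow(x@features) < 2) {
    pclrError("need >= 2 rows to learn normalization statistics",
              "pclr_config_error")
  }
  sdv <- pmax(sdv, SD_FLOOR)
  f <- sweep(sweep(x@features, 2, mu, "-"), 2, sdv, "/")
  new("FeatureTable", features = f, recordIds = x@recordIds,
      normStats = list(mean = mu, sd = sdv), normalized = TRUE)
}

#' @rdname normalizeFeatures
#' @export
normalizeWith <- function(x, train) {
  stopifnot(is(x, "FeatureTable"), is(train, "FeatureTable"))
  if (!train@normalized || !length(train@normStats)) {
    pclrError("training table carries no normalization statistics",
              "pclr_config_error")
  }
  st <- train@normStats
  if (length(st$mean) != ncol(x@features)) {
    pclrError("feature width mismatch between holdout and training tables",
              "pclr_width_mismatch")
  }
  f <- sweep(sweep(x@features, 2, st$mean, "-"), 2, st$sd, "/")
  new("FeatureTable", features = f, recordIds = x@recordIds,
      normStats = st, normalized = TRUE)
}

## Ridge regression via SVD: coefficients for every penalty in one pass.
## X is assumed column-normalized; y is centered internally; the intercept
## is unpenalized (it equals mean(y) for centered X).
ridgePath <- function(X, y, lambdas) {
  ybar <- mean(y)
  sv <- svd(X)
  uty <- crossprod(sv$u, y - ybar)
  sapply(lambdas, function(l) {
    sv$v %*% (sv$d / (sv$d^2 + l) * uty)
  })
}

## Logistic ridge by damped Newton iterations (IRLS); intercept unpenalized.
## Minimizes -loglik + (lambda/2) ||beta||^2.
logisticRidge <- function(X, y01, lambda, maxIter = 50, tol = 1e-9) {
  n <- nrow(X); d <- ncol(X)
  beta <- numeric(d); b0 <- 0
  for (it in seq_len(maxIter)) {
    eta <- as.vector(X %*% beta) + b0
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    g <- c(sum(p - y01), crossprod(X, p - y01) + lambda * beta)
    Xw <- X * w
    H <- rbind(c(sum(w), colSums(Xw)),
               cbind(colSums(Xw), crossprod(X, Xw) + diag(lambda, d)))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) step <- solve(H + diag(1e-8, d + 1), g)
    b0 <- b0 - step[1]
    beta <- beta - step[-1]
    if (max(abs(step)) < tol) break
  }
  list(coef = beta, intercept = b0)
}

#' Fit a ridge-regularized linear probe
#'
#' Trains a linear (regression) or logistic (classification) ridge model on
#' a normalized training feature table. The l2 penalty is selected from the
#' 10-value grid of [penaltyGrid()] by seeded 4-fold cross-validation scored
#' with the task metric (f1 of the positive class, or r-squared), then the
#' probe is refit on all training rows at the selected penalty.
#'
#' @param train A normalized training [FeatureTable-class].
#' @param labels Vector aligned with the rows: two-class for classification,
#'   numeric for regression.
#' @param task `"classification"` or `"regression"`.
#' @param seed Integer seed for the fold assignment.
#' @param nFolds Number of CV folds (default 4).
#' @param positive Label treated as the positive class for f1 (default: the
#'   lexicographically larger of the two levels).
#' @return A [LinearProbe-class].
#' @export
fitProbe <- function(train, labels, task = c("classification", "regression"),
                     seed = 1L, nFolds = 4L, positive = NULL) {
  task <- match.arg(task)
  stopifnot(is(train, "FeatureTable"))
  if (!train@normalized) {
    pclrError("training table must be normalized before fitting",
              "pclr_config_error")
  }
  X <- train@features
  n <- nrow(X)
  if (n < nFolds) {
    pclrError(sprintf("fewer rows (%d) than folds (%d)", n, nFolds),
              "pclr_config_error")
  }
  lambdas <- penaltyGrid()
  if (task == "classification") {
    lv <- sort(unique(as.character(labels)))
    if (length(lv) < 2) {
      pclrError("single-class labels cannot be fit", "pclr_degenerate_labels")
    }
    if (length(lv) != 2) pclrError("probe is binary", "pclr_config_error")
    if (is.null(positive)) positive <- lv[2]
    y01 <- as.integer(as.character(labels) == positive)
  } else {
    y <- as.numeric(labels)
  }
  folds <- withSeed(deriveSeed(seed, 71),
                    sample(rep(seq_len(nFolds), length.out = n)))
  scores <- matrix(NA_real_, nFolds, length(lambdas))
  for (f in seq_len(nFolds)) {
    tr <- folds != f
    te <- !tr
    if (task == "regression") {
      B <- ridgePath(X[tr, , drop = FALSE], y[tr], lambdas)
      for (k in seq_along(lambdas)) {
        pred <- X[te, , drop = FALSE] %*% B[, k] + mean(y[tr])
        scores[f, k] <- r2Score(y[te], as.vector(pred))
      }
    } else {
      for (k in seq_along(lambdas)) {
        fitk <- logisticRidge(X[tr, , drop = FALSE], y01[tr], lambdas[k])
        eta <- as.vector(X[te, , drop = FALSE] %*% fitk$coef) + fitk$intercept
        scores[f, k] <- f1Score(y01[te], as.integer(eta > 0), positive = 1)
      }
    }
  }
  meanScore <- colMeans(scores)
  kBest <- which.max(meanScore) # ties: smaller penalty (first index) wins
  lambda <- lambdas[kBest]
  if (task == "regression") {
    co <- as.vector(ridgePath(X, y, lambda))
    probe <- new("LinearProbe", task = task, coef = co, intercept = mean(y),
                 selectedPenalty = lambda,
                 cvScores = data.frame(penalty = lambdas, meanScore = meanScore),
                 positive = NULL)
  } else {
    fitb <- logisticRidge(X, y01, lambda)
    probe <- new("LinearProbe", task = task, coef = fitb$coef,
                 intercept = fitb$intercept, selectedPenalty = lambda,
                 cvScores = data.frame(penalty = lambdas, meanScore = meanScore),
                 positive = positive)
  }
  probe
}

#' Predict with a linear probe
#'
#' @param probe A [LinearProbe-class].
#' @param holdout A [FeatureTable-class] normalized with the training
#'   statistics ([normalizeWith()]).
#' @return Classification: vector of predicted labels (positive label or
#'   `"not_<positive>"` complement when the negative level is unknown);
#'   regression: numeric predictions.
#' @export
predictProbe <- function(probe, holdout) {
  stopifnot(is(probe, "LinearProbe"), is(holdout, "FeatureTable"))
  if (!holdout@normalized) {
    pclrError("holdout table must be normalized with training statistics",
              "pclr_config_error")
  }
  eta <- as.vector(holdout@features %*% probe@coef) + probe@intercept
  if (probe@task == "regression") eta else as.integer(eta > 0)
}

#' Evaluate a probe on holdout data
#'
#' Computes the point estimate of the task metric (positive-class f1 or
#' r-squared) on the full holdout set, plus the standard deviation of the
#' metric over seeded bootstrap resamples (with replacement, same size as
#' the holdout). A classification resample containing a single truth class
#' is redrawn (and the occurrence counted).
#'
#' @param probe A [LinearProbe-class].
#' @param holdout A [FeatureTable-class] normalized with training statistics.
#' @param labels Holdout truth, aligned with the rows.
#' @param nBootstraps Number of resamples (default 1,000).
#' @param seed Integer seed.
#' @return A [ProbeResult-class].
#' @export
evaluateProbe <- function(probe, holdout, labels, nBootstraps = 1000L,
                          seed = 1L) {
  stopifnot(nBootstraps >= 1)
  if (probe@task == "classification") {
    truth <- as.integer(as.character(labels) == probe@positive)
    pred <- predictProbe(probe, holdout)
    metric <- "f1"
    point <- f1Score(truth, pred, positive = 1)
  } else {
    truth <- as.numeric(labels)
    pred <- predictProbe(probe, holdout)
    metric <- "r2"
    point <- r2Score(truth, pred)
  }
  n <- length(truth)
  redraws <- 0L
  vals <- withSeed(deriveSeed(seed, 81), {
    v <- numeric(nBootstraps)
    for (b in seq_len(nBootstraps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (metric == "f1" && length(unique(truth[idx])) < 2) {
          redraws <- redraws + 1L
          next
        }
        break
      }
      v[b] <- if (metric == "f1") f1Score(truth[idx], pred[idx], positive = 1)
              else r2Score(truth[idx], pred[idx])
    }
    v
  })
  if (redraws > 0) {
    message(sprintf("%d single-class bootstrap resample(s) redrawn", redraws))
  }
  new("ProbeResult", task = probe@task, metric = metric,
      pointEstimate = point, bootstrapSD = sd(vals),
      nBootstraps = as.integer(nBootstraps),
      selectedPenalty = probe@selectedPenalty,
      predictions = pred, truth = truth, recordIds = recordIds(holdout))
}

#' Score fixed predictions as a ProbeResult
#'
#' Wraps an arbitrary model's holdout predictions in a
#' [ProbeResult-class] (point estimate plus seeded bootstrap SD) so that
#' non-probe models -- e.g. a supervised from-scratch network -- can enter
#' [compareModels()] on the same footing as linear probes.
#'
#' @param predictions Holdout predictions: 0/1 for classification (1 =
#'   positive class), numeric for regression.
#' @param truth Holdout truth on the same coding.
#' @param task `"classification"` or `"regression"`.
#' @param recordIds Holdout record identifiers.
#' @param nBootstraps Number of resamples (default 1,000).
#' @param seed Integer seed.
#' @return A [ProbeResult-class].
#' @export
scorePredictions <- function(predictions, truth,
                             task = c("classification", "regression"),
                             recordIds = as.character(seq_along(truth)),
                             nBootstraps = 1000L, seed = 1L) {
  task <- match.arg(task)
  metric <- if (task == "classification") "f1" else "r2"
  point <- if (metric == "f1") f1Score(truth, predictions, positive = 1)
           else r2Score(truth, predictions)
  n <- length(truth)
  vals <- withSeed(deriveSeed(seed, 81), {
    v <- numeric(nBootstraps)
    for (b in seq_len(nBootstraps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (metric == "f1" && length(unique(truth[idx])) < 2) next
        break
      }
      v[b] <- if (metric == "f1") f1Score(truth[idx], predictions[idx], positive = 1)
              else r2Score(truth[idx], predictions[idx])
    }
    v
  })
  new("ProbeResult", task = task, metric = metric, pointEstimate = point,
      bootstrapSD = sd(vals), nBootstraps = as.integer(nBootstraps),
      selectedPenalty = NA_real_, predictions = predictions, truth = truth,
      recordIds = recordIds)
}

#' Compare models on shared bootstrap resamples
#'
#' Paired bootstrap comparison of several [ProbeResult-class] objects
#' evaluated on the same holdout records: the same seeded resample indices
#' are applied to every model, the model with the highest point estimate is
#' flagged best, and any other model whose paired metric difference is
#' within one standard deviation of zero (over the shared resamples) is
#' flagged as tied for best.
#'
#' @param results Named list of [ProbeResult-class] objects with identical
#'   holdout records and truth.
#' @param nBootstraps Number of shared resamples (default 1,000).
#' @param seed Integer seed.
#' @return `data.frame(model, estimate, bootstrapSD, best)` sorted by
#'   estimate.
#' @export
compareModels <- function(results, nBootstraps = 1000L, seed = 1L) {
  stopifnot(is.list(results), length(results) >= 2)
  if (is.null(names(results)) || any(!nzchar(names(results)))) {
    names(results) <- paste0("model", seq_along(results))
  }
  r1 <- results[[1]]
  for (r in results) {
    stopifnot(is(r, "ProbeResult"))
    if (!identical(r@recordIds, r1@recordIds) ||
        !isTRUE(all.equal(r@truth, r1@truth)) || r@metric != r1@metric) {
      pclrError("models must be evaluated on the same holdout records",
                "pclr_config_error")
    }
  }
  metric <- r1@metric
  truth <- r1@truth
  n <- length(truth)
  scoreFn <- if (metric == "f1") {
    function(t, p) f1Score(t, p, positive = 1)
  } else r2Score
  M <- withSeed(deriveSeed(seed, 91), {
    m <- matrix(NA_real_, nBootstraps, length(results))
    for (b in seq_len(nBootstraps)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (metric == "f1" && length(unique(truth[idx])) < 2) next
        break
      }
      for (j in seq_along(results)) {
        m[b, j] <- scoreFn(truth[idx], results[[j]]@predictions[idx])
      }
    }
    m
  })
  est <- vapply(results, function(r) r@pointEstimate, 0)
  bsd <- apply(M, 2, sd)
  jBest <- which.max(est)
  best <- logical(length(results))
  best[jBest] <- TRUE
  for (j in seq_along(results)) {
    if (j == jBest) next
    d <- M[, jBest] - M[, j]
    best[j] <- abs(mean(d)) <= sd(d) # zero difference within +/- 1 SD: a tie
  }
  out <- data.frame(model = names(results), estimate = est, bootstrapSD = bsd,
                    best = best, row.names = NULL)
  out[order(-out$estimate), ]
}

#' Persist / load a feature table
#'
#' CSV with a `record_id` column followed by the feature columns.
#'
#' @param x A [FeatureTable-class].
#' @param path CSV file path.
#' @return `writeFeatureTable()` returns `path` invisibly; `readFeatureTable()`
#'   an (unnormalized) [FeatureTable-class].
#' @export
writeFeatureTable <- function(x, path) {
  stopifnot(is(x, "FeatureTable"))
  f <- x@features
  colnames(f) <- paste0("f", seq_len(ncol(f)))
  df <- data.frame(record_id = x@recordIds, f)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!"record_id" %in% names(df)) {
    pclrError("feature table file lacks a record_id column", "pclr_parse_error")
  }
  f <- as.matrix(df[, setdiff(names(df), "record_id"), drop = FALSE])
  new("FeatureTable", features = f, recordIds = as.character(df$record_id),
      normStats = list(), normalized = FALSE)
}
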