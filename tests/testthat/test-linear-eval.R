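makeTable <- function(X, ids = sprintf("R%03d", seq_len(nrow(X)))) {
  new("FeatureTable", features = X, recordIds = ids,
      normStats = list(), normalized = FALSE)
}

test_that("the penalty grid spans 1e-6 to 1e5 in ten log-even steps", {
  g <- penaltyGrid()
  expect_length(g, 10L)
  expect_equal(g[1], 1e-6)
  expect_equal(g[10], 1e5)
  ratios <- g[-1] / g[-10]
  expect_equal(ratios, rep(10^(11 / 9), 9), tolerance = 1e-12)
})

test_that("feature extraction has the contracted shape and determinism", {
  cfg <- encoderConfig(inputLength = 128, channelsPerStage = c(4, 8),
                       downsamplePerBlock = 4, stemPool = 2)
  enc <- buildEncoder(cfg, seed = 4)
  set.seed(5)
  arr <- array(rnorm(128 * 12 * 5), c(128, 12, 5))
  arr[, , 4] <- arr[, , 2] # duplicate record
  ts <- new("ECGTensorSet", tensors = arr, recordIds = sprintf("R%d", 1:5),
            patientIds = sprintf("P%d", 1:5))
  ft <- extractFeatures(enc, ts)
  expect_equal(dim(features(ft)), c(5L, 8L))
  expect_equal(recordIds(ft), recordIds(ts))
  expect_equal(features(ft)[4, ], features(ft)[2, ])
  empty <- extractFeatures(enc, subsetTensorSet(ts, integer(0)))
  expect_equal(dim(features(empty)), c(0L, 8L))
})

test_that("normalization learns training statistics and never the holdout's", {
  set.seed(6)
  Xtr <- matrix(rnorm(40 * 6, mean = 2, sd = 3), 40, 6)
  Xho <- matrix(rnorm(20 * 6, mean = -5, sd = 10), 20, 6)
  tr <- normalizeFeatures(makeTable(Xtr))
  expect_equal(colMeans(features(tr)), rep(0, 6), tolerance = 1e-12)
  expect_equal(apply(features(tr), 2, sd), rep(1, 6), tolerance = 1e-12)
  ho <- normalizeWith(makeTable(Xho), tr)
  expect_equal(ho@normStats, tr@normStats)
  # corrupting holdout rows must not change the stored statistics
  Xho2 <- Xho; Xho2[1, ] <- 1e6
  ho2 <- normalizeWith(makeTable(Xho2), tr)
  expect_identical(ho2@normStats, tr@normStats)
  expect_equal(features(ho2)[-1, ], features(ho)[-1, ])
  # holdout normalized with its own stats would differ
  own <- normalizeFeatures(makeTable(Xho))
  expect_false(isTRUE(all.equal(features(own), features(ho))))
  # constant columns are floored, not fatal
  Xc <- Xtr; Xc[, 3] <- 7
  expect_true(all(is.finite(features(normalizeFeatures(makeTable(Xc))))))
})

test_that("ridge solutions match the closed-form oracle at every grid penalty", {
  set.seed(7)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  B <- pclr:::ridgePath(X, y, penaltyGrid())
  for (k in seq_along(penaltyGrid())) {
    expect_equal(as.vector(B[, k]),
                 as.vector(ridgeOracle(X, y, penaltyGrid()[k])),
                 tolerance = 1e-8)
  }
})

test_that("noise-free linear labels select the grid minimum penalty", {
  set.seed(8)
  X <- matrix(rnorm(60 * 8), 60, 8)
  tr <- normalizeFeatures(makeTable(X))
  beta <- rnorm(8)
  y <- as.vector(features(tr) %*% beta) + 2
  probe <- fitProbe(tr, y, "regression", seed = 3)
  expect_equal(probe@selectedPenalty, 1e-6)
  pred <- predictProbe(probe, tr)
  expect_gt(r2Score(y, pred), 0.999)
})

test_that("cross-validation is deterministic in the seed", {
  set.seed(9)
  X <- matrix(rnorm(48 * 6), 48, 6)
  tr <- normalizeFeatures(makeTable(X))
  y <- as.integer(X[, 1] + rnorm(48, sd = 0.5) > 0)
  p1 <- fitProbe(tr, y, "classification", seed = 11)
  p2 <- fitProbe(tr, y, "classification", seed = 11)
  expect_identical(p1@selectedPenalty, p2@selectedPenalty)
  expect_identical(p1@cvScores, p2@cvScores)
  expect_identical(p1@coef, p2@coef)
})

test_that("logistic ridge agrees with glmnet on a shared problem", {
  skip_if_not_installed("glmnet")
  set.seed(10)
  n <- 200; d <- 5
  X <- matrix(rnorm(n * d), n, d)
  y <- as.integer(X[, 1] - 0.5 * X[, 2] + rnorm(n, sd = 0.8) > 0)
  lambda <- 3
  mine <- pclr:::logisticRidge(X, y, lambda)
  gl <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = lambda / n, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(mine$coef, as.vector(gl$beta), tolerance = 1e-3)
  expect_equal(mine$intercept, as.numeric(gl$a0), tolerance = 1e-3)
})

test_that("probe evaluation reproduces hand-computed metrics", {
  # perfect predictions: f1 = 1 with zero bootstrap spread
  probeLike <- scorePredictions(rep(c(1, 0), 10), rep(c(1, 0), 10),
                                "classification", nBootstraps = 50, seed = 1)
  expect_equal(probeLike@pointEstimate, 1)
  expect_equal(probeLike@bootstrapSD, 0)
  # TP=2, FP=1, FN=1: f1 = 2/3
  truth <- c(1, 1, 1, 0, 0, 0)
  pred <- c(1, 1, 0, 1, 0, 0)
  r <- scorePredictions(pred, truth, "classification", nBootstraps = 10, seed = 1)
  expect_equal(r@pointEstimate, 2 / 3)
  # predicting the label mean gives r2 = 0
  y <- rnorm(30)
  r2 <- scorePredictions(rep(mean(y), 30), y, "regression",
                         nBootstraps = 10, seed = 1)
  expect_equal(r2@pointEstimate, 0, tolerance = 1e-12)
})

test_that("errors are raised for degenerate probe inputs", {
  X <- matrix(rnorm(12), 3, 4)
  tr <- suppressWarnings(normalizeFeatures(makeTable(X)))
  expect_error(fitProbe(tr, c(1, 0, 1), "classification", seed = 1),
               class = "pclr_config_error") # fewer rows than folds
  X2 <- matrix(rnorm(40), 10, 4)
  tr2 <- normalizeFeatures(makeTable(X2))
  expect_error(fitProbe(tr2, rep(1, 10), "classification", seed = 1),
               class = "pclr_degenerate_labels")
  expect_error(fitProbe(makeTable(X2), rnorm(10), "regression", seed = 1),
               class = "pclr_config_error") # unnormalized table
})

test_that("model comparison flags match a brute-force paired bootstrap", {
  set.seed(12)
  n <- 60
  truth <- rep(c(1, 0), n / 2)
  predGood <- truth; predGood[sample(n, 6)] <- 1 - predGood[sample(n, 6)]
  predMid <- truth; predMid[sample(n, 18)] <- 1 - predMid[sample(n, 18)]
  predSame <- predMid
  rs <- list(
    good = scorePredictions(predGood, truth, "classification", nBootstraps = 200, seed = 4),
    mid = scorePredictions(predMid, truth, "classification", nBootstraps = 200, seed = 4),
    same = scorePredictions(predSame, truth, "classification", nBootstraps = 200, seed = 4)
  )
  cmp <- compareModels(rs, nBootstraps = 200, seed = 9)
  # identical prediction sets must share the best flag state
  expect_equal(cmp$best[cmp$model == "mid"], cmp$best[cmp$model == "same"])

  # brute-force recomputation over the same seeded resamples
  bf <- pclr:::withSeed(pclr:::deriveSeed(9, 91), {
    M <- matrix(NA_real_, 200, 3)
    preds <- list(predGood, predMid, predSame)
    for (b in 1:200) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(truth[idx])) < 2) next
        break
      }
      for (j in 1:3) M[b, j] <- f1Score(truth[idx], preds[[j]][idx], positive = 1)
    }
    M
  })
  est <- vapply(rs, function(r) r@pointEstimate, 0)
  jBest <- which.max(est)
  flags <- logical(3); flags[jBest] <- TRUE
  for (j in seq_len(3)) {
    if (j == jBest) next
    d <- bf[, jBest] - bf[, j]
    flags[j] <- abs(mean(d)) <= sd(d)
  }
  expect_equal(cmp$best[match(names(rs), cmp$model)], flags)

  # a strictly dominating model is uniquely flagged
  rs2 <- list(a = rs$good, b = scorePredictions(1 - truth, truth, "classification",
                                                nBootstraps = 100, seed = 4))
  cmp2 <- compareModels(rs2, nBootstraps = 100, seed = 2)
  expect_equal(sum(cmp2$best), 1L)
  expect_true(cmp2$best[cmp2$model == "a"])

  # mismatched holdout sets are rejected
  short <- scorePredictions(predGood[1:30], truth[1:30], "classification",
                            nBootstraps = 10, seed = 1)
  expect_error(compareModels(list(rs$good, short), nBootstraps = 10, seed = 1),
               class = "pclr_config_error")
})

test_that("feature tables persist through CSV", {
  dir <- withr::local_tempdir()
  set.seed(13)
  ft <- makeTable(matrix(rnorm(24), 6, 4))
  p <- file.path(dir, "features.csv")
  writeFeatureTable(ft, p)
  back <- readFeatureTable(p)
  expect_equal(features(back), features(ft), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(recordIds(back), recordIds(ft))
})
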