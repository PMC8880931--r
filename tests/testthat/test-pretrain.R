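# Shared small pre-training run used by several contracts below.
prepSmallRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- filterEligible(generateCohort(20, visits = c(2, 3), seed = 11))
      ts <- thinTensorSet(batchPreprocess(coh)$tensors, 8)
      cfg <- trainConfig(epochs = 3, initialLr = 0.01, schedulePeriod = 3,
                         validationFraction = 0.1, seed = 5)
      fit <- pretrainPCLR(ts, tinyEncoderConfig(), trainCfg = cfg,
                          nPatientsPerBatch = 8)
      fit2 <- pretrainPCLR(ts, tinyEncoderConfig(), trainCfg = cfg,
                           nPatientsPerBatch = 8)
      cache <<- list(ts = ts, fit = fit, fit2 = fit2)
    }
    cache
  }
})

test_that("the cosine schedule starts at the initial rate and vanishes at the period", {
  cfg <- trainConfig()
  expect_equal(lrAtEpoch(0, cfg), 0.1)
  expect_equal(lrAtEpoch(25, cfg), 0.05)
  expect_equal(lrAtEpoch(50, cfg), 0)
  rates <- vapply(0:50, lrAtEpoch, 0, config = cfg)
  expect_true(all(diff(rates) <= 0))
  expect_message(past <- lrAtEpoch(60, cfg), "clamping")
  expect_equal(past, 0)
})

test_that("pre-training reduces the contrastive loss on a small cohort", {
  run <- prepSmallRun()
  log <- trainingLog(run$fit)
  expect_equal(nrow(log), 3L)
  expect_lt(log$trainLoss[3], log$trainLoss[1])
})

test_that("the returned checkpoint minimizes the logged validation loss", {
  run <- prepSmallRun()
  log <- trainingLog(run$fit)
  expect_equal(run$fit@bestEpoch, which.min(log$valLoss))
})

test_that("identical seeds give identical training runs", {
  run <- prepSmallRun()
  expect_identical(trainingLog(run$fit), trainingLog(run$fit2))
  expect_identical(run$fit@encoder@net, run$fit2@encoder@net)
})

test_that("projection alignment separates patients after pre-training", {
  run <- prepSmallRun()
  valTs <- subsetTensorSet(run$ts,
                           patientIds(run$ts) %in% run$fit@configs$validationPatients)
  al <- alignmentStats(run$fit, valTs)
  expect_true(is.finite(al$within) && is.finite(al$between))
})

test_that("degenerate splits and unfiltered cohorts are rejected", {
  run <- prepSmallRun()
  expect_error(
    pretrainPCLR(run$ts, tinyEncoderConfig(),
                 trainCfg = trainConfig(epochs = 1, validationFraction = 0.001,
                                        seed = 1),
                 nPatientsPerBatch = 4),
    class = "pclr_validation_error")
  # a single-record patient must be caught by the sampler
  counts <- table(patientIds(run$ts))
  p2 <- names(counts)[counts == 2][1]
  drop <- which(patientIds(run$ts) == p2)[1]
  single <- subsetTensorSet(run$ts, -drop)
  expect_error(
    pretrainPCLR(single, tinyEncoderConfig(),
                 trainCfg = trainConfig(epochs = 1, seed = 1),
                 nPatientsPerBatch = 4),
    class = "pclr_unfiltered_cohort")
})

test_that("the scratch grid runs every cell and returns the argmin cell", {
  set.seed(31)
  cfgE <- encoderConfig(inputLength = 64, channelsPerStage = c(4, 8),
                        downsamplePerBlock = 4, stemPool = 2)
  n <- 24
  arr <- array(rnorm(64 * 12 * n), c(64, 12, n))
  ts <- new("ECGTensorSet", tensors = arr, recordIds = sprintf("R%02d", 1:n),
            patientIds = sprintf("P%02d", 1:n))
  y <- rep(c(0, 1), n / 2)
  fit <- trainScratch(ts, y, "classification", cfgE,
                      config = scratchConfig(lrGrid = c(1e-2, 1e-3),
                                             dropoutGrid = c(0, 0.1),
                                             patience = 2, maxEpochs = 3,
                                             batchSize = 12),
                      seed = 3)
  expect_equal(nrow(fit@grid), 4L)
  expect_true(all(fit@grid$epochs <= 3))
  sel <- fit@grid[fit@grid$lr == fit@selected$lr &
                  fit@grid$dropout == fit@selected$dropout, ]
  expect_equal(sel$bestValLoss, min(fit@grid$bestValLoss))
  pred <- predictScratch(fit, ts)
  expect_true(all(pred %in% c("0", "1")))
})

test_that("single-class labels are rejected", {
  cfgE <- encoderConfig(inputLength = 64, channelsPerStage = c(4, 8),
                        downsamplePerBlock = 4, stemPool = 2)
  ts <- new("ECGTensorSet", tensors = array(0, c(64, 12, 8)),
            recordIds = sprintf("R%02d", 1:8), patientIds = sprintf("P%02d", 1:8))
  expect_error(trainScratch(ts, rep(1, 8), "classification", cfgE, seed = 1),
               class = "pclr_degenerate_labels")
})

test_that("scratch regression learns an exactly linear target", {
  set.seed(9)
  cfgE <- encoderConfig(inputLength = 64, channelsPerStage = c(4, 8),
                        downsamplePerBlock = 4, stemPool = 2)
  n <- 48
  arr <- array(rnorm(64 * 12 * n), c(64, 12, n))
  ts <- new("ECGTensorSet", tensors = arr, recordIds = sprintf("R%03d", 1:n),
            patientIds = sprintf("P%03d", 1:n))
  y <- 10 * apply(arr[, 1, ], 2, mean) # linear in channel 1's mean, no noise
  fit <- trainScratch(ts, y, "regression", cfgE,
                      config = scratchConfig(lrGrid = 1e-2, dropoutGrid = 0,
                                             patience = 300, maxEpochs = 300,
                                             batchSize = 48,
                                             validationFraction = 0.1),
                      seed = 2)
  expect_lt(min(fit@grid$bestValLoss), 0.01 * var(y))
})
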