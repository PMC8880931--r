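test_that("eligibility filtering keeps exactly the multi-record patients", {
  # build a cohort with record counts 1, 2, 5 by concatenating generated parts
  c1 <- generateCohort(1, visits = 1, seed = 101)
  c2 <- generateCohort(1, visits = 2, seed = 102)
  c5 <- generateCohort(1, visits = 5, seed = 103)
  relabel <- function(coh, pid) {
    for (i in seq_along(coh@records)) {
      coh@records[[i]]$patientId <- pid
      coh@records[[i]]$recordId <- paste0(pid, "_E", i)
    }
    names(coh@records) <- vapply(coh@records, `[[`, "", "recordId")
    coh@metadata$patient_id <- pid
    coh@metadata$record_id <- names(coh@records)
    coh@signatures$patient_id <- pid
    coh
  }
  c1 <- relabel(c1, "A"); c2 <- relabel(c2, "B"); c5 <- relabel(c5, "C")
  coh <- new("ECGCohort",
             records = c(c1@records, c2@records, c5@records),
             metadata = rbind(cohortMetadata(c1), cohortMetadata(c2),
                              cohortMetadata(c5)),
             signatures = rbind(c1@signatures, c2@signatures, c5@signatures))
  filt <- filterEligible(coh)
  counts <- table(patientIds(filt))
  expect_setequal(names(counts), c("B", "C"))
  expect_equal(sort(as.integer(counts)), c(2L, 5L))
  # record order within patients preserved
  expect_equal(recordIds(filt), c(recordIds(c2), recordIds(c5)))

  # all single-record patients -> empty cohort; none -> identity
  expect_equal(nRecords(filterEligible(c1)), 0L)
  expect_identical(cohortMetadata(filterEligible(filt)), cohortMetadata(filt))
})

test_that("batches have valid pair structure and cover each patient once", {
  ts <- indexTensorSet(rep(3, 10))
  batches <- sampleBatches(ts, 4, seed = 7, epoch = 1)
  expect_length(batches, 2L) # trailing incomplete chunk of 2 patients dropped
  seen <- character()
  for (b in batches) {
    expect_length(recordIds(b), 8L)
    pid <- patientIds(b)
    expect_equal(pid[b@pairIndex[, 1]], pid[b@pairIndex[, 2]])
    expect_false(anyDuplicated(pid[b@pairIndex[, 1]]) > 0)
    expect_false(anyDuplicated(recordIds(b)) > 0)
    seen <- c(seen, unique(pid))
  }
  expect_false(anyDuplicated(seen) > 0) # at most one batch per patient per epoch

  # patient count a multiple of the batch size -> every patient appears
  full <- sampleBatches(ts, 5, seed = 7, epoch = 1)
  expect_setequal(unlist(lapply(full, patientIds)), unique(patientIds(ts)))
})

test_that("the batch stream is reproducible from (seed, epoch)", {
  ts <- indexTensorSet(rep(4, 8))
  a <- sampleBatches(ts, 4, seed = 3, epoch = 2)
  b <- sampleBatches(ts, 4, seed = 3, epoch = 2)
  expect_identical(lapply(a, recordIds), lapply(b, recordIds))
  c2 <- sampleBatches(ts, 4, seed = 3, epoch = 3)
  expect_false(identical(lapply(a, recordIds), lapply(c2, recordIds)))
})

test_that("a two-record patient always contributes its only pair", {
  ts <- indexTensorSet(c(2, 3))
  for (e in 1:10) {
    b <- sampleBatches(ts, 2, seed = 5, epoch = e)[[1]]
    two <- recordIds(b)[patientIds(b) == "P0001"]
    expect_setequal(two, c("P0001_E1", "P0001_E2"))
  }
})

test_that("pairs from a four-record patient are uniform over the six pairs", {
  ts <- indexTensorSet(4)
  draws <- vapply(seq_len(20000), function(e) {
    b <- sampleBatches(ts, 1, seed = 42, epoch = e)[[1]]
    paste(sort(recordIds(b)), collapse = "+")
  }, "")
  freq <- table(draws) / length(draws)
  expect_length(freq, 6L)
  se <- sqrt((1 / 6) * (5 / 6) / length(draws))
  expect_true(all(abs(freq - 1 / 6) < 3 * se))
})

test_that("unfiltered cohorts and oversized batches are rejected", {
  ts <- indexTensorSet(c(1, 2, 2))
  expect_error(sampleBatches(ts, 2, seed = 1), class = "pclr_unfiltered_cohort")
  ok <- indexTensorSet(c(2, 2))
  expect_error(sampleBatches(ok, 3, seed = 1), class = "pclr_config_error")
})

test_that("materialization returns tensors in batch order", {
  coh <- smallCohort(nPatients = 3, visits = c(2, 2), seed = 17)
  ts <- thinTensorSet(batchPreprocess(coh)$tensors, 8)
  b <- sampleBatches(ts, 3, seed = 1, epoch = 1)[[1]]
  X <- materializeBatch(ts, b)
  expect_equal(dim(X), c(6L, 512L, 12L))
  k <- match(recordIds(b)[4], recordIds(ts))
  expect_equal(X[4, , ], ts@tensors[, , k])
})
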