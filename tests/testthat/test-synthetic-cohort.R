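test_that("cohort generation honours the counting and determinism contracts", {
  coh <- generateCohort(2, visits = 2, seed = 7)
  expect_equal(nRecords(coh), 4L)
  md <- cohortMetadata(coh)
  expect_equal(length(unique(md$patient_id)), 2L)
  for (rec in coh@records) {
    expect_equal(ncol(rec$leads), 12L)
    expect_equal(nrow(rec$leads), 10L * rec$samplingRate)
    expect_type(rec$leads[1, 1], "integer")
  }
  # per-record age advances with the visit day
  expect_equal(md$age, coh@signatures$baseline_age[match(md$patient_id,
               coh@signatures$patient_id)] + md$acquisition_day / 365.25)

  # identical seed reproduces the cohort exactly
  coh2 <- generateCohort(2, visits = 2, seed = 7)
  expect_identical(coh@records, coh2@records)
  expect_identical(cohortMetadata(coh), cohortMetadata(coh2))
  # different seed does not
  coh3 <- generateCohort(2, visits = 2, seed = 8)
  expect_false(identical(coh@records, coh3@records))
})

test_that("noiseless fixed-rate records are exact circular repetitions of the beat", {
  coh <- generateCohort(1, visits = 1, seed = 3, noiseLevel = 0,
                        baselineWanderAmp = 0, heartRate = 60,
                        afPropensity = 0, samplingRates = 250)
  x <- coh@records[[1]]$leads
  period <- 250L # 60 bpm at 250 Hz
  expect_identical(x[seq_len(nrow(x) - period), ], x[(period + 1):nrow(x), ])
})

test_that("hypertrophy flag is a deterministic threshold on amplitude scale", {
  coh <- generateCohort(30, visits = 1, seed = 21)
  sig <- coh@signatures
  expect_identical(sig$hypertrophy_like,
                   as.integer(sig$amplitude_scale > pclr:::HYPERTROPHY_SCALE_THRESHOLD))
  # regeneration from the same seed reproduces signatures bit-exactly
  expect_identical(sig, generateCohort(30, visits = 1, seed = 21)@signatures)
})

test_that("arrhythmia-flagged records have no P-wave and irregular beats", {
  coh <- generateCohort(3, visits = 2, seed = 5, afPropensity = 1,
                        noiseLevel = 0, baselineWanderAmp = 0)
  md <- cohortMetadata(coh)
  expect_true(all(md$af_active == 1))
  w <- pclr:::waveTable()
  for (rid in md$record_id) {
    tpl <- cleanBeatTemplate(coh, rid)
    # P-wave segment of the template is flat
    t <- seq(-0.3, 0.5, by = 1 / 500)
    pWin <- abs(t - w$center[w$wave == "P"]) < 0.03
    expect_lt(max(abs(tpl[pWin, "II"])), 1e-3)
  }
  # RR interval dispersion: detect R peaks in lead II of a noiseless record
  rec <- coh@records[[1]]
  fs <- rec$samplingRate
  x <- as.numeric(rec$leads[, "II"])
  thr <- 0.6 * max(x)
  above <- which(x > thr)
  peaks <- above[c(TRUE, diff(above) > fs * 0.2)]
  rr <- diff(peaks) / fs
  expect_gte(sd(rr) / mean(rr), 0.15)
})

test_that("same-patient beat templates are closer than cross-patient ones", {
  coh <- generateCohort(50, visits = 2, seed = 31, afPropensity = 0)
  md <- cohortMetadata(coh)
  tpls <- lapply(md$record_id, function(r) as.vector(cleanBeatTemplate(coh, r)))
  n <- length(tpls)
  dsame <- c(); ddiff <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((tpls[[i]] - tpls[[j]])^2))
    if (md$patient_id[i] == md$patient_id[j]) dsame <- c(dsame, d)
    else ddiff <- c(ddiff, d)
  }
  expect_lt(mean(dsame), mean(ddiff))
})

test_that("hypertrophy label is linearly recoverable from template R amplitudes", {
  coh <- generateCohort(120, visits = 1, seed = 41, afPropensity = 0)
  md <- cohortMetadata(coh)
  feats <- t(vapply(md$record_id, function(r) {
    apply(abs(cleanBeatTemplate(coh, r)), 2, max)
  }, numeric(12)))
  y <- md$hypertrophy_like
  fit <- suppressWarnings(glm(y ~ feats, family = binomial()))
  auc <- pclr:::aucScore(y, fitted(fit))
  expect_gt(auc, 0.95)
})

test_that("invalid sampling rates are rejected with a named error", {
  expect_error(generateCohort(1, visits = 1, seed = 1, samplingRates = 300),
               class = "pclr_invalid_sampling_rate")
})

test_that("the cohort store round-trips and flags malformed files", {
  dir <- withr::local_tempdir()
  coh <- smallCohort(seed = 13)
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_identical(lapply(coh@records, `[[`, "leads"),
                   lapply(back@records, `[[`, "leads"))
  expect_equal(cohortMetadata(back), cohortMetadata(coh), tolerance = 1e-12)

  # a record file missing a lead column names the lead and record
  rid <- recordIds(coh)[1]
  f <- file.path(dir, "records", paste0(rid, ".csv"))
  tab <- data.table::fread(f, skip = 1)
  hdr <- readLines(f, n = 1)
  tab[["III"]] <- NULL
  writeLines(hdr, f)
  data.table::fwrite(tab, f, append = TRUE, col.names = TRUE)
  err <- tryCatch(readCohort(dir), pclr_missing_lead = function(e) e)
  expect_s3_class(err, "pclr_missing_lead")
  expect_match(conditionMessage(err), "III")
  expect_match(conditionMessage(err), rid, fixed = TRUE)

  # an unknown patient_id in a record header is rejected
  dir2 <- withr::local_tempdir()
  writeCohort(coh, dir2)
  f2 <- file.path(dir2, "records", paste0(rid, ".csv"))
  lines <- readLines(f2)
  lines[1] <- sub("patient_id=[^,]+", "patient_id=GHOST", lines[1])
  writeLines(lines, f2)
  expect_error(readCohort(dir2), class = "pclr_parse_error")
})
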