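## Synthetic multi-visit ECG cohort generator.
##
## Each patient gets a latent "signature": a per-wave shaped beat template
## (P, Q, R, S, T as Gaussian bumps on a 3-component dipole), a global
## amplitude scale, and attribute labels. Visits re-render that template at a
## visit-specific heart rate with baseline wander and white noise, so records
## from the same patient share morphology while differing in rhythm and
## noise -- the structure patient-contrastive pre-training exploits.

pclrError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pclr_error")))
}

## Base beat template: one Gaussian per wave on a 3-component dipole.
## Times in seconds relative to the R peak, amplitudes in mV (before the
## per-patient scale), directions are unit 3-vectors.
waveTable <- function() {
  w <- data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    center = c(-0.170, -0.030, 0.000, 0.028, 0.300),
    sigma = c(0.022, 0.009, 0.011, 0.010, 0.060),
    amp = c(0.12, -0.10, 1.00, -0.25, 0.30),
    dx = c(0.50, 0.20, 0.25, 0.30, 0.35),
    dy = c(0.80, 0.90, 0.90, 0.85, 0.80),
    dz = c(0.20, 0.30, 0.35, 0.40, 0.45)
  )
  nrm <- sqrt(w$dx^2 + w$dy^2 + w$dz^2)
  w$dx <- w$dx / nrm; w$dy <- w$dy / nrm; w$dz <- w$dz / nrm
  w
}

## Fixed full-rank 12 x 3 mixing matrix: frontal limb-lead vectors plus a
## precordial arc sweeping from right-anterior to left-lateral.
leadMixingMatrix <- function() {
  m <- rbind(
    I = c(1.00, 0.00, 0.00),
    II = c(0.50, 0.87, 0.00),
    III = c(-0.50, 0.87, 0.00),
    AVR = c(-0.75, -0.435, 0.00),
    AVL = c(0.75, -0.435, 0.00),
    AVF = c(0.00, 0.87, 0.00),
    V1 = c(-0.40, 0.20, 0.90),
    V2 = c(-0.10, 0.30, 1.00),
    V3 = c(0.30, 0.40, 0.80),
    V4 = c(0.60, 0.50, 0.50),
    V5 = c(0.90, 0.40, 0.20),
    V6 = c(1.00, 0.30, 0.00)
  )
  colnames(m) <- c("x", "y", "z")
  m
}

## Threshold on the per-patient amplitude scale above which the
## hypertrophy-like (high-voltage) flag is set; deterministic given the scale.
HYPERTROPHY_SCALE_THRESHOLD <- 1.25

## Sex-linked multiplicative morphology effects (amplitude per wave, and a
## mild QRS widening), loosely mirroring higher QRS voltage and flatter
## T waves in one sex class.
sexAmpFactors <- function(sexLike) {
  if (sexLike == 1) c(P = 1, Q = 1, R = 1.10, S = 1.08, T = 0.85)
  else c(P = 1, Q = 1, R = 1, S = 1, T = 1)
}
sexSigmaFactors <- function(sexLike) {
  if (sexLike == 1) c(P = 1, Q = 1, R = 1.06, S = 1, T = 1)
  else c(P = 1, Q = 1, R = 1, S = 1, T = 1)
}

## Per-patient effective wave parameters from a signature row.
effectiveWaves <- function(sig) {
  w <- waveTable()
  ampF <- sexAmpFactors(sig$sex_like)
  sigF <- sexSigmaFactors(sig$sex_like)
  for (i in seq_len(nrow(w))) {
    nm <- w$wave[i]
    w$amp[i] <- (w$amp[i] + sig[[paste0("amp_off_", nm)]]) *
      ampF[[nm]] * sig$amplitude_scale
    w$sigma[i] <- max(w$sigma[i] + sig[[paste0("dur_off_", nm)]], 0.004)
  }
  w
}

drawSignatures <- function(nPatients) {
  amplitudeScale <- rlnorm(nPatients, 0, 0.2)
  sig <- data.frame(
    patient_id = sprintf("P%05d", seq_len(nPatients)),
    sex_like = rbinom(nPatients, 1, 0.5),
    baseline_age = runif(nPatients, 25, 85),
    amplitude_scale = amplitudeScale,
    hypertrophy_like = as.integer(amplitudeScale > HYPERTROPHY_SCALE_THRESHOLD),
    af_propensity = ifelse(runif(nPatients) < 0.10, runif(nPatients, 0.3, 0.9), 0),
    heart_rate_base = rnorm(nPatients, 72, 7)
  )
  ## per-wave amplitude (mV) and duration (s) offsets, drawn once per patient
  ampSd <- c(P = 0.02, Q = 0.02, R = 0.06, S = 0.04, T = 0.05)
  durSd <- c(P = 0.003, Q = 0.001, R = 0.0015, S = 0.0015, T = 0.008)
  for (nm in names(ampSd)) {
    sig[[paste0("amp_off_", nm)]] <- rnorm(nPatients, 0, ampSd[[nm]])
    sig[[paste0("dur_off_", nm)]] <- rnorm(nPatients, 0, durSd[[nm]])
  }
  sig
}

## R-peak times covering [-1, duration + 1] s so the rendered signal has no
## edge effects (and is exactly periodic in the noiseless regular-rhythm case).
beatTimes <- function(heartRate, duration, afActive, afRRSdlog = 0.25) {
  meanRR <- 60 / heartRate
  phase <- runif(1, 0, meanRR)
  if (!afActive) {
    start <- phase - meanRR * ceiling((1 + phase) / meanRR)
    seq(start, duration + 1, by = meanRR)
  } else {
    k <- ceiling((duration + 3) / meanRR * 2) + 4
    rr <- meanRR * rlnorm(k, 0, afRRSdlog)
    tt <- (phase - 1 - meanRR) + cumsum(c(0, rr))
    tt[tt >= -1 & tt <= duration + 1]
  }
}

## Render one visit: clean dipole from the tiled template, optional baseline
## wander (in dipole space, so it is correlated across leads), projection to
## 12 leads, additive white noise, integer microvolt emission.
renderVisit <- function(waves, rTimes, fs, duration, noiseLevel,
                        wanderAmp, afActive) {
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  D <- matrix(0, n, 3)
  for (i in seq_len(nrow(waves))) {
    if (afActive && waves$wave[i] == "P") next # absent P-waves under AF
    a <- waves$amp[i]; s2 <- 2 * waves$sigma[i]^2
    g <- numeric(n)
    for (r in rTimes) {
      c0 <- r + waves$center[i]
      g <- g + exp(-(t - c0)^2 / s2)
    }
    D <- D + (a * g) %o% c(waves$dx[i], waves$dy[i], waves$dz[i])
  }
  if (wanderAmp > 0) {
    f <- runif(1, 0.12, 0.40)
    ph <- runif(1, 0, 2 * pi)
    amp <- wanderAmp * runif(1, 0.5, 1.5)
    wdir <- c(0.6, 0.6, 0.5); wdir <- wdir / sqrt(sum(wdir^2))
    D <- D + (amp * sin(2 * pi * f * t + ph)) %o% wdir
  }
  leadsMv <- D %*% t(leadMixingMatrix())
  if (noiseLevel > 0) {
    leadsMv <- leadsMv + matrix(rnorm(n * 12, 0, 0.025 * noiseLevel), n, 12)
  }
  uv <- round(leadsMv * 1000)
  uv <- pmin(pmax(uv, -32768), 32767) # 16-bit signed saturation
  storage.mode(uv) <- "integer"
  colnames(uv) <- leadOrder()
  uv
}

#' Generate a synthetic multi-visit 12-lead ECG cohort
#'
#' Draws one latent signature per patient (sex-like class, baseline age,
#' a global amplitude scale, per-wave shape offsets, an arrhythmia
#' propensity) and renders each visit as a 10-second 12-lead record:
#' a P-QRS-T sum-of-Gaussians beat template on a 3-component dipole, tiled at
#' the visit heart rate, projected through a fixed full-rank 12 x 3 lead
#' matrix, with sinusoidal baseline wander and white noise added, and
#' amplitudes emitted as 16-bit-saturated integer microvolts. The
#' hypertrophy-like flag is `amplitude_scale > 1.25` (deterministic); when a
#' visit's arrhythmia flag is active the beat intervals are log-normally
#' jittered (coefficient of variation about 0.25) and the P-wave is absent.
#' Consecutive visits are 30--500 days apart (uniform), and the per-record
#' age advances accordingly.
#'
#' @param nPatients Number of patients (>= 1).
#' @param visits Either a single integer (constant visit count) or a
#'   length-2 integer vector `c(min, max)` for uniform visit counts; all
#'   counts must be >= 1.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param samplingRates Candidate sampling rates, a subset of `c(250, 500)`
#'   Hz; each record draws one uniformly.
#' @param noiseLevel Unitless white-noise multiplier (>= 0); level 1 means
#'   25 microvolt RMS muscle-artifact-like noise per lead.
#' @param baselineWanderAmp Baseline-wander amplitude in mV (>= 0).
#' @param heartRate Optional fixed heart rate in beats/min for every visit;
#'   default `NULL` draws per-patient/per-visit rates.
#' @param afPropensity Optional fixed arrhythmia propensity in \[0, 1\] for
#'   every patient, overriding the drawn one.
#' @param visitGapRange Length-2 vector, uniform range in days between
#'   consecutive visits.
#' @return An [ECGCohort-class] with records, per-record metadata and
#'   per-patient signatures.
#' @examples
#' coh <- generateCohort(2, visits = 2, seed = 7)
#' nRecords(coh)
#' @export
generateCohort <- function(nPatients, visits = c(2, 4), seed,
                           samplingRates = c(250, 500),
                           noiseLevel = 1, baselineWanderAmp = 0.08,
                           heartRate = NULL, afPropensity = NULL,
                           visitGapRange = c(30, 500)) {
  stopifnot(nPatients >= 1, noiseLevel >= 0, baselineWanderAmp >= 0)
  if (!all(samplingRates %in% c(250, 500))) {
    pclrError(sprintf("invalid sampling rate(s): %s (must be 250 or 500 Hz)",
                      paste(setdiff(samplingRates, c(250, 500)), collapse = ", ")),
              "pclr_invalid_sampling_rate")
  }
  if (length(visits) == 1) visits <- c(visits, visits)
  stopifnot(length(visits) == 2, visits[1] >= 1, visits[1] <= visits[2])

  withSeed(seed, {
    sig <- drawSignatures(nPatients)
    if (!is.null(afPropensity)) {
      stopifnot(afPropensity >= 0, afPropensity <= 1)
      sig$af_propensity <- afPropensity
    }
    records <- list()
    md <- list()
    for (i in seq_len(nPatients)) {
      p <- sig[i, , drop = FALSE]
      waves <- effectiveWaves(p)
      vRange <- seq(visits[1], visits[2])
      nv <- vRange[sample.int(length(vRange), 1)]
      gaps <- runif(nv, visitGapRange[1], visitGapRange[2])
      days <- cumsum(c(0, gaps[-1]))
      for (v in seq_len(nv)) {
        fs <- if (length(samplingRates) == 1) samplingRates else sample(samplingRates, 1)
        afActive <- as.integer(runif(1) < p$af_propensity)
        hr <- if (!is.null(heartRate)) heartRate else {
          base <- p$heart_rate_base + if (afActive) 18 else 0
          min(max(rnorm(1, base, 5), 45), 150)
        }
        rid <- sprintf("%s_E%02d", p$patient_id, v)
        rts <- beatTimes(hr, 10, afActive == 1)
        uv <- renderVisit(waves, rts, fs, 10, noiseLevel,
                          baselineWanderAmp, afActive == 1)
        records[[rid]] <- list(leads = uv, samplingRate = fs,
                               patientId = p$patient_id, recordId = rid)
        md[[rid]] <- data.frame(
          patient_id = p$patient_id, record_id = rid,
          acquisition_day = days[v],
          age = p$baseline_age + days[v] / 365.25,
          sex_like = p$sex_like,
          hypertrophy_like = p$hypertrophy_like,
          af_active = afActive,
          heart_rate = hr,
          sampling_rate_hz = fs
        )
      }
    }
    metadata <- do.call(rbind, md)
    rownames(metadata) <- NULL
    new("ECGCohort", records = records, metadata = metadata, signatures = sig)
  })
}

#' Clean beat template of a record
#'
#' The noise-free single-beat 12-lead waveform implied by a record's patient
#' signature and its visit-level arrhythmia flag (absent P-wave when active),
#' evaluated on a fixed grid around the R peak. Used to verify that
#' morphology is patient-stable and that amplitude labels are recoverable.
#'
#' @param cohort An [ECGCohort-class] produced by [generateCohort()] (needs
#'   signatures).
#' @param recordId A record identifier.
#' @param fs Grid sampling rate (Hz).
#' @return Numeric matrix (`samples x 12`, mV) spanning -0.3 to 0.5 s
#'   around the R peak.
#' @export
cleanBeatTemplate <- function(cohort, recordId, fs = 500) {
  stopifnot(is(cohort, "ECGCohort"))
  if (!nrow(cohort@signatures)) {
    pclrError("cohort has no signature provenance", "pclr_parse_error")
  }
  md <- cohort@metadata
  row <- md[md$record_id == recordId, , drop = FALSE]
  if (!nrow(row)) pclrError(paste("unknown record_id:", recordId), "pclr_parse_error")
  sig <- cohort@signatures
  p <- sig[sig$patient_id == row$patient_id, , drop = FALSE]
  waves <- effectiveWaves(p)
  t <- seq(-0.3, 0.5, by = 1 / fs)
  D <- matrix(0, length(t), 3)
  for (i in seq_len(nrow(waves))) {
    if (row$af_active == 1 && waves$wave[i] == "P") next
    g <- waves$amp[i] * exp(-(t - waves$center[i])^2 / (2 * waves$sigma[i]^2))
    D <- D + g %o% c(waves$dx[i], waves$dy[i], waves$dz[i])
  }
  out <- D %*% t(leadMixingMatrix())
  colnames(out) <- leadOrder()
  out
}

## ---------------------------------------------------------------------------
## Cohort store: a plain-text directory layout.
##   <dir>/metadata.csv              one row per record
##   <dir>/signatures.csv            per-patient signatures (if available)
##   <dir>/records/<record_id>.csv   '#'-prefixed attribute header line, then
##                                   12 integer microvolt lead columns
## ---------------------------------------------------------------------------

#' Write / read a cohort store
#'
#' `writeCohort()` persists an [ECGCohort-class] as a directory of plain-text
#' files: a metadata table, optional per-patient signatures, and one CSV per
#' record whose first line is a commented attribute header
#' (`# patient_id=...,record_id=...,sampling_rate_hz=...`) followed by the 12
#' integer microvolt lead columns in the fixed lead order. `readCohort()`
#' restores it; integer amplitude arrays round-trip exactly.
#'
#' @param cohort An [ECGCohort-class].
#' @param path Directory to create/read.
#' @return `writeCohort()` returns `path` invisibly; `readCohort()` returns
#'   an [ECGCohort-class].
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "ECGCohort"))
  dir.create(file.path(path, "records"), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort@metadata, file.path(path, "metadata.csv"))
  if (nrow(cohort@signatures)) {
    data.table::fwrite(cohort@signatures, file.path(path, "signatures.csv"))
  }
  for (rec in cohort@records) {
    f <- file.path(path, "records", paste0(rec$recordId, ".csv"))
    hdr <- sprintf("# patient_id=%s,record_id=%s,sampling_rate_hz=%d",
                   rec$patientId, rec$recordId, as.integer(rec$samplingRate))
    writeLines(hdr, f)
    data.table::fwrite(as.data.frame(rec$leads), f, append = TRUE,
                       col.names = TRUE)
  }
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  mf <- file.path(path, "metadata.csv")
  if (!file.exists(mf)) pclrError(paste("no metadata.csv under", path), "pclr_parse_error")
  metadata <- as.data.frame(data.table::fread(mf))
  sf <- file.path(path, "signatures.csv")
  signatures <- if (file.exists(sf)) as.data.frame(data.table::fread(sf)) else data.frame()
  records <- list()
  for (k in seq_len(nrow(metadata))) {
    rid <- metadata$record_id[k]
    f <- file.path(path, "records", paste0(rid, ".csv"))
    if (!file.exists(f)) {
      pclrError(sprintf("record '%s': file missing from cohort store", rid),
                "pclr_parse_error")
    }
    hdr <- readLines(f, n = 1)
    attrs <- strsplit(sub("^#\\s*", "", hdr), ",")[[1]]
    kv <- strsplit(attrs, "=")
    av <- vapply(kv, `[`, "", 2)
    names(av) <- vapply(kv, `[`, "", 1)
    if (!identical(unname(av[["record_id"]]), as.character(rid))) {
      pclrError(sprintf("record '%s': header record_id mismatch ('%s')",
                        rid, av[["record_id"]]), "pclr_parse_error")
    }
    pid <- av[["patient_id"]]
    if (!pid %in% metadata$patient_id) {
      pclrError(sprintf("record '%s': unknown patient_id '%s'", rid, pid),
                "pclr_parse_error")
    }
    leads <- as.data.frame(data.table::fread(f, skip = 1))
    missing <- setdiff(leadOrder(), names(leads))
    if (length(missing)) {
      pclrError(sprintf("record '%s': missing lead(s) %s", rid,
                        paste(missing, collapse = ", ")), "pclr_missing_lead")
    }
    m <- as.matrix(leads[, leadOrder()])
    storage.mode(m) <- "integer"
    records[[rid]] <- list(leads = m,
                           samplingRate = as.numeric(av[["sampling_rate_hz"]]),
                           patientId = pid, recordId = rid)
  }
  new("ECGCohort", records = records, metadata = metadata, signatures = signatures)
}
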