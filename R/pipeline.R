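## End-to-end workflow orchestration: synth -> preprocess -> pretrain ->
## embed -> probe, driven by a single config (YAML file or list), with
## content-hash stage caching and a JSON-lines run log. Each stage directory
## carries a manifest recording the config hash and seed that produced it;
## re-running with an unchanged config reuses completed stages.

PIPELINE_LABELS <- c("sex_like", "hypertrophy_like", "af_active", "age",
                     "heart_rate")

#' Demo pipeline configuration
#'
#' A small, fast configuration exercising every stage: a 40-patient
#' synthetic cohort, 512-sample desk-scale encoder, 2 pre-training epochs,
#' and a sex-like classification probe.
#'
#' @param out Output directory for artifacts.
#' @param seed Integer seed.
#' @return A named config list accepted by [runPipeline()].
#' @export
demoConfig <- function(out = file.path(tempdir(), "pclr_demo"), seed = 1L) {
  list(
    experiment = "demo",
    out = out,
    seed = as.integer(seed),
    cohort = list(n_patients = 40L, min_visits = 2L, max_visits = 3L),
    preprocess = list(thin = 8L),
    encoder = list(input_length = 512L, channels = c(12L, 24L, 48L),
                   downsample = 4L, stem_pool = 2L, kernel = 16L),
    pretrain = list(epochs = 2L, initial_lr = 0.01,
                    n_patients_per_batch = 8L, validation_fraction = 0.1,
                    temperature = 0.1),
    probe = list(label = "sex_like", task = "classification",
                 n_train = 32L, n_bootstraps = 100L)
  )
}

## Validate a run config before any compute.
validateRunConfig <- function(config) {
  need <- c("experiment", "out", "seed", "cohort", "preprocess", "encoder",
            "pretrain", "probe")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    pclrError(paste("config missing field(s):", paste(missing, collapse = ", ")),
              "pclr_validation_error")
  }
  if (is.null(config$seed)) {
    pclrError("config must carry an explicit seed", "pclr_validation_error")
  }
  if (is.null(config$probe$label) || !config$probe$label %in% PIPELINE_LABELS) {
    pclrError(sprintf("probe label '%s' is not a cohort metadata column (known: %s)",
                      if (is.null(config$probe$label)) "<none>" else config$probe$label,
                      paste(PIPELINE_LABELS, collapse = ", ")),
              "pclr_validation_error")
  }
  if (!config$probe$task %in% c("classification", "regression")) {
    pclrError("probe task must be classification or regression",
              "pclr_validation_error")
  }
  invisible(TRUE)
}

appendLog <- function(out, entry) {
  line <- jsonlite::toJSON(entry, auto_unbox = TRUE)
  cat(line, "\n", sep = "", file = file.path(out, "log.jsonl"), append = TRUE)
}

## Run one stage with manifest-based caching; returns the upstream hash chain.
runStage <- function(name, out, hash, seed, fn) {
  dir <- file.path(out, name)
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    m <- jsonlite::read_json(mf)
    if (identical(m$hash, hash)) {
      appendLog(out, list(stage = name, status = "cached", hash = hash))
      return(list(dir = dir, executed = FALSE))
    }
  }
  unlink(dir, recursive = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ok <- tryCatch({ fn(dir); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) {
    appendLog(out, list(stage = name, status = "failed", hash = hash,
                        message = conditionMessage(ok)))
    stop(sprintf("stage '%s' failed (config hash %s): %s", name, hash,
                 conditionMessage(ok)), call. = FALSE)
  }
  jsonlite::write_json(list(stage = name, hash = hash, seed = seed,
                            created = format(Sys.time(), tz = "UTC")),
                       mf, auto_unbox = TRUE)
  appendLog(out, list(stage = name, status = "run", hash = hash))
  list(dir = dir, executed = TRUE)
}

#' Run the end-to-end pipeline
#'
#' Executes synth -> preprocess -> pretrain -> embed -> probe from a single
#' config (a YAML file path or a named list, see [demoConfig()]). Every stage
#' writes its artifacts plus a manifest with the hash of the config slice
#' (and upstream hashes) that produced it; re-running with the same config
#' reuses completed stages. The config is validated before any compute.
#'
#' @param config Path to a YAML config or a named list.
#' @return List with the artifact directory, per-stage `executed` flags and
#'   the probe result, invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validateRunConfig(config)
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  executed <- list()

  ## ---- synth
  hSynth <- configHash(list(stage = "synth", cfg = config$cohort, seed = seed))
  sSynth <- runStage("synth", out, hSynth, seed, function(dir) {
    coh <- generateCohort(config$cohort$n_patients,
                          visits = c(config$cohort$min_visits,
                                     config$cohort$max_visits),
                          seed = deriveSeed(seed, 1))
    writeCohort(coh, file.path(dir, "cohort"))
  })
  executed$synth <- sSynth$executed

  ## ---- preprocess
  hPre <- configHash(list(stage = "preprocess", cfg = config$preprocess,
                          upstream = hSynth))
  sPre <- runStage("preprocess", out, hPre, seed, function(dir) {
    coh <- readCohort(file.path(sSynth$dir, "cohort"))
    bp <- batchPreprocess(coh)
    if (nrow(bp$failures)) {
      data.table::fwrite(bp$failures, file.path(dir, "failures.csv"))
    }
    ts <- bp$tensors
    thin <- config$preprocess$thin
    if (!is.null(thin) && thin > 1) ts <- thinTensorSet(ts, thin)
    saveRDS(ts, file.path(dir, "tensors.rds"))
  })
  executed$preprocess <- sPre$executed

  encCfg <- encoderConfig(
    inputLength = config$encoder$input_length,
    channelsPerStage = unlist(config$encoder$channels),
    downsamplePerBlock = config$encoder$downsample,
    stemPool = config$encoder$stem_pool,
    convFilterSize = config$encoder$kernel
  )

  ## ---- pretrain
  hFit <- configHash(list(stage = "pretrain", cfg = config$pretrain,
                          encoder = unclass(encCfg), upstream = hPre))
  sFit <- runStage("pretrain", out, hFit, seed, function(dir) {
    ts <- readRDS(file.path(sPre$dir, "tensors.rds"))
    eligible <- names(which(table(patientIds(ts)) >= 2))
    ts <- subsetTensorSet(ts, patientIds(ts) %in% eligible)
    fit <- pretrainPCLR(
      ts, encCfg,
      lossCfg = lossConfig(temperature = config$pretrain$temperature %||% 0.1),
      trainCfg = trainConfig(
        epochs = config$pretrain$epochs,
        initialLr = config$pretrain$initial_lr,
        schedulePeriod = config$pretrain$epochs,
        validationFraction = config$pretrain$validation_fraction,
        seed = seed),
      nPatientsPerBatch = config$pretrain$n_patients_per_batch)
    saveRDS(fit, file.path(dir, "fit.rds"))
    data.table::fwrite(trainingLog(fit), file.path(dir, "training_log.csv"))
  })
  executed$pretrain <- sFit$executed

  ## ---- embed
  hEmb <- configHash(list(stage = "embed", upstream = c(hPre, hFit)))
  sEmb <- runStage("embed", out, hEmb, seed, function(dir) {
    ts <- readRDS(file.path(sPre$dir, "tensors.rds"))
    fit <- readRDS(file.path(sFit$dir, "fit.rds"))
    ft <- extractFeatures(fit@encoder, ts)
    writeFeatureTable(ft, file.path(dir, "features.csv"))
  })
  executed$embed <- sEmb$executed

  ## ---- probe
  hProbe <- configHash(list(stage = "probe", cfg = config$probe,
                            upstream = c(hSynth, hEmb)))
  probePath <- file.path(out, "probe", "result.json")
  sProbe <- runStage("probe", out, hProbe, seed, function(dir) {
    coh <- readCohort(file.path(sSynth$dir, "cohort"))
    ft <- readFeatureTable(file.path(sEmb$dir, "features.csv"))
    md <- cohortMetadata(coh)
    labels <- md[[config$probe$label]][match(recordIds(ft), md$record_id)]
    nTrain <- config$probe$n_train
    idx <- withSeed(deriveSeed(seed, 5), sample(nrow(ft@features), nTrain))
    subTable <- function(k) new("FeatureTable",
                                features = ft@features[k, , drop = FALSE],
                                recordIds = ft@recordIds[k],
                                normStats = list(), normalized = FALSE)
    ftTr <- normalizeFeatures(subTable(idx))
    ftHo <- normalizeWith(subTable(setdiff(seq_len(nrow(ft@features)), idx)), ftTr)
    yTr <- labels[idx]
    yHo <- labels[-idx]
    probe <- fitProbe(ftTr, yTr, config$probe$task, seed = seed)
    res <- evaluateProbe(probe, ftHo, yHo,
                         nBootstraps = config$probe$n_bootstraps, seed = seed)
    jsonlite::write_json(list(task = res@task, metric = res@metric,
                              point_estimate = res@pointEstimate,
                              bootstrap_sd = res@bootstrapSD,
                              n_bootstraps = res@nBootstraps,
                              selected_penalty = res@selectedPenalty),
                         file.path(dir, "result.json"), auto_unbox = TRUE,
                         digits = NA)
  })
  executed$probe <- sProbe$executed

  invisible(list(out = out, executed = executed,
                 probeResult = jsonlite::read_json(probePath)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
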