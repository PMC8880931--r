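## Desk-scale representation-quality benchmark.
##
## The mechanism the method rests on, exercised end-to-end at laptop scale:
## pre-train a small encoder contrastively on a synthetic multi-visit cohort,
## then compare linear probes for a patient-stable attribute (the sex-like
## morphology class) trained on few labeled records against (a) a probe on a
## randomly initialized encoder's representations and (b) the same encoder
## trained from scratch on those labels. Pre-training should win in the
## low-label regime, and same-patient projections should be more similar
## than cross-patient ones on held-out patients.

#' Desk-scale encoder configuration
#'
#' A small encoder instance for 512-sample inputs (the canonical 4,096-sample
#' grid thinned by 8): two residual blocks, channels 12-24-48, kernel 16,
#' 48-dimensional representations.
#'
#' @return An [encoderConfig()].
#' @export
tinyEncoderConfig <- function() {
  encoderConfig(inputLength = 512L, channelsPerStage = c(12L, 24L, 48L),
                downsamplePerBlock = 4L, stemPool = 2L)
}

#' Run the representation-quality benchmark for one seed
#'
#' Steps, all seeded from `seed`:
#' 1. generate a multi-visit pre-training cohort (default 200 patients, 2--3
#'    visits each), preprocess, thin to 512 samples, and pre-train the
#'    desk-scale encoder (8 epochs, 32 patients per batch, Adam with a
#'    half-period cosine schedule starting at 0.01);
#' 2. generate a disjoint single-visit labeled cohort; extract features for
#'    `nLabels` training records and `nHoldout` holdout records from the
#'    pre-trained encoder and from a randomly initialized encoder of the same
#'    architecture, and fit/evaluate a ridge logistic probe for the sex-like
#'    attribute on each;
#' 3. train the same architecture from scratch on the `nLabels` records
#'    (reduced grid: learning rates 1e-2/1e-3, dropout 0/0.2, patience 3)
#'    and evaluate it on the same holdout;
#' 4. measure projection alignment (same-patient vs cross-patient cosine
#'    similarity) on the pre-training validation patients.
#'
#' @param seed Integer seed.
#' @param nPatients Pre-training cohort size (default 200).
#' @param nLabels Labeled training records (default 64).
#' @param nHoldout Holdout records (default 200).
#' @param epochs Pre-training epochs (default 8).
#' @param nBootstraps Bootstrap resamples for the reported SDs (default 200).
#' @return List with f1 point estimates (`pclrF1`, `randomF1`, `scratchF1`),
#'   alignment similarities (`within`, `between`), the three
#'   [ProbeResult-class] objects, and the [PCLRFit-class].
#' @export
runBenchmark <- function(seed, nPatients = 200L, nLabels = 64L,
                         nHoldout = 200L, epochs = 8L, nBootstraps = 200L) {
  encCfg <- tinyEncoderConfig()

  ## -- pre-training cohort and contrastive fit
  cohort <- generateCohort(nPatients, visits = c(2, 3),
                           seed = deriveSeed(seed, 1))
  cohort <- filterEligible(cohort)
  ts <- thinTensorSet(batchPreprocess(cohort)$tensors, 8L)
  fit <- pretrainPCLR(ts, encCfg,
                      lossCfg = lossConfig(temperature = 0.1),
                      trainCfg = trainConfig(epochs = epochs, initialLr = 0.01,
                                             schedulePeriod = epochs,
                                             validationFraction = 0.1,
                                             seed = seed),
                      nPatientsPerBatch = 32L)

  ## -- labeled single-visit cohort, disjoint from pre-training
  evalCohort <- generateCohort(nLabels + nHoldout, visits = 1,
                               seed = deriveSeed(seed, 2))
  evalTs <- thinTensorSet(batchPreprocess(evalCohort)$tensors, 8L)
  md <- cohortMetadata(evalCohort)
  sex <- md$sex_like[match(recordIds(evalTs), md$record_id)]
  trainIdx <- withSeed(deriveSeed(seed, 3),
                       sample(nRecords(evalTs), nLabels))
  holdIdx <- setdiff(seq_len(nRecords(evalTs)), trainIdx)
  trTs <- subsetTensorSet(evalTs, trainIdx)
  hoTs <- subsetTensorSet(evalTs, holdIdx)
  yTr <- sex[trainIdx]
  yHo <- sex[holdIdx]

  probeOn <- function(encoder) {
    ftTr <- normalizeFeatures(extractFeatures(encoder, trTs))
    ftHo <- normalizeWith(extractFeatures(encoder, hoTs), ftTr)
    probe <- fitProbe(ftTr, yTr, "classification", seed = seed, positive = "1")
    evaluateProbe(probe, ftHo, yHo, nBootstraps = nBootstraps, seed = seed)
  }
  pclrRes <- probeOn(fit@encoder)
  randomRes <- probeOn(buildEncoder(encCfg, seed = deriveSeed(seed, 4)))

  ## -- supervised from-scratch baseline on the same labels
  scratch <- trainScratch(trTs, yTr, "classification", encCfg,
                          config = scratchConfig(lrGrid = c(1e-2, 1e-3),
                                                 dropoutGrid = c(0, 0.2),
                                                 patience = 3L, maxEpochs = 12L,
                                                 batchSize = 32L,
                                                 validationFraction = 0.25),
                          seed = seed)
  scratchPred <- as.integer(predictScratch(scratch, hoTs) == "1")
  scratchRes <- scorePredictions(scratchPred, as.integer(yHo == 1),
                                 "classification", recordIds = recordIds(hoTs),
                                 nBootstraps = nBootstraps, seed = seed)

  ## -- alignment on the held-out pre-training patients
  valTs <- subsetTensorSet(ts, patientIds(ts) %in% fit@configs$validationPatients)
  align <- alignmentStats(fit, valTs)

  list(pclrF1 = pclrRes@pointEstimate,
       randomF1 = randomRes@pointEstimate,
       scratchF1 = scratchRes@pointEstimate,
       within = align$within, between = align$between,
       results = list(pclr = pclrRes, random = randomRes, scratch = scratchRes),
       fit = fit)
}
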