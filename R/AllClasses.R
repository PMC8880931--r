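#' @import methods
NULL

## ---------------------------------------------------------------------------
## ECGCohort: raw multi-visit cohort (the unit the generator emits and the
## pairing/preprocessing modules consume).
##
## Each element of @records is one raw acquisition:
##   list(leads        = integer matrix (samples x 12, columns leadOrder()),
##        samplingRate = 250 or 500,
##        patientId, recordId = character scalars)
## @metadata has one row per record; @signatures one row per patient.
## ---------------------------------------------------------------------------

#' ECGCohort: a collection of raw 12-lead ECG records grouped by patient
#'
#' Container for raw ECG acquisitions (integer microvolt amplitudes) together
#' with per-record metadata and, for synthetic cohorts, the per-patient latent
#' signatures the generator drew. Records are grouped by `patient_id`; the
#' same patient may contribute several records acquired at different times.
#'
#' @slot records Named list of raw records; each holds an integer
#'   `samples x 12` lead matrix (microvolts, columns in [leadOrder()]),
#'   the sampling rate in Hz and the patient/record identifiers.
#' @slot metadata `data.frame` with one row per record: `patient_id`,
#'   `record_id`, `acquisition_day`, `age`, `sex_like`, `hypertrophy_like`,
#'   `af_active`, `heart_rate`, `sampling_rate_hz`.
#' @slot signatures `data.frame` with one row per patient
#'   (`patient_id`, `sex_like`, `baseline_age`, `amplitude_scale`,
#'   `hypertrophy_like`, `af_propensity`); empty for cohorts read from disk
#'   without signature provenance.
#'
#' @seealso [generateCohort()], [writeCohort()], [readCohort()],
#'   [filterEligible()]
#' @export
setClass("ECGCohort",
  representation(
    records = "list",
    metadata = "data.frame",
    signatures = "data.frame"
  )
)

setValidity("ECGCohort", function(object) {
  msgs <- character()
  md <- object@metadata
  need <- c("patient_id", "record_id")
  if (!all(need %in% names(md))) {
    msgs <- c(msgs, "metadata must contain patient_id and record_id columns")
  } else {
    if (length(object@records) != nrow(md)) {
      msgs <- c(msgs, "one metadata row per record required")
    }
    if (anyDuplicated(md$record_id)) {
      msgs <- c(msgs, "record_id values must be unique")
    }
  }
  for (rec in object@records) {
    if (!is.matrix(rec$leads) || ncol(rec$leads) != 12) {
      msgs <- c(msgs, sprintf("record '%s': leads must be a samples x 12 matrix",
                              rec$recordId))
      break
    }
    if (!rec$samplingRate %in% c(250, 500)) {
      msgs <- c(msgs, sprintf("record '%s': sampling rate must be 250 or 500 Hz",
                              rec$recordId))
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## ECGTensorSet: preprocessed records as a 3-D array (records kept together
## so batched encoder calls are single BLAS operations).
## ---------------------------------------------------------------------------

#' ECGTensorSet: preprocessed ECG tensors
#'
#' A stack of preprocessed ECG records. Each record is a real
#' `samples x 12` matrix in millivolts with columns in the fixed lead order
#' ([leadOrder()]); the canonical preprocessing grid has 4,096 samples.
#'
#' @slot tensors 3-D numeric array `samples x 12 x n_records`.
#' @slot recordIds Character vector of record identifiers (third dimension).
#' @slot patientIds Character vector of patient identifiers, aligned with
#'   `recordIds`.
#'
#' @seealso [preprocessRecord()], [batchPreprocess()], [thinTensorSet()]
#' @export
setClass("ECGTensorSet",
  representation(
    tensors = "array",
    recordIds = "character",
    patientIds = "character"
  )
)

setValidity("ECGTensorSet", function(object) {
  d <- dim(object@tensors)
  if (length(d) != 3) return("tensors must be a 3-D array (samples x leads x records)")
  if (d[2] != 12) return("tensors must have 12 leads")
  if (d[3] != length(object@recordIds)) return("recordIds must match third dimension")
  if (length(object@patientIds) != length(object@recordIds)) {
    return("patientIds must align with recordIds")
  }
  if (d[3] > 0 && !all(is.finite(object@tensors))) return("all tensor values must be finite")
  TRUE
})

## ---------------------------------------------------------------------------
## ContrastiveBatch: 2N tensors from N distinct patients with explicit pairs.
## ---------------------------------------------------------------------------

#' ContrastiveBatch: 2N ECGs from N patients with explicit positive pairs
#'
#' One contrastive mini-batch: for each of N distinct patients, two records
#' acquired at different times. `pairIndex[p, ]` gives the two positions of
#' patient p's records within the batch.
#'
#' @slot recordIds Character vector of length 2N (batch order).
#' @slot patientIds Character vector of length 2N aligned with `recordIds`.
#' @slot pairIndex Integer `N x 2` matrix of in-batch positions.
#'
#' @seealso [sampleBatches()], [materializeBatch()]
#' @export
setClass("ContrastiveBatch",
  representation(
    recordIds = "character",
    patientIds = "character",
    pairIndex = "matrix"
  )
)

setValidity("ContrastiveBatch", function(object) {
  n2 <- length(object@recordIds)
  pi <- object@pairIndex
  if (length(object@patientIds) != n2) return("patientIds must align with recordIds")
  if (!is.matrix(pi) || ncol(pi) != 2) return("pairIndex must be an N x 2 matrix")
  if (nrow(pi) * 2L != n2) return("batch must hold exactly 2N records for N pairs")
  pos <- as.vector(pi)
  if (any(pi[, 1] == pi[, 2])) return("a pair must reference two distinct positions")
  if (length(unique(pos)) != n2 || !setequal(pos, seq_len(n2))) {
    return("each batch position must belong to exactly one pair")
  }
  pidL <- object@patientIds[pi[, 1]]
  pidR <- object@patientIds[pi[, 2]]
  if (!all(pidL == pidR)) return("both members of a pair must share patient_id")
  if (anyDuplicated(pidL)) return("a patient may appear in at most one pair per batch")
  TRUE
})

## ---------------------------------------------------------------------------
## Model wrappers.
## ---------------------------------------------------------------------------

#' ECGEncoder: residual convolutional encoder f(.)
#'
#' The encoder maps a preprocessed ECG (`input_length x 12`) to a fixed-width
#' representation `h` via an initial convolution / batch-norm / ReLU /
#' max-pool stem, a chain of residual blocks, and global average pooling
#' over time. Built by [buildEncoder()].
#'
#' @slot config The validated [encoderConfig()] list used to build it.
#' @slot net Internal layer list (weights, batch-norm state).
#'
#' @export
setClass("ECGEncoder", representation(config = "list", net = "list"))

#' ProjectionHead: nonlinear projection g(.) used only during pre-training
#'
#' Dense(hidden) -> ReLU -> Dense(output); applied to encoder representations
#' to obtain the projections `z` on which the contrastive loss acts, then
#' discarded for downstream use.
#'
#' @slot config The validated [projectionConfig()] list.
#' @slot net Internal layer list.
#'
#' @export
setClass("ProjectionHead", representation(config = "list", net = "list"))

#' PCLRFit: result of contrastive pre-training
#'
#' @slot encoder The [ECGEncoder-class] at the best-validation checkpoint.
#' @slot head The [ProjectionHead-class] at the same checkpoint.
#' @slot log `data.frame` of per-epoch learning rate and train/validation
#'   contrastive losses (mean per positive pair).
#' @slot bestEpoch Integer epoch whose validation loss was lowest.
#' @slot configs List of the configs and seed the run used.
#'
#' @seealso [pretrainPCLR()]
#' @export
setClass("PCLRFit",
  representation(
    encoder = "ECGEncoder",
    head = "ProjectionHead",
    log = "data.frame",
    bestEpoch = "integer",
    configs = "list"
  )
)

## ---------------------------------------------------------------------------
## Linear-evaluation containers.
## ---------------------------------------------------------------------------

#' FeatureTable: per-record representation features
#'
#' One row per ECG record, one column per representation dimension. Holdout
#' tables must be normalized with the *training* per-column mean/sd
#' (see [normalizeFeatures()] / [normalizeWith()]); the statistics learned on
#' the training rows travel with the table.
#'
#' @slot features Numeric `n x representation_dim` matrix.
#' @slot recordIds Character vector, one id per row.
#' @slot normStats `list(mean=, sd=)` learned on training rows, or empty
#'   list for an unnormalized table.
#' @slot normalized Logical flag.
#'
#' @seealso [extractFeatures()]
#' @export
setClass("FeatureTable",
  representation(
    features = "matrix",
    recordIds = "character",
    normStats = "list",
    normalized = "logical"
  )
)

setValidity("FeatureTable", function(object) {
  if (nrow(object@features) != length(object@recordIds)) {
    return("one record id per feature row required")
  }
  TRUE
})

#' LinearProbe: ridge-regularized linear model on frozen features
#'
#' @slot task `"classification"` (logistic ridge) or `"regression"`
#'   (linear ridge).
#' @slot coef Numeric coefficient vector (no intercept term).
#' @slot intercept Numeric scalar.
#' @slot selectedPenalty The l2 penalty chosen by 4-fold cross-validation.
#' @slot cvScores `data.frame` of mean fold score per candidate penalty.
#' @slot positive The label value treated as positive for f1 (classification).
#'
#' @seealso [fitProbe()], [evaluateProbe()]
#' @export
setClass("LinearProbe",
  representation(
    task = "character",
    coef = "numeric",
    intercept = "numeric",
    selectedPenalty = "numeric",
    cvScores = "data.frame",
    positive = "ANY"
  )
)

#' ProbeResult: holdout evaluation of a linear probe
#'
#' @slot task Task name.
#' @slot metric `"f1"` or `"r2"`.
#' @slot pointEstimate Metric on the full holdout set.
#' @slot bootstrapSD Standard deviation of the metric over seeded bootstrap
#'   resamples of the holdout set.
#' @slot nBootstraps Number of bootstrap resamples (default 1,000).
#' @slot selectedPenalty Penalty of the underlying probe.
#' @slot predictions Holdout predictions (class labels or numeric values);
#'   kept so several models can be compared on shared bootstrap resamples.
#' @slot truth Holdout truth aligned with `predictions`.
#' @slot recordIds Holdout record ids.
#'
#' @seealso [evaluateProbe()], [compareModels()]
#' @export
setClass("ProbeResult",
  representation(
    task = "character",
    metric = "character",
    pointEstimate = "numeric",
    bootstrapSD = "numeric",
    nBootstraps = "integer",
    selectedPenalty = "numeric",
    predictions = "ANY",
    truth = "ANY",
    recordIds = "character"
  )
)
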