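#' Accessors
#'
#' Accessor generics for the core containers: record/patient identifiers,
#' record counts, per-record metadata, the feature matrix of a
#' [FeatureTable-class] and the training log of a [PCLRFit-class].
#'
#' @param x An object.
#' @return `recordIds`/`patientIds`: character vectors; `nRecords`: integer;
#'   `cohortMetadata`: data.frame; `features`: numeric matrix;
#'   `trainingLog`: data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname accessors
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @rdname accessors
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' @rdname accessors
#' @export
setMethod("recordIds", "ECGCohort", function(x) x@metadata$record_id)

#' @rdname accessors
#' @export
setMethod("recordIds", "ECGTensorSet", function(x) x@recordIds)

#' @rdname accessors
#' @export
setMethod("recordIds", "ContrastiveBatch", function(x) x@recordIds)

#' @rdname accessors
#' @export
setMethod("recordIds", "FeatureTable", function(x) x@recordIds)

#' @rdname accessors
#' @export
setMethod("patientIds", "ECGCohort", function(x) x@metadata$patient_id)

#' @rdname accessors
#' @export
setMethod("patientIds", "ECGTensorSet", function(x) x@patientIds)

#' @rdname accessors
#' @export
setMethod("patientIds", "ContrastiveBatch", function(x) x@patientIds)

#' @rdname accessors
#' @export
setMethod("nRecords", "ECGCohort", function(x) length(x@records))

#' @rdname accessors
#' @export
setMethod("nRecords", "ECGTensorSet", function(x) dim(x@tensors)[3])

#' @rdname accessors
#' @export
setMethod("cohortMetadata", "ECGCohort", function(x) x@metadata)

#' @rdname accessors
#' @export
setMethod("features", "FeatureTable", function(x) x@features)

#' @rdname accessors
#' @export
setMethod("trainingLog", "PCLRFit", function(x) x@log)

#' Records of one patient
#'
#' @param cohort An [ECGCohort-class].
#' @param patientId A patient identifier present in the cohort.
#' @return The list of raw records belonging to that patient, in cohort order.
#' @export
patientRecords <- function(cohort, patientId) {
  stopifnot(is(cohort, "ECGCohort"))
  idx <- which(cohort@metadata$patient_id == patientId)
  if (!length(idx)) stop("unknown patient_id: ", patientId)
  cohort@records[idx]
}

setMethod("show", "ECGCohort", function(object) {
  md <- object@metadata
  cat(sprintf("ECGCohort: %d records from %d patients\n",
              nrow(md), length(unique(md$patient_id))))
  if (nrow(md)) {
    cat(sprintf("  sampling rates: %s Hz\n",
                paste(sort(unique(md$sampling_rate_hz)), collapse = "/")))
    cat(sprintf("  visits per patient: %s\n",
                paste(range(table(md$patient_id)), collapse = "-")))
  }
})

setMethod("show", "ECGTensorSet", function(object) {
  d <- dim(object@tensors)
  cat(sprintf("ECGTensorSet: %d records, %d samples x %d leads (mV)\n",
              d[3], d[1], d[2]))
})

setMethod("show", "ContrastiveBatch", function(object) {
  cat(sprintf("ContrastiveBatch: %d ECGs from %d patients\n",
              length(object@recordIds), nrow(object@pairIndex)))
})

setMethod("show", "PCLRFit", function(object) {
  cat(sprintf("PCLRFit: %d epochs, best validation loss %.4f at epoch %d\n",
              nrow(object@log), min(object@log$valLoss), object@bestEpoch))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d records x %d features (%snormalized)\n",
              nrow(object@features), ncol(object@features),
              if (object@normalized) "" else "not "))
})

setMethod("show", "LinearProbe", function(object) {
  cat(sprintf("LinearProbe (%s): %d coefficients, penalty %.3g\n",
              object@task, length(object@coef), object@selectedPenalty))
})

setMethod("show", "ProbeResult", function(object) {
  cat(sprintf("ProbeResult [%s]: %s = %.3f +/- %.3f (%d bootstraps)\n",
              object@task, object@metric, object@pointEstimate,
              object@bootstrapSD, object@nBootstraps))
})
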