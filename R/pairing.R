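## ECG selection module: eligibility filtering and random same-patient pair
## sampling into contrastive batches. Pair selection ignores acquisition time
## and health change entirely; each eligible patient contributes exactly one
## positive pair (two records) per batch appearance.

#' Filter a cohort to patients eligible for contrastive pre-training
#'
#' Retains exactly the patients with at least two ECG records (a patient
#' with a single record admits no positive pair). Record order within
#' patients is preserved.
#'
#' @param cohort An [ECGCohort-class].
#' @return The filtered [ECGCohort-class].
#' @export
filterEligible <- function(cohort) {
  stopifnot(is(cohort, "ECGCohort"))
  md <- cohort@metadata
  counts <- table(md$patient_id)
  keepPatients <- names(counts)[counts >= 2]
  keep <- md$patient_id %in% keepPatients
  sig <- cohort@signatures
  if (nrow(sig)) sig <- sig[sig$patient_id %in% keepPatients, , drop = FALSE]
  md2 <- md[keep, , drop = FALSE]
  rownames(md2) <- NULL
  rownames(sig) <- NULL
  new("ECGCohort", records = cohort@records[md$record_id[keep]],
      metadata = md2, signatures = sig)
}

## Records per patient as a named list of record-id vectors (cohort order).
patientIndex <- function(patientIds, recordIds) {
  split(recordIds, factor(patientIds, levels = unique(patientIds)))
}

#' Sample contrastive batches for one epoch
#'
#' Patients are permuted (seeded by `(seed, epoch)`) and chunked into groups
#' of `nPatientsPerBatch`; a trailing incomplete chunk is dropped so every
#' batch holds exactly 2N records. For each patient in a chunk, two distinct
#' records are drawn uniformly over that patient's unordered record pairs,
#' regardless of acquisition time. The full stream is reproducible from
#' `(seed, epoch)`.
#'
#' @param x An [ECGCohort-class] or [ECGTensorSet-class] already filtered for
#'   eligibility (every patient with >= 2 records).
#' @param nPatientsPerBatch Patients per batch, N (default 512, i.e. 1,024
#'   ECGs per batch); must not exceed the number of eligible patients.
#' @param seed Integer seed.
#' @param epoch Epoch number (>= 1); distinct epochs give distinct,
#'   reproducible permutations and pair draws.
#' @return List of [ContrastiveBatch-class] objects.
#' @export
sampleBatches <- function(x, nPatientsPerBatch = 512, seed, epoch = 1) {
  if (is(x, "ECGCohort")) {
    pids <- x@metadata$patient_id; rids <- x@metadata$record_id
  } else if (is(x, "ECGTensorSet")) {
    pids <- x@patientIds; rids <- x@recordIds
  } else stop("x must be an ECGCohort or ECGTensorSet")
  byPatient <- patientIndex(pids, rids)
  short <- vapply(byPatient, length, 1L) < 2L
  if (any(short)) {
    pclrError(sprintf("unfiltered cohort: patient(s) with a single record: %s",
                      paste(head(names(byPatient)[short], 5), collapse = ", ")),
              "pclr_unfiltered_cohort")
  }
  nP <- length(byPatient)
  if (nPatientsPerBatch > nP) {
    pclrError(sprintf("nPatientsPerBatch (%d) exceeds eligible patients (%d)",
                      nPatientsPerBatch, nP), "pclr_config_error")
  }
  withSeed(deriveSeed(seed, 1000 + epoch), {
    perm <- sample(names(byPatient))
    nBatches <- nP %/% nPatientsPerBatch
    batches <- vector("list", nBatches)
    for (b in seq_len(nBatches)) {
      chunk <- perm[((b - 1) * nPatientsPerBatch + 1):(b * nPatientsPerBatch)]
      n2 <- 2L * nPatientsPerBatch
      rec <- character(n2); pat <- character(n2)
      pairIdx <- matrix(0L, nPatientsPerBatch, 2)
      for (p in seq_along(chunk)) {
        recs <- byPatient[[chunk[p]]]
        pick <- if (length(recs) == 2) recs else sample(recs, 2)
        pos <- c(2L * p - 1L, 2L * p)
        rec[pos] <- pick
        pat[pos] <- chunk[p]
        pairIdx[p, ] <- pos
      }
      batches[[b]] <- new("ContrastiveBatch", recordIds = rec,
                          patientIds = pat, pairIndex = pairIdx)
    }
    batches
  })
}

#' Materialize a contrastive batch as a tensor array
#'
#' @param tensorSet An [ECGTensorSet-class] holding (at least) the batch's
#'   records.
#' @param batch A [ContrastiveBatch-class].
#' @return Numeric array `2N x samples x 12` in batch order.
#' @export
materializeBatch <- function(tensorSet, batch) {
  stopifnot(is(tensorSet, "ECGTensorSet"), is(batch, "ContrastiveBatch"))
  idx <- match(batch@recordIds, tensorSet@recordIds)
  if (anyNA(idx)) {
    pclrError(sprintf("records not in tensor set: %s",
                      paste(head(batch@recordIds[is.na(idx)], 5), collapse = ", ")),
              "pclr_parse_error")
  }
  aperm(tensorSet@tensors[, , idx, drop = FALSE], c(3, 1, 2))
}
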