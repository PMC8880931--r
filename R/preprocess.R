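## Raw-ECG-to-model-input contract: microvolts / 1,000 -> millivolts, then
## per-lead linear interpolation onto a fixed 4,096-sample grid spanning the
## same time extent (endpoint-inclusive). Deliberately no filtering,
## detrending or artifact removal: the encoder is meant to be trained on the
## noise it will see at evaluation time.

TARGET_SAMPLES <- 4096L

#' Preprocess one raw ECG record
#'
#' Each lead is divided by 1,000 (microvolts to millivolts), converted to
#' real values, and linearly interpolated from its native length onto 4,096
#' points spanning the same extent: output grid positions are
#' `t_k = k (L - 1) / 4095` over source indices `0 ... L-1`, so the first and
#' last samples are preserved exactly. Leads are assembled column-wise in the
#' fixed order [leadOrder()]. No filtering or artifact removal is applied.
#'
#' @param raw A raw record: `list(leads = samples x 12 matrix (microvolts,
#'   columns named by lead), samplingRate, patientId, recordId)`, as stored
#'   in an [ECGCohort-class].
#' @return `list(values = 4096 x 12 numeric matrix (mV), recordId,
#'   patientId)`.
#' @examples
#' coh <- generateCohort(1, visits = 1, seed = 1)
#' x <- preprocessRecord(coh@records[[1]])
#' dim(x$values)
#' @export
preprocessRecord <- function(raw) {
  leads <- raw$leads
  rid <- if (!is.null(raw$recordId)) raw$recordId else "<unknown>"
  if (is.null(raw$samplingRate) || !raw$samplingRate %in% c(250, 500)) {
    pclrError(sprintf("record '%s': unsupported sampling rate %s (need 250 or 500 Hz)",
                      rid, format(raw$samplingRate)), "pclr_invalid_sampling_rate")
  }
  if (!is.matrix(leads)) {
    pclrError(sprintf("record '%s': leads must be a matrix", rid), "pclr_missing_lead")
  }
  cn <- colnames(leads)
  missing <- setdiff(leadOrder(), cn)
  if (length(missing)) {
    pclrError(sprintf("record '%s': missing lead(s) %s", rid,
                      paste(missing, collapse = ", ")), "pclr_missing_lead")
  }
  if (nrow(leads) < 1) {
    pclrError(sprintf("record '%s': empty leads", rid), "pclr_missing_lead")
  }
  if (!all(is.finite(leads))) {
    pclrError(sprintf("record '%s': non-finite amplitude values", rid),
              "pclr_nonfinite_input")
  }
  L <- nrow(leads)
  out <- matrix(0, TARGET_SAMPLES, 12, dimnames = list(NULL, leadOrder()))
  xout <- seq(0, L - 1, length.out = TARGET_SAMPLES)
  for (j in seq_len(12)) {
    y <- as.numeric(leads[, leadOrder()[j]]) / 1000
    out[, j] <- if (L == 1) rep(y, TARGET_SAMPLES) else {
      approx(x = 0:(L - 1), y = y, xout = xout, method = "linear")$y
    }
  }
  list(values = out, recordId = rid, patientId = raw$patientId)
}

#' Preprocess a collection of records
#'
#' Order-preserving batch version of [preprocessRecord()]. Per-record
#' failures are collected (with record ids and messages), not silently
#' dropped, and the successes are stacked into an [ECGTensorSet-class].
#'
#' @param x An [ECGCohort-class] or a list of raw records.
#' @return `list(tensors = ECGTensorSet of the successes (input order),
#'   failures = data.frame(record_id, message))`.
#' @export
batchPreprocess <- function(x) {
  records <- if (is(x, "ECGCohort")) x@records else x
  oks <- list()
  fails <- list()
  for (rec in records) {
    res <- tryCatch(preprocessRecord(rec), pclr_error = function(e) e)
    if (inherits(res, "error")) {
      rid <- if (!is.null(rec$recordId)) rec$recordId else "<unknown>"
      fails[[length(fails) + 1L]] <- data.frame(record_id = rid,
                                                message = conditionMessage(res))
    } else {
      oks[[length(oks) + 1L]] <- res
    }
  }
  n <- length(oks)
  arr <- array(0, c(TARGET_SAMPLES, 12L, n))
  rids <- character(n); pids <- character(n)
  for (i in seq_len(n)) {
    arr[, , i] <- oks[[i]]$values
    rids[i] <- oks[[i]]$recordId
    pids[i] <- if (is.null(oks[[i]]$patientId)) NA_character_ else oks[[i]]$patientId
  }
  ts <- new("ECGTensorSet", tensors = arr, recordIds = rids, patientIds = pids)
  failures <- if (length(fails)) do.call(rbind, fails) else {
    data.frame(record_id = character(), message = character())
  }
  list(tensors = ts, failures = failures)
}

#' Thin a tensor set along the time axis
#'
#' Keeps every `factor`-th sample of each record, e.g. factor 8 turns the
#' canonical 4,096-sample grid into 512 samples. A desk-scale device for
#' feeding small encoder instances; the full-size encoder consumes the
#' 4,096-sample grid directly.
#'
#' @param tensorSet An [ECGTensorSet-class].
#' @param factor Positive integer dividing the sample count.
#' @return An [ECGTensorSet-class] with `samples / factor` rows per record.
#' @export
thinTensorSet <- function(tensorSet, factor) {
  stopifnot(is(tensorSet, "ECGTensorSet"), factor >= 1)
  d <- dim(tensorSet@tensors)
  if (d[1] %% factor != 0) {
    pclrError(sprintf("thinning factor %d does not divide %d samples", factor, d[1]),
              "pclr_config_error")
  }
  keep <- seq(1, d[1], by = factor)
  new("ECGTensorSet",
      tensors = tensorSet@tensors[keep, , , drop = FALSE],
      recordIds = tensorSet@recordIds, patientIds = tensorSet@patientIds)
}
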