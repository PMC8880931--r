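#' @importFrom stats approx rnorm runif rbinom rlnorm sd quantile coef predict
#' @importFrom utils head tail str
#' @importFrom data.table fwrite fread
#' @importFrom jsonlite toJSON write_json read_json
#' @importFrom yaml read_yaml
NULL

#' Standard 12-lead order
#'
#' The fixed lead order used for every preprocessed ECG matrix:
#' I, II, III, AVR, AVL, AVF, V1--V6.
#'
#' @return Character vector of the 12 lead labels.
#' @export
leadOrder <- function() {
  c("I", "II", "III", "AVR", "AVL", "AVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

## Evaluate `expr` under a temporary RNG state so package functions are
## reproducible from an explicit seed without clobbering the caller's stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed from a user seed; stays < 2^31.
deriveSeed <- function(seed, offset) {
  s <- (as.double(seed) %% 1000003) + 1
  as.integer((s * 8191 + as.double(offset) * 7919 + 12345) %% 2147483629)
}

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

## FNV-1a over serialized R objects; used for pipeline stage caching.
configHash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2L)
  raw <- as.integer(raw[-seq_len(14L)]) # drop header (R version stamp)
  h <- 2166136261
  for (b in raw) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

#' Positive-class f1 score
#'
#' Harmonic mean of precision and recall for the designated positive class.
#' Returns 0 when the model predicts no positives and there are no true
#' positives to find.
#'
#' @param truth Vector of true labels.
#' @param pred Vector of predicted labels, same length and coding as `truth`.
#' @param positive The label value treated as the positive class (default 1).
#' @return f1 in \[0, 1\].
#' @export
f1Score <- function(truth, pred, positive = 1) {
  stopifnot(length(truth) == length(pred))
  tp <- sum(truth == positive & pred == positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Coefficient of determination
#'
#' `r2 = 1 - SS_res / SS_tot`, with `SS_tot` taken about the mean of `truth`.
#'
#' @param truth Numeric vector of true values.
#' @param pred Numeric vector of predictions.
#' @return r-squared (can be negative for predictions worse than the mean).
#' @export
r2Score <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((truth - pred)^2) / sst
}

## Rank-based AUC (Mann-Whitney), used in generator diagnostics.
aucScore <- function(truth, score) {
  r <- rank(score)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  stopifnot(n1 > 0, n0 > 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
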