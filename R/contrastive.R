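## Normalized temperature-scaled cross-entropy (NT-Xent) on patient pairs.
##
## For a batch of N patients with projections z_1 ... z_2N and positive pair
## (i, j):
##   l(i, j) = -log exp(sim(z_i, z_j)/tau) / sum_{k != i} exp(sim(z_i, z_k)/tau)
## and the batch loss sums l(p1, p2) over patients. The printed batch loss is
## asymmetric (it does not add l(p2, p1)); a `symmetric` switch provides the
## SimCLR convention. Computation uses log-sum-exp stabilization, and
## projection norms are floored at 1e-12 so all-zero projections (possible
## under a ReLU head) are handled rather than fatal.

NORM_EPS <- 1e-12

#' Contrastive loss configuration
#'
#' @param temperature Positive temperature tau of the softmax (default 0.1).
#' @param symmetric If `TRUE`, the batch loss sums `l(p1,p2) + l(p2,p1)`
#'   per patient (SimCLR convention); default `FALSE` sums only `l(p1,p2)`.
#' @return Validated config list of class `lossConfig`.
#' @export
lossConfig <- function(temperature = 0.1, symmetric = FALSE) {
  if (!is.numeric(temperature) || temperature <= 0) {
    pclrError("temperature must be > 0", "pclr_config_error")
  }
  structure(list(temperature = temperature, symmetric = isTRUE(symmetric)),
            class = c("lossConfig", "list"))
}

#' Cosine similarity
#'
#' Inner product of the unit-normalized vectors; undefined (an error) for a
#' zero vector.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Similarity in \[-1, 1\].
#' @export
cosineSimilarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    pclrError("cosine similarity undefined for a zero vector", "pclr_zero_vector")
  }
  sum(u * v) / (nu * nv)
}

## Unit-normalize projection rows with the documented norm floor.
normalizeRows <- function(Z) {
  nrm <- sqrt(rowSums(Z^2))
  Z / pmax(nrm, NORM_EPS)
}

#' Loss of one positive pair
#'
#' Evaluates `l(i, j)` for anchor `i` and positive `j` within a projection
#' batch: the numerator uses the positive pair, the denominator sums over
#' all `k != i` (including `k = j`), with log-sum-exp stabilization.
#'
#' @param i,j Distinct positions in `1 ... 2N`.
#' @param projections Numeric `2N x d` matrix of projections.
#' @param config A [lossConfig()].
#' @return Nonnegative loss value.
#' @examples
#' z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
#' pairLoss(1, 2, z, lossConfig(temperature = 0.1))
#' @export
pairLoss <- function(i, j, projections, config = lossConfig()) {
  if (i == j) pclrError("pair loss needs two distinct positions", "pclr_config_error")
  stopifnot(nrow(projections) >= 2)
  U <- normalizeRows(projections)
  s <- as.vector(U %*% U[i, ]) / config$temperature
  lse <- logSumExp(s[-i])
  max(lse - s[j], 0)
}

#' Batch contrastive loss
#'
#' Sums the pair losses of all positive pairs in a batch; optionally (and
#' off by default) also the reversed-anchor terms. Can return the analytic
#' gradient with respect to the projection matrix, used by the pre-training
#' loop.
#'
#' @param projections Numeric `2N x d` matrix aligned with `pairIndex`.
#' @param pairIndex Integer `N x 2` matrix of pair positions (see
#'   [ContrastiveBatch-class]).
#' @param config A [lossConfig()].
#' @param gradient If `TRUE`, also return `dL/dprojections`.
#' @return The loss, or `list(loss, grad)` when `gradient = TRUE`.
#' @export
batchLoss <- function(projections, pairIndex, config = lossConfig(),
                      gradient = FALSE) {
  n2 <- nrow(projections)
  if (!is.matrix(pairIndex) || ncol(pairIndex) != 2 ||
      nrow(pairIndex) * 2L != n2 ||
      !setequal(as.vector(pairIndex), seq_len(n2))) {
    pclrError("pair index inconsistent with batch size", "pclr_config_error")
  }
  tau <- config$temperature
  nrm <- sqrt(rowSums(projections^2))
  nrmF <- pmax(nrm, NORM_EPS)
  U <- projections / nrmF
  S <- tcrossprod(U) / tau
  anchors <- if (config$symmetric) {
    rbind(pairIndex, pairIndex[, 2:1, drop = FALSE])
  } else pairIndex
  loss <- 0
  G <- if (gradient) matrix(0, n2, n2) else NULL
  for (r in seq_len(nrow(anchors))) {
    a <- anchors[r, 1]
    pp <- anchors[r, 2]
    row <- S[a, ]
    m <- max(row[-a])
    w <- exp(row - m)
    w[a] <- 0
    Zs <- sum(w)
    loss <- loss + (m + log(Zs)) - row[pp]
    if (gradient) {
      sm <- w / Zs
      sm[pp] <- sm[pp] - 1
      G[a, ] <- G[a, ] + sm / tau
    }
  }
  if (!gradient) return(loss)
  ## dL/dU = G U + G^t U, then back through row normalization
  dU <- G %*% U + crossprod(G, U)
  dZ <- (dU - U * rowSums(dU * U)) / nrmF
  list(loss = loss, grad = dZ)
}
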