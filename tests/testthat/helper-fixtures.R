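# Shared fixtures and independent oracles, all built in code.

# Small cohort shortcuts -------------------------------------------------

smallCohort <- function(nPatients = 4, visits = c(2, 3), seed = 11, ...) {
  generateCohort(nPatients, visits = visits, seed = seed, ...)
}

# A record-id-only tensor set: 1 sample per record, used where only the
# patient/record index structure matters (pair sampling contracts).
indexTensorSet <- function(recordsPerPatient) {
  pids <- rep(sprintf("P%04d", seq_along(recordsPerPatient)), recordsPerPatient)
  rids <- paste0(pids, "_E", unlist(lapply(recordsPerPatient, seq_len)))
  new("ECGTensorSet", tensors = array(0, c(1, 12, length(rids))),
      recordIds = rids, patientIds = pids)
}

# Raw record built by hand (for preprocessing contracts).
rawRecord <- function(leads, fs = 250, rid = "R1", pid = "P1") {
  list(leads = leads, samplingRate = fs, patientId = pid, recordId = rid)
}

leadsMatrix <- function(values) {
  m <- matrix(values, length(values), 12)
  colnames(m) <- leadOrder()
  m
}

# Independent scalar oracle for the contrastive loss: plain double loop on
# the printed formula, no log-sum-exp, no vectorization.
naiveBatchLoss <- function(Z, pairIndex, tau, symmetric = FALSE) {
  cosim <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  n2 <- nrow(Z)
  ell <- function(i, j) {
    den <- 0
    for (k in seq_len(n2)) if (k != i) den <- den + exp(cosim(Z[i, ], Z[k, ]) / tau)
    -log(exp(cosim(Z[i, ], Z[j, ]) / tau) / den)
  }
  total <- 0
  for (p in seq_len(nrow(pairIndex))) {
    total <- total + ell(pairIndex[p, 1], pairIndex[p, 2])
    if (symmetric) total <- total + ell(pairIndex[p, 2], pairIndex[p, 1])
  }
  total
}

# Closed-form ridge oracle (intercept via centering).
ridgeOracle <- function(X, y, lambda) {
  yc <- y - mean(y)
  solve(crossprod(X) + diag(lambda, ncol(X)), crossprod(X, yc))
}

randomProjBatch <- function(nPairs, width) {
  Z <- matrix(rnorm(2 * nPairs * width), 2 * nPairs, width)
  pairs <- cbind(seq(1, 2 * nPairs, by = 2), seq(2, 2 * nPairs, by = 2))
  list(Z = Z, pairs = pairs)
}
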