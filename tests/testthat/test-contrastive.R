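test_that("cosine similarity satisfies its defining identities", {
  set.seed(8)
  v <- rnorm(6)
  expect_equal(cosineSimilarity(v, v), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 1), c(-1, -1)), -1)
  expect_equal(cosineSimilarity(3 * v, 0.5 * v), 1)
  expect_error(cosineSimilarity(c(0, 0), c(1, 2)), class = "pclr_zero_vector")
})

test_that("a batch of one patient has exactly zero loss", {
  set.seed(9)
  Z <- matrix(rnorm(2 * 7), 2, 7)
  expect_equal(pairLoss(1, 2, Z, lossConfig(0.1)), 0)
  expect_equal(batchLoss(Z, matrix(c(1L, 2L), 1), lossConfig(0.1)), 0)
})

test_that("hand-evaluated loss values are reproduced", {
  # all four projections identical, tau = 1: softmax uniform over 3 terms
  Z <- matrix(1, 4, 5)
  pairs <- cbind(c(1L, 3L), c(2L, 4L))
  expect_equal(pairLoss(1, 2, Z, lossConfig(1)), log(3), tolerance = 1e-12)
  expect_equal(batchLoss(Z, pairs, lossConfig(1)), 2 * log(3), tolerance = 1e-12)
  # orthogonal pairs at tau = 0.1: l(1,2) = log(1 + 2 exp(-10))
  Z2 <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  expect_equal(pairLoss(1, 2, Z2, lossConfig(0.1)), log(1 + 2 * exp(-10)),
               tolerance = 1e-12)
})

test_that("vectorized batch loss matches the scalar double-loop oracle", {
  set.seed(10)
  for (rep in 1:60) {
    nPairs <- sample(1:8, 1)
    width <- sample(2:16, 1)
    tau <- sample(c(0.05, 0.1, 0.5, 1), 1)
    symmetric <- rep %% 2 == 0
    pb <- randomProjBatch(nPairs, width)
    got <- batchLoss(pb$Z, pb$pairs, lossConfig(tau, symmetric = symmetric))
    want <- naiveBatchLoss(pb$Z, pb$pairs, tau, symmetric = symmetric)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("batch loss is invariant to patient order and projection rescaling", {
  set.seed(11)
  pb <- randomProjBatch(5, 8)
  base <- batchLoss(pb$Z, pb$pairs, lossConfig(0.1))
  perm <- sample(nrow(pb$pairs))
  expect_equal(batchLoss(pb$Z, pb$pairs[perm, ], lossConfig(0.1)), base)
  Zs <- pb$Z
  Zs[3, ] <- 17.3 * Zs[3, ]
  Zs[8, ] <- 0.002 * Zs[8, ]
  expect_equal(batchLoss(Zs, pb$pairs, lossConfig(0.1)), base, tolerance = 1e-9)
})

test_that("increasing positive-pair similarity strictly decreases the pair loss", {
  set.seed(12)
  pb <- randomProjBatch(4, 6)
  Z <- pb$Z
  z1 <- Z[1, ] / sqrt(sum(Z[1, ]^2))
  w <- rnorm(6); w <- w - sum(w * z1) * z1; w <- w / sqrt(sum(w^2))
  sims <- c(); losses <- c()
  for (theta in seq(2.5, 0.1, by = -0.4)) {
    Z[2, ] <- cos(theta) * z1 + sin(theta) * w
    sims <- c(sims, cosineSimilarity(Z[1, ], Z[2, ]))
    losses <- c(losses, pairLoss(1, 2, Z, lossConfig(0.1)))
  }
  expect_true(all(diff(sims) > 0))
  expect_true(all(diff(losses) < 0))
})

test_that("the loss flattens to log(2N - 1) in the infinite-temperature limit", {
  set.seed(13)
  for (nPairs in c(2, 5)) {
    pb <- randomProjBatch(nPairs, 4)
    l <- pairLoss(pb$pairs[1, 1], pb$pairs[1, 2], pb$Z, lossConfig(1e6))
    expect_equal(l, log(2 * nPairs - 1), tolerance = 1e-4)
  }
})

test_that("the analytic gradient matches finite differences", {
  set.seed(14)
  pb <- randomProjBatch(3, 5)
  for (symmetric in c(FALSE, TRUE)) {
    cfg <- lossConfig(0.2, symmetric = symmetric)
    bl <- batchLoss(pb$Z, pb$pairs, cfg, gradient = TRUE)
    eps <- 1e-6
    for (i in sample(length(pb$Z), 12)) {
      Zp <- pb$Z; Zp[i] <- Zp[i] + eps
      Zm <- pb$Z; Zm[i] <- Zm[i] - eps
      num <- (batchLoss(Zp, pb$pairs, cfg) - batchLoss(Zm, pb$pairs, cfg)) / (2 * eps)
      expect_lt(abs(num - bl$grad[i]), 1e-5 * max(1, abs(num)))
    }
  }
})

test_that("degenerate inputs are handled as documented", {
  # i = j is a named error
  Z <- matrix(rnorm(8), 4, 2)
  expect_error(pairLoss(2, 2, Z, lossConfig(0.1)), class = "pclr_config_error")
  # inconsistent pairing is a named error
  expect_error(batchLoss(Z, cbind(1L, 2L), lossConfig(0.1)),
               class = "pclr_config_error")
  # an all-zero projection row is floored, not fatal
  Z[1, ] <- 0
  expect_true(is.finite(batchLoss(Z, cbind(c(1L, 3L), c(2L, 4L)), lossConfig(0.1))))
  # temperature must be positive
  expect_error(lossConfig(0), class = "pclr_config_error")
})
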