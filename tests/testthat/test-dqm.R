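test_that("QC-FC is the per-pair Pearson correlation with the SQM", {
  set.seed(40)
  n <- 20
  sqm <- runif(n, 0.05, 0.4)
  z <- matrix(rnorm(n * 4), n, 4)
  z[, 2] <- 0.5 + 2 * sqm            # perfect positive linear
  z[, 3] <- 1 - 3 * sqm              # perfect negative linear
  qc <- qcfc(z, sqm)
  expect_equal(qc$values[2], 1, tolerance = 1e-12)
  expect_equal(qc$values[3], -1, tolerance = 1e-12)
  expect_equal(qc$values[1], cor(sqm, z[, 1]), tolerance = 1e-12)
  expect_error(qcfc(z, rep(0.2, n)), "zero-variance")
})

test_that("permuting subject labels destroys QC-FC", {
  set.seed(41)
  n <- 40
  sqm <- runif(n, 0.05, 0.4)
  z <- matrix(rep(2 * sqm, 10), n, 10) + rnorm(n * 10, sd = 0.05)
  strong <- mean(abs(qcfc(z, sqm)$values))
  perm <- mean(abs(qcfc(z, sample(sqm))$values))
  expect_gt(strong, 0.9)
  expect_lt(perm, 0.5)
})

test_that("qcfc_summaries: trivial and rank-perfect cases", {
  qz <- structure(list(values = rep(0, 10), n = 20, which = "mean_fd"),
                  class = "qcfc")
  s <- qcfc_summaries(qz, pair_distances = 1:10)
  expect_equal(s$median_abs, 0)
  expect_equal(s$null_rejection_rate, 0)
  expect_equal(as.numeric(s$distance_corr), 0)
  expect_true(isTRUE(attr(s$distance_corr, "undefined")))
  d <- seq(10, 100, by = 10)
  qz2 <- structure(list(values = -d / 200, n = 20, which = "mean_fd"),
                   class = "qcfc")
  expect_equal(as.numeric(qcfc_summaries(qz2, d)$distance_corr), -1)
})

test_that("FDR rejection under an exact null is conservative", {
  set.seed(42)
  n <- 60
  rates <- replicate(30, {
    z <- matrix(rnorm(n * 50), n, 50)
    sqm <- runif(n)
    qcfc_summaries(qcfc(z, sqm), pair_distances = runif(50, 10, 100))$null_rejection_rate
  })
  expect_lt(mean(rates), 0.02)
})

test_that("high-low: identical RSFC gives rate 0; tercile size enforced", {
  n <- 12
  z <- matrix(0.4, n, 6)
  hl <- highlow_rejection(z, seq(0.1, 0.4, length.out = n),
                          alpha = c(0.01, 0.05, 0.1))
  expect_equal(hl$rate, rep(0, 3))
  expect_error(highlow_rejection(z[1:5, ], seq_len(5)), "6 subjects")
})

test_that("high-low type-I calibration under the null", {
  set.seed(43)
  n <- 60
  rates <- replicate(40, {
    z <- matrix(rnorm(n * 60), n, 60)
    highlow_rejection(z, runif(n), alpha = 0.05)$rate
  })
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("glm_metrics recovers an exact distance-linear structure", {
  set.seed(44)
  n <- 25
  d <- runif(30, 10, 120)
  sqm <- runif(n, 0.05, 0.3)
  z <- matrix(rep(0.2 + 0.004 * d, each = n), n, 30)
  g <- glm_metrics(z, sqm, d)
  expect_equal(g$rsfc_distance_slope, 0.004, tolerance = 1e-10)
  expect_equal(g$mean_rsfc, 0.2, tolerance = 1e-10)
  expect_equal(g$mean_qcfc, 0, tolerance = 1e-10)
  expect_equal(g$qcfc_distance_slope, 0, tolerance = 1e-10)
  # per-mm units: doubling the SQM halves the QC-FC slope metrics
  z2 <- z + outer(sqm, rep(0.5, 30))
  g1 <- glm_metrics(z2, sqm, d)
  g2 <- glm_metrics(z2, 2 * sqm, d)
  expect_equal(g2$mean_qcfc, g1$mean_qcfc / 2, tolerance = 1e-10)
})

test_that("glm step-1 intercepts equal pair means with centered SQM", {
  set.seed(45)
  z <- matrix(rnorm(15 * 8), 15, 8)
  sqm <- runif(15)
  g <- glm_metrics(z, sqm, rep(50, 8))
  # with constant distance, step-2 intercept = mean of step-1 intercepts
  expect_equal(g$mean_rsfc, mean(colMeans(z)), tolerance = 1e-12)
})

test_that("variance_change identities", {
  set.seed(46)
  z <- matrix(rnorm(20 * 10), 20, 10)
  rownames(z) <- sprintf("s%02d", 1:20)
  expect_equal(variance_change(z, z), 0)
  shrunk <- sweep(sweep(z, 2, colMeans(z)), 2, rep(0.9, 10), `*`) +
    rep(colMeans(z), each = 20)
  expect_equal(variance_change(shrunk, z),
               (0.81 - 1) * mean(apply(z, 2, var)), tolerance = 1e-12)
})
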