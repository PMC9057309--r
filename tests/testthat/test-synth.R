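test_that("generator geometry and determinism", {
  cfg <- synth_config(n_subjects = 3, runs_per_subject = 2, T = 240,
                      n_roi = 5, seed = 7)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  expect_length(ds1$runs, 6)
  expect_equal(dim(ds1$runs[[1]]$data), c(240, 5))
  expect_identical(ds1$runs[[4]]$data, ds2$runs[[4]]$data)
  expect_identical(ds1$runs[[4]]$motion$values, ds2$runs[[4]]$motion$values)
  ds3 <- simulate_dataset(synth_config(n_subjects = 3, runs_per_subject = 2,
                                       T = 240, n_roi = 5, seed = 8))
  expect_false(identical(ds1$runs[[1]]$data, ds3$runs[[1]]$data))
  expect_length(ds1$ground_truth_z, 10)
  expect_length(ds1$pair_dist, 10)
})

test_that("config invariants are enforced", {
  expect_error(synth_config(T = 100), "240")
  expect_error(synth_config(resp_freq = 0.8), "Nyquist")
  bad_cov <- matrix(c(1, 2, 2, 1), 2) # not PSD
  expect_error(synth_config(n_roi = 2, network_covariance = bad_cov),
               "positive semi-definite")
  expect_error(synth_config(n_roi = 3,
                            network_covariance = matrix(rnorm(9), 3)),
               "symmetric")
})

test_that("FD of simulated motion has its spectral peak at resp_freq", {
  cfg <- synth_config(T = 600, seed = 3, spike_rate = 0)
  mt <- simulate_motion_trace(cfg, subject_severity = 1, seed = 21)
  fd <- compute_fd(mt, "standard")$values[-1]
  fd <- fd - mean(fd)
  sp <- Mod(fft(fd))^2
  freqs <- (seq_along(fd) - 1) / (length(fd) * cfg$TR)
  half <- freqs > 0.05 & freqs < 1 / (2 * cfg$TR)
  peak <- freqs[half][which.max(sp[half])]
  expect_equal(peak, cfg$resp_freq, tolerance = 0.02)
})

test_that("empirical run correlations track the observed-signal ground truth", {
  cfg <- synth_config(n_subjects = 1, runs_per_subject = 1, T = 6000,
                      n_roi = 4, seed = 5, artifact_coupling = 0)
  ds <- simulate_dataset(cfg)
  r <- cor(ds$runs[[1]]$data)
  z_emp <- atanh(r[upper.tri(r)])
  expect_equal(z_emp, ds$ground_truth_z, tolerance = 0.06)
})

test_that("artifact coupling inflates connectivity, more at short distance", {
  cfg0 <- synth_config(n_subjects = 6, runs_per_subject = 1, T = 480,
                       n_roi = 8, seed = 9, artifact_coupling = 0)
  cfg1 <- synth_config(n_subjects = 6, runs_per_subject = 1, T = 480,
                       n_roi = 8, seed = 9, artifact_coupling = 2)
  z0 <- rsfc_pipeline(simulate_dataset(cfg0))$z
  z1 <- rsfc_pipeline(simulate_dataset(cfg1))$z
  expect_gt(mean(z1) - mean(z0), 0)
})

test_that("confounded cohort: trait shifts truth and severity", {
  cfg <- synth_config(n_subjects = 6, runs_per_subject = 1, T = 240,
                      n_roi = 6, seed = 13)
  ds <- simulate_confounded_cohort(cfg, trait_effect = 0.3,
                                   severity_factor = 1.5)
  expect_identical(ds$subjects$trait, rep(c(TRUE, FALSE), 3))
  tz <- ds$subject_truth_z
  hub_pair <- 1 # pair (1,2), both in the hub set
  expect_equal(tz[1, hub_pair] - tz[2, hub_pair], 0.3, tolerance = 1e-12)
  # non-hub pair unchanged
  pr <- roi_pairs(6)
  far <- which(pr$i >= 5)[1]
  expect_equal(tz[1, far], tz[2, far], tolerance = 1e-12)
  expect_equal(ds$subjects$severity[1] / ds$subjects$severity[2] *
                 cfg$motion_level[2] / cfg$motion_level[1], 1.5,
               tolerance = 1e-12)
})
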