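toy_table <- function(dz) {
  structure(list(delta_z = dz, z = dz, n_rand = 10,
                 n_runs = rep(1, nrow(dz)), seed = 1),
            class = "delta_z_table")
}

test_that("Eq. 2 hand arithmetic and sign invariance", {
  dz <- rbind(c(0.1, -0.3), c(0.2, 0))
  expect_equal(mac_rsfc(toy_table(dz), boot = 0)$mac, 0.15)
  expect_equal(mac_rsfc(toy_table(matrix(0, 3, 4)), boot = 0)$mac, 0)
  flip <- dz * matrix(c(1, -1, -1, 1), 2)
  expect_equal(mac_rsfc(toy_table(flip), boot = 0)$mac, 0.15)
})

test_that("no censoring gives delta z identically zero and MAC-RSFC 0", {
  ds <- small_dataset()
  plan <- full_plan(ds) # thresholds above every framewise value
  tab <- delta_z(ds, plan, n_rand = 3, seed = 5)
  expect_true(all(tab$delta_z == 0))
  expect_equal(mac_rsfc(tab, boot = 0)$mac, 0)
})

test_that("delta_z matches a brute-force rebuild of every random pipeline", {
  ds <- small_dataset()
  plan <- fd_plan(ds, 10)
  n_rand <- 4; seed <- 17
  tab <- delta_z(ds, plan, n_rand = n_rand, seed = seed)
  # brute force for subject 1 (runs 1-2): run full rsfc_pipeline per mask
  subj_ids <- vapply(ds$runs, `[[`, character(1), "subject")
  band <- filter_spec("bandpass", c(0.009, 0.08))
  dsn <- normalize_dataset(ds)
  run_dz <- lapply(which(subj_ids == "sub001" & plan$runs$included),
                   function(i) {
    keep <- plan$keep[[i]]
    run <- dsn$runs[[i]]
    # explicit reference pipeline per mask
    single <- function(k) {
      pr <- preprocess_run(run$data, run$TR, k, band, trim = 30)
      X <- nuisance_design(run$motion, run$nuisance$WM, run$nuisance$CSF,
                           gs = NULL, keep = k, TR = run$TR, band = band,
                           trim = 30)
      partial_corr_z(pr$data, X)
    }
    zt <- single(keep)
    zr <- lapply(seq_len(n_rand), function(p)
      single(random_mask_like(keep, mbcensor:::derive_seed(seed, 1, i, p))))
    zt - Reduce(`+`, zr) / n_rand
  })
  brute <- colMeans(do.call(rbind, run_dz))
  expect_equal(as.numeric(tab$delta_z["sub001", ]), brute, tolerance = 1e-12)
})

test_that("doubling n_rand changes delta z less than the Monte-Carlo SE", {
  ds <- small_dataset()
  plan <- fd_plan(ds, 12)
  t10 <- delta_z(ds, plan, n_rand = 10, seed = 3)
  t20 <- delta_z(ds, plan, n_rand = 20, seed = 3)
  # the two estimates share no permutation-level variance bound, so compare
  # the shift in MAC against the across-subject SE of the contributions
  se <- sd(rowMeans(abs(t10$delta_z))) / sqrt(nrow(t10$delta_z))
  expect_lt(abs(mac_rsfc(t10, boot = 0)$mac - mac_rsfc(t20, boot = 0)$mac), se)
})

test_that("BCa: equivariance, degeneracy, symmetric ~ percentile", {
  set.seed(50)
  x <- rnorm(40, 1, 0.3)
  ci <- bca_ci(x, B = 4000, seed = 2)
  ci_shift <- bca_ci(x + 5, B = 4000, seed = 2)
  expect_equal(ci_shift, ci + 5, tolerance = 1e-10, ignore_attr = TRUE)
  # degenerate input collapses to the point
  cd <- bca_ci(rep(0.2, 10), B = 500, seed = 1)
  expect_equal(as.numeric(cd), c(0.2, 0.2))
  expect_true(isTRUE(attr(cd, "degenerate")))
  # symmetric contributions: BCa close to percentile
  set.seed(51)
  xs <- rnorm(60)
  ci_b <- bca_ci(xs, B = 10000, seed = 3)
  set.seed(3)
  idx <- matrix(sample.int(60, 60 * 10000, replace = TRUE), nrow = 10000)
  thetas <- rowMeans(matrix(xs[idx], nrow = 10000))
  ci_p <- quantile(thetas, c(0.025, 0.975), names = FALSE)
  w <- diff(ci_p)
  expect_lt(max(abs(ci_b - ci_p)), 0.05 * w)
  expect_error(bca_ci(rnorm(5)), "8 subjects")
})

test_that("MAC-RSFC null scales like 1/sqrt(n_rand) and is positive", {
  ds <- small_dataset()
  plan <- fd_plan(ds, 10)
  # substitute an extra random vector for the targeted mask: null condition
  null_plan <- plan
  null_plan$keep <- lapply(seq_along(plan$keep), function(i)
    random_mask_like(plan$keep[[i]], mbcensor:::derive_seed(999, 0, i, 0)))
  m2 <- mac_rsfc(delta_z(ds, null_plan, n_rand = 2, seed = 7), boot = 0)$mac
  m8 <- mac_rsfc(delta_z(ds, null_plan, n_rand = 8, seed = 7), boot = 0)$mac
  expect_gt(m8, 0)
  expect_lt(m8, m2) # decreasing in n_rand
  # two interchangeable random "methods" agree within CI width
  alt_plan <- plan
  alt_plan$keep <- lapply(seq_along(plan$keep), function(i)
    random_mask_like(plan$keep[[i]], mbcensor:::derive_seed(555, 0, i, 0)))
  r1 <- mac_rsfc(delta_z(ds, null_plan, n_rand = 5, seed = 7), boot = 2000)
  r2 <- mac_rsfc(delta_z(ds, alt_plan, n_rand = 5, seed = 7), boot = 2000)
  width <- (r1$ci_high - r1$ci_low) + (r2$ci_high - r2$ci_low)
  expect_lt(abs(r1$mac - r2$mac), width)
})
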