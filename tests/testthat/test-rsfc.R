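test_that("mode-1000 normalization finds the histogram mode", {
  set.seed(30)
  ref <- c(rnorm(5000, 800, 5), rnorm(500, 300, 20)) # mode near 800
  x <- matrix(rnorm(100, 800, 5), 20, 5)
  out <- mode1000_normalize(x, reference = ref)
  expect_equal(attr(out, "scale") * 800, 1000, tolerance = 15)
  expect_equal(out, x * attr(out, "scale"), ignore_attr = TRUE)
  expect_error(mode1000_normalize(matrix(-5, 4, 4)), "positive")
})

test_that("6-connected erosion: 5x5x5 cube erodes to 3x3x3 then 1 voxel", {
  m <- array(FALSE, c(7, 7, 7))
  m[2:6, 2:6, 2:6] <- TRUE
  e1 <- erode_mask(m)
  expect_equal(sum(e1), 27)
  expect_true(all(which(e1, arr.ind = TRUE) >= 3 & which(e1, arr.ind = TRUE) <= 5))
  e2 <- erode_mask(e1)
  expect_equal(sum(e2), 1)
  expect_true(e2[4, 4, 4])
  expect_equal(sum(erode_mask(e2)), 0)
})

test_that("nuisance erosion stops before emptying the mask", {
  arr <- array(1, c(7, 7, 7, 3))
  for (t in 1:3) arr[, , , t] <- t
  brain <- array(TRUE, c(7, 7, 7))
  wm <- array(FALSE, c(7, 7, 7)); wm[2:6, 2:6, 2:6] <- TRUE
  csf <- array(FALSE, c(7, 7, 7)); csf[4, 4, 4] <- TRUE
  out <- compute_nuisance_signals(arr, brain, wm, csf)
  # 5^3 -> 3^3 -> 1 voxel; a third erosion would empty it, so 2 iterations
  expect_equal(unname(out$erosions["WM"]), 2L)
  expect_equal(unname(out$erosions["CSF"]), 0L)
  expect_equal(out$GS, as.numeric(1:3))
  expect_equal(out$WM, as.numeric(1:3))
})

test_that("preprocess_run removes mean and linear trend in the passband", {
  T <- 400; TR <- 0.72
  tt <- seq_len(T)
  x <- 5 + 0.01 * tt + sin(2 * pi * 0.03 * (tt - 1) * TR)
  out <- preprocess_run(x, TR = TR)
  # trend and mean gone; 0.03 Hz passband component survives
  expect_lt(abs(mean(out$data)), 0.05)
  expect_gt(sd(out$data), 0.5)
  expect_equal(out$window, 31:(T - 30))
  expect_equal(out$retained, 31:(T - 30))
})

test_that("censored frames are linearly interpolated before filtering", {
  T <- 300
  keep <- rep(TRUE, T); keep[c(1:3, 150, 298:300)] <- FALSE
  x <- rnorm(T)
  out <- preprocess_run(x, TR = 0.72, keep = keep)
  expect_equal(length(out$retained), sum(keep[31:270]))
  expect_false(150 %in% out$retained)
  expect_error(preprocess_run(x, TR = 0.72, keep = rep(FALSE, T)), "kept")
})

test_that("partial_corr_z matches brute-force residualize-then-correlate", {
  set.seed(31)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4)
  design <- cbind(1, matrix(rnorm(n * 6), n, 6))
  colnames(design) <- c("intercept", paste0("c", 1:6))
  z <- partial_corr_z(x, design)
  E <- apply(x, 2, function(col) residuals(lm(col ~ design - 1)))
  r <- cor(E)
  expect_equal(z, atanh(r[upper.tri(r)]), tolerance = 1e-10)
})

test_that("rank-deficient design errors and names the collinear column", {
  set.seed(32)
  n <- 60
  x <- matrix(rnorm(n * 3), n, 3)
  d <- cbind(intercept = 1, a = rnorm(n), b = 0)
  d <- cbind(d, dup = d[, "a"])
  expect_error(partial_corr_z(x, d), "collinear")
})

test_that("subject_rsfc averages runs", {
  z1 <- c(0.1, 0.2); z2 <- c(0.3, 0.4)
  out <- subject_rsfc(list(z1, z2))
  expect_equal(as.numeric(out), c(0.2, 0.3))
  expect_equal(attr(out, "n_runs"), 2)
})

test_that("pipeline batch engine equals the exported reference path exactly", {
  ds <- normalize_dataset(small_dataset())
  run <- ds$runs[[3]]
  T <- nrow(run$data)
  set.seed(33)
  keep <- rep(TRUE, T); keep[sample(seq(10, T - 10), 25)] <- FALSE
  band <- filter_spec("bandpass", c(0.009, 0.08))
  # reference path: preprocess_run + nuisance_design + partial_corr_z
  pr <- preprocess_run(run$data, run$TR, keep, band, trim = 30)
  X <- nuisance_design(run$motion, run$nuisance$WM, run$nuisance$CSF,
                       gs = NULL, keep = keep, TR = run$TR, band = band,
                       trim = 30)
  z_ref <- partial_corr_z(pr$data, X)
  # batch engine used by rsfc_pipeline / delta_z
  cache <- mbcensor:::run_cache(run, band, gsr = FALSE)
  z_batch <- mbcensor:::run_z_masks(cache, list(keep), band, trim = 30)[[1]]
  expect_equal(z_batch, z_ref, tolerance = 1e-12)
})

test_that("rsfc_pipeline output shape, GSR design size, run averaging", {
  ds <- small_dataset()
  rs <- rsfc_pipeline(ds)
  expect_s3_class(rs, "rsfc_result")
  expect_equal(dim(rs$z), c(10, 15))
  expect_identical(rownames(rs$z), ds$subjects$subject)
  expect_true(all(rs$n_runs == 2))
  # nuisance design has 29 columns (31 with GSR)
  run <- normalize_dataset(ds)$runs[[1]]
  X <- nuisance_design(run$motion, run$nuisance$WM, run$nuisance$CSF,
                       gs = NULL, TR = run$TR)
  expect_equal(ncol(X), 29)
  Xg <- nuisance_design(run$motion, run$nuisance$WM, run$nuisance$CSF,
                        gs = run$nuisance$GS, TR = run$TR)
  expect_equal(ncol(Xg), 31)
  # subject z is the unweighted mean of run z
  plan <- full_plan(ds)
  band <- filter_spec("bandpass", c(0.009, 0.08))
  dsn <- normalize_dataset(ds)
  z_runs <- vapply(1:2, function(i) {
    cache <- mbcensor:::run_cache(dsn$runs[[i]], band, FALSE)
    mbcensor:::run_z_masks(cache, list(rep(TRUE, 300)), band, 30)[[1]]
  }, numeric(15))
  expect_equal(as.numeric(rs$z[1, ]), rowMeans(z_runs), tolerance = 1e-12)
})

test_that("excluded runs and subjects are dropped from the result", {
  ds <- small_dataset()
  masks <- lapply(ds$runs, function(r) rep(TRUE, nrow(r$data)))
  masks[[1]] <- c(rep(TRUE, 100), rep(FALSE, 200)) # run 1 of sub001 dies
  masks[[2]] <- masks[[1]]                         # run 2 of sub001 dies
  plan <- apply_exclusion(masks,
                          vapply(ds$runs, `[[`, character(1), "subject"),
                          vapply(ds$runs, `[[`, character(1), "run"))
  rs <- rsfc_pipeline(ds, plan)
  expect_equal(nrow(rs$z), 9)
  expect_false("sub001" %in% rownames(rs$z))
})
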