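make_mp <- function(values, TR = 0.72, units = "degrees") {
  motion_trace(values, TR = TR, units = units)
}

test_that("FD rotation arc-length convention (50 mm sphere)", {
  T <- 50
  mp <- matrix(0, T, 6)
  mp[25:T, 4] <- 1 # persisting 1 degree rotation step
  fd <- compute_fd(make_mp(mp), "standard")
  expect_equal(fd$values[25], 50 * pi / 180, tolerance = 1e-12)
  expect_equal(fd$values[-25], rep(0, T - 1))
})

test_that("FD sums absolute translation differences; first frame is 0", {
  T <- 40
  mp <- matrix(0, T, 6)
  mp[10, 1] <- 0.3
  mp[10, 2] <- -0.2
  fd <- compute_fd(make_mp(mp), "standard")
  expect_equal(fd$values[1], 0)
  expect_equal(fd$values[10], 0.5, tolerance = 1e-12) # step in
  expect_equal(fd$values[11], 0.5, tolerance = 1e-12) # step out
})

test_that("radian input matches degree input after conversion", {
  set.seed(5)
  deg <- matrix(rnorm(60 * 6, sd = 0.1), 60, 6)
  rad <- deg
  rad[, 4:6] <- rad[, 4:6] * pi / 180
  f1 <- compute_fd(make_mp(deg, units = "degrees"), "standard")
  f2 <- compute_fd(make_mp(rad, units = "radians"), "standard")
  expect_equal(f1$values, f2$values, tolerance = 1e-12)
})

test_that("LPF-FD suppresses respiratory-band motion, keeps slow motion", {
  T <- 600; TR <- 0.72
  tt <- (seq_len(T) - 1) * TR
  slow <- matrix(0, T, 6); slow[, 1] <- 0.5 * sin(2 * pi * 0.02 * tt)
  fast <- matrix(0, T, 6); fast[, 1] <- 0.5 * sin(2 * pi * 0.35 * tt)
  core <- 50:(T - 50)
  red_slow <- mean(compute_fd(make_mp(slow), "lpf")$values[core]) /
    mean(compute_fd(make_mp(slow), "standard")$values[core])
  red_fast <- mean(compute_fd(make_mp(fast), "lpf")$values[core]) /
    mean(compute_fd(make_mp(fast), "standard")$values[core])
  expect_gt(red_slow, 0.9)
  expect_lt(red_fast, 0.2)
})

test_that("notch variant uses the respiratory band-stop by default", {
  T <- 600; TR <- 0.72
  tt <- (seq_len(T) - 1) * TR
  mp <- matrix(0, T, 6); mp[, 2] <- 0.3 * sin(2 * pi * 0.37 * tt)
  fd_n <- compute_fd(make_mp(mp), "notch")
  fd_s <- compute_fd(make_mp(mp), "standard")
  core <- 50:(T - 50)
  expect_lt(mean(fd_n$values[core]), 0.05 * mean(fd_s$values[core]))
  expect_identical(fd_n$filter$kind, "bandstop")
  expect_equal(fd_n$filter$cutoffs, c(0.31, 0.43))
})

test_that("DV is the RMS over series of the backward difference", {
  x <- rbind(c(0, 0), c(3, 4), c(3, 4))
  # pad rows so the length check passes
  dv <- compute_dv(x, TR = 0.72, "standard")
  expect_equal(dv$values, c(0, sqrt((9 + 16) / 2), 0), tolerance = 1e-12)
})

test_that("smooth_gaussian preserves constants and respects the mask", {
  arr <- array(5, c(6, 6, 6))
  out <- smooth_gaussian(arr, fwhm = 4, voxdim = 2)
  expect_equal(out, arr, tolerance = 1e-10)
  mask <- array(FALSE, c(6, 6, 6)); mask[2:5, 2:5, 2:5] <- TRUE
  arr2 <- array(0, c(6, 6, 6)); arr2[mask] <- 7
  out2 <- smooth_gaussian(arr2, fwhm = 4, voxdim = 2, mask = mask)
  expect_equal(out2[mask], rep(7, sum(mask)), tolerance = 1e-10)
  expect_equal(out2[!mask], arr2[!mask]) # untouched outside the mask
})
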