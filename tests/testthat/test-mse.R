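# helper: minimal hand-built sweep_result on an analytic resampled grid
fake_sweep <- function(pgrid, delta_bias, var_c, n_s, var_u, n_su,
                       percent = NULL, param = NULL) {
  n_pair <- nrow(delta_bias)
  if (is.null(percent)) percent <- range(pgrid)
  if (is.null(param)) param <- c(Inf, 1)
  structure(list(method = "lpf-fd", ratio = NULL, targets = percent,
                 param = param, percent = percent,
                 n_s = rep(n_su, length(percent)),
                 delta_bias = delta_bias[, c(1, ncol(delta_bias)), drop = FALSE],
                 var_c = var_c[, c(1, ncol(var_c)), drop = FALSE],
                 var_u = var_u, n_su = n_su, pgrid = pgrid,
                 rs_delta_bias = delta_bias, rs_var = var_c, rs_n_s = n_s,
                 n_pair = n_pair, n_gev_fallback = 0L, n_rand = 10, seed = 1),
            class = "sweep_result")
}

fake_bias <- function(bias_u, sweep) {
  structure(list(bias_u = bias_u, slope = bias_u / 100,
                 converged = rep(TRUE, length(bias_u)), n_fallback = 0L,
                 n_points = length(sweep$pgrid), n_pair = sweep$n_pair,
                 method = sweep$method),
            class = "bias_estimate")
}

test_that("Eqs. 11-12 hand case: Bias_u 0.05, dBias -0.02 -> Bias_c^2 0.0009", {
  pgrid <- c(0, 10)
  sw <- fake_sweep(pgrid,
                   delta_bias = rbind(c(0, -0.02)),
                   var_c = rbind(c(0, 0)), n_s = c(1, 1),
                   var_u = 0, n_su = 1)
  be <- fake_bias(0.05, sw)
  cv <- delta_mse(sw, be)
  # delta_mse at the censored point = Bias_c^2 - Bias_u^2 = 0.0009 - 0.0025
  expect_equal(cv$delta_mse[cv$percent == 10], 0.0009 - 0.0025,
               tolerance = 1e-12)
  expect_equal(cv$delta_mse[cv$percent == 0], 0)
  # full bias removal collapses Bias_c^2 to 0
  sw2 <- fake_sweep(pgrid, rbind(c(0, -0.05)), rbind(c(0, 0)), c(1, 1), 0, 1)
  cv2 <- delta_mse(sw2, fake_bias(0.05, sw2))
  expect_equal(cv2$delta_mse[2], -0.0025, tolerance = 1e-12)
  # mismatched grids error
  expect_error(delta_mse(sw, fake_bias(c(0.05, 0.1), sw)), "mismatch")
})

test_that("overshoot cells are counted, not clamped", {
  pgrid <- c(0, 10)
  sw <- fake_sweep(pgrid, rbind(c(0, -0.12)), rbind(c(0, 0)), c(1, 1), 0, 1)
  cv <- delta_mse(sw, fake_bias(0.05, sw))
  expect_equal(attr(cv, "n_overshoot"), 1)
  # (0.05 - 0.12)^2 - 0.05^2 = 0.0049 - 0.0025 > 0: no silent clamping
  expect_equal(cv$delta_mse[2], 0.0049 - 0.0025, tolerance = 1e-12)
})

test_that("noiseless-line bias extrapolation is exact", {
  pgrid <- seq(0, 60, by = 0.01)
  db <- rbind(-0.001 * pgrid, 0 * pgrid)
  sw <- fake_sweep(pgrid, db, 0 * db, rep(5, length(pgrid)),
                   c(0, 0), 5)
  be <- estimate_uncensored_bias(sw)
  expect_equal(be$bias_u[1], 0.1, tolerance = 1e-10)
  expect_equal(be$bias_u[2], 0)
  expect_true(all(be$converged))
})

test_that("bisquare IRLS resists gross outliers where OLS does not", {
  set.seed(60)
  pgrid <- seq(0, 80, by = 0.1)
  y <- 0.001 * pgrid
  out_idx <- sample(which(pgrid > 60), ceiling(0.05 * length(pgrid)))
  y[out_idx] <- y[out_idx] + 0.3
  fit <- mbcensor:::irls_origin_slope(pgrid, y)
  ols <- sum(pgrid * y) / sum(pgrid^2)
  expect_lt(abs(fit$slope * 100 - 0.1) / 0.1, 0.05)
  expect_gt(abs(ols * 100 - 0.1) / 0.1, 0.15)
})

test_that("optimize_single: constructed parabola, boundary, errors", {
  p <- seq(0, 80, by = 0.01)
  parab <- data.frame(percent = p, delta_mse = (p - 35)^2 * 1e-6 - 0.001)
  opt <- optimize_single(parab)
  expect_equal(opt$percent_removed, 35, tolerance = 0.01)
  mono <- data.frame(percent = p, delta_mse = 1e-5 * p)
  expect_equal(optimize_single(mono)$percent_removed, 0)
  bad <- data.frame(percent = p, delta_mse = ifelse(p > 40, NaN, 0))
  expect_error(optimize_single(bad), "non-finite")
  # restricted range avoids the non-finite region
  expect_equal(optimize_single(bad, c(0, 39))$delta_mse, 0)
})

test_that("sweep anchors, quantile inversion, and plan bookkeeping", {
  ds <- small_dataset()
  sw <- sweep_censoring(ds, "lpf-fd", targets = c(0, 10, 20), n_rand = 3,
                        seed = 4)
  expect_equal(sw$percent[1], 0)
  expect_true(all(sw$delta_bias[, 1] == 0))
  expect_equal(sw$var_c[, 1], sw$var_u, tolerance = 1e-12)
  expect_equal(sw$n_s[1], sw$n_su)
  # realized percents within 1 of the targets
  expect_equal(sw$percent[2], 10, tolerance = 1)
  expect_equal(sw$percent[3], 20, tolerance = 1)
  # delta_bias is never positive (Eq. 7)
  expect_true(all(sw$delta_bias[is.finite(sw$delta_bias)] <= 0))
  # the resampled curve gives delta-MSE exactly 0 at 0%
  cv <- delta_mse(sw, estimate_uncensored_bias(sw))
  expect_equal(cv$delta_mse[1], 0, tolerance = 1e-14)
})

test_that("gev-dv sweep hits percent targets via d_G inversion", {
  ds <- small_dataset()
  sw <- sweep_censoring(ds, "gev-dv", targets = c(0, 10), n_rand = 2,
                        seed = 4)
  expect_equal(sw$percent[2], 10, tolerance = 1.5)
  expect_identical(sw$param[1], Inf)
})

test_that("combined-ratio: union property and threshold saturation", {
  ds <- normalize_dataset(small_dataset())
  fw <- mbcensor:::sweep_framewise(ds, "combined-ratio", "lpf", "lpf")
  # at a common (phi_F, d_G), combined flags are a superset of each method's
  d_g <- 1.2; phi_f <- 0.03
  mk_f <- lapply(fw$fd, function(v) v <= phi_f)
  mk_d <- lapply(seq_along(fw$dv), function(i)
    fw$dv[[i]] <= gev_dv_threshold(fw$gev[[i]], d_g, fw$dv[[i]]))
  mk_c <- mbcensor:::method_masks(fw, "combined-ratio", d_g,
                                  ratio = phi_f / d_g)
  for (i in seq_along(mk_c)) {
    expect_true(all(which(!mk_f[[i]]) %in% which(!mk_c[[i]])))
    expect_true(all(which(!mk_d[[i]]) %in% which(!mk_c[[i]])))
    expect_identical(mk_c[[i]], mk_f[[i]] & mk_d[[i]])
  }
  # ratio -> infinity: FD never flags, combined == GEV-DV alone
  mk_sat <- mbcensor:::method_masks(fw, "combined-ratio", d_g, ratio = 1e12)
  for (i in seq_along(mk_sat)) expect_identical(mk_sat[[i]], mk_d[[i]])
})

test_that("bias-variance identity against brute-force MSE (Eq. 5)", {
  set.seed(61)
  z <- matrix(rnorm(30 * 8, 0.2, 0.1), 30, 8)
  truth <- runif(8, 0, 0.4)
  brute <- mean(vapply(1:8, function(k)
    (mean(z[, k]) - truth[k])^2 + var(z[, k]) / 30, numeric(1)))
  expect_equal(truth_referenced_mse(z, truth), brute, tolerance = 1e-12)
})

test_that("optimize_2d_grid: degenerate grid and containment", {
  ds <- small_dataset()
  sw <- sweep_censoring(ds, "combined-ratio", targets = c(0, 10, 20),
                        ratio = 0.025, n_rand = 2, seed = 4)
  be <- estimate_uncensored_bias(sw)
  one <- suppressMessages(
    optimize_2d_grid(ds, phi_grid = 0.03, dg_grid = 1.2, bias = be,
                     n_rand = 2, seed = 4))
  expect_equal(one$phi_f, 0.03)
  expect_equal(one$d_g, 1.2)
  grid <- suppressMessages(
    optimize_2d_grid(ds, phi_grid = c(0.02, 0.03, 0.05),
                     dg_grid = c(0.9, 1.2), bias = be, n_rand = 2, seed = 4))
  expect_lte(grid$delta_mse, one$delta_mse)
})
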