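# Delta-MSE-RSFC (Eqs. 3-12): censoring-parameter sweeps re-parameterized by
# percent of volumes removed, extrapolation of the uncensored bias by robust
# regression through the origin, the bias-variance change in mean squared
# error per retained subject count, and 1D / fixed-ratio / 2D optimizers.

# ---- threshold solvers ------------------------------------------------------

# per-run framewise values used by each censoring method
sweep_framewise <- function(dataset, method, fd_variant, dv_variant) {
  out <- list()
  if (method %in% c("lpf-fd", "combined-ratio"))
    out$fd <- dataset_framewise(dataset, "fd", fd_variant)
  if (method %in% c("gev-dv", "combined-ratio")) {
    out$dv <- dataset_framewise(dataset, "dv", dv_variant)
    out$gev <- lapply(out$dv, function(v) fit_gev(v[-1]))
  }
  out
}

# flagged-percent realized by a parameter value, and the per-run keep masks
method_masks <- function(fw, method, param, ratio = NULL) {
  n_runs <- length(if (is.null(fw$fd)) fw$dv else fw$fd)
  masks <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    keep <- NULL
    if (method %in% c("lpf-fd", "combined-ratio")) {
      phi_f <- if (method == "lpf-fd") param else ratio * param
      keep <- if (is.finite(phi_f)) fw$fd[[i]] <= phi_f
              else rep(TRUE, length(fw$fd[[i]]))
    }
    if (method %in% c("gev-dv", "combined-ratio")) {
      d_g <- param
      thr <- if (is.finite(d_g)) {
        suppressWarnings(gev_dv_threshold(fw$gev[[i]], d_g, fw$dv[[i]]))
      } else Inf
      kd <- fw$dv[[i]] <= thr
      keep <- if (is.null(keep)) kd else keep & kd
    }
    masks[[i]] <- keep
  }
  masks
}

realized_percent <- function(masks) {
  100 * sum(!unlist(masks)) / length(unlist(masks))
}

# invert the parameter -> percent-removed map for a percent target.
# lpf-fd uses the pooled-FD quantile directly; gev-dv and combined-ratio
# solve the (monotone, stepwise) percent(parameter) relation by uniroot on a
# log parameter scale.
solve_param <- function(fw, method, target, ratio = NULL) {
  if (target <= 0) return(Inf)
  if (method == "lpf-fd") {
    pool <- unlist(fw$fd)
    return(unname(quantile(pool, max(0, 1 - target / 100))))
  }
  f <- function(lp) realized_percent(method_masks(fw, method, exp(lp), ratio)) - target
  lo <- log(1e-4); hi <- log(1e6)
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0) return(exp(lo))   # even the harshest parameter undershoots
  if (fhi > 0) return(exp(hi))
  exp(uniroot(f, c(lo, hi), tol = 1e-6)$root)
}

# ---- sweep ------------------------------------------------------------------

#' Censoring-parameter sweep with random-censoring baselines
#'
#' Sweeps a censoring method over thresholds chosen so that the realized
#' percentage of volumes removed across the dataset tracks `targets`
#' (pooled-statistic quantile inversion). At every grid point the full
#' censor plan (167-volume run exclusion) is built and, for each retained
#' subject, the targeted and `n_rand` count-matched random-censoring
#' pipelines are run. Per pair the sweep records `delta_bias` (Eq. 7, the
#' negated absolute across-subject mean of delta z), the across-subject
#' variance of targeted Fisher-z, and the retained subject count; curves are
#' re-parameterized by realized percent removed and linearly resampled to a
#' 0.01% grid (retained-subject counts use piecewise-constant resampling).
#' Grid points where fewer than 2 subjects survive are dropped from the
#' resampled curves, which therefore end at the last usable percent.
#'
#' @param dataset an `"mb_dataset"`.
#' @param method `"lpf-fd"` (threshold `phi_F` on LPF-FD), `"gev-dv"`
#'   (dataset parameter `d_G` with per-run GEV-fit thresholds on LPF-DV), or
#'   `"combined-ratio"` (`phi_F = ratio * d_G` union censoring; `ratio` in mm).
#' @param targets percent-removed targets; 0 is always included (default
#'   0--100% in 0.5% steps; pass a coarser grid for large datasets).
#' @param ratio `phi_F / d_G` for `"combined-ratio"`.
#' @param n_rand,seed random-baseline count and master seed (see [delta_z()]).
#' @param gsr,band,trim RSFC pipeline options.
#' @param min_vol minimum surviving frames per run.
#' @param fd_variant,dv_variant framewise statistic variants (default LPF).
#' @return object of class `"sweep_result"`; see Details in the vignette.
#' @export
sweep_censoring <- function(dataset,
                            method = c("lpf-fd", "gev-dv", "combined-ratio"),
                            targets = seq(0, 100, by = 0.5), ratio = NULL,
                            n_rand = 10, seed = 1, gsr = FALSE,
                            band = filter_spec("bandpass", c(0.009, 0.08)),
                            trim = 30, min_vol = 167,
                            fd_variant = "lpf", dv_variant = "lpf") {
  method <- match.arg(method)
  if (method == "combined-ratio" && (is.null(ratio) || ratio <= 0))
    stop("combined-ratio requires a positive ratio (phi_F / d_G, mm)")
  dataset <- normalize_dataset(dataset)
  targets <- sort(unique(c(0, targets)))
  fw <- sweep_framewise(dataset, method, fd_variant, dv_variant)
  caches <- dataset_caches(dataset, gsr, band)
  subjects <- vapply(dataset$runs, `[[`, character(1), "subject")
  runs <- vapply(dataset$runs, `[[`, character(1), "run")
  n_pair <- length(run_z_masks(caches[[1]],
                               list(rep(TRUE, nrow(caches[[1]]$base))),
                               band, trim)[[1]])
  G <- length(targets)
  param <- percent <- n_s <- rep(NA_real_, G)
  db <- vc <- matrix(NA_real_, n_pair, G)
  z_u <- NULL; n_su <- NA_integer_
  for (g in seq_len(G)) {
    param[g] <- solve_param(fw, method, targets[g], ratio)
    masks <- method_masks(fw, method, param[g], ratio)
    plan <- apply_exclusion(masks, subjects, runs, min_vol)
    percent[g] <- plan$percent_removed
    n_s[g] <- plan$n_retained
    if (plan$n_retained < 2) next
    dzt <- delta_z_impl(caches, plan, n_rand, seed, band, trim)
    db[, g] <- -abs(colMeans(dzt$delta_z))
    vc[, g] <- col_vars(dzt$z)
    if (targets[g] == 0) { z_u <- dzt$z; n_su <- plan$n_retained }
  }
  if (is.null(z_u)) stop("uncensored (0%) grid point failed")
  ok <- which(n_s >= 2 & is.finite(percent))
  ord <- ok[order(percent[ok])]
  pmax_ok <- max(percent[ord])
  pgrid <- seq(0, floor(pmax_ok * 100) / 100, by = 0.01)
  lin <- function(y) approx(percent[ord], y[ord], xout = pgrid,
                            ties = mean, rule = 2)$y
  rs_db <- t(apply(db, 1, lin))
  rs_vc <- t(apply(vc, 1, lin))
  rs_ns <- approx(percent[ord], n_s[ord], xout = pgrid, method = "constant",
                  f = 0, ties = "ordered", rule = 2)$y
  structure(list(method = method, ratio = ratio, targets = targets,
                 param = param, percent = percent, n_s = n_s,
                 delta_bias = db, var_c = vc,
                 var_u = col_vars(z_u), n_su = n_su,
                 pgrid = pgrid, rs_delta_bias = rs_db, rs_var = rs_vc,
                 rs_n_s = rs_ns, n_pair = n_pair,
                 n_gev_fallback = if (is.null(fw$gev)) 0L else
                   sum(!vapply(fw$gev, `[[`, logical(1), "converged")),
                 n_rand = n_rand, seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(paste0("%s sweep: %d grid points, realized removal ",
                     "%.2f-%.2f%%, %d pairs, N_SU = %d\n"),
              x$method, length(x$targets), min(x$percent, na.rm = TRUE),
              max(x$percent, na.rm = TRUE), x$n_pair, x$n_su))
  invisible(x)
}

# ---- uncensored-bias extrapolation ------------------------------------------

# IRLS slope-through-origin with Tukey bisquare weights; returns slope and a
# convergence flag. scale = MAD of residuals about 0 (consistent for normal).
irls_origin_slope <- function(x, y, c = 4.685, max_iter = 50, tol = 1e-8) {
  if (all(y == 0)) return(list(slope = 0, converged = TRUE))
  sxx <- sum(x^2)
  if (sxx == 0) return(list(slope = 0, converged = TRUE))
  b <- sum(x * y) / sxx            # OLS start
  b_ols <- b
  for (it in seq_len(max_iter)) {
    r <- y - b * x
    s <- median(abs(r - median(r))) / 0.6745
    if (s == 0) return(list(slope = b, converged = TRUE))
    u <- r / (c * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    sw <- sum(w * x^2)
    if (sw == 0) return(list(slope = b_ols, converged = FALSE))
    b_new <- sum(w * x * y) / sw
    if (abs(b_new - b) <= tol * max(1, abs(b_new)))
      return(list(slope = b_new, converged = TRUE))
    b <- b_new
  }
  list(slope = b_ols, converged = FALSE)
}

#' Extrapolate the uncensored bias per ROI pair
#'
#' Fits, per pair, the resampled `-delta_bias` curve against percent removed
#' by a zero-intercept robust regression (IRLS with bisquare weights, tuning
#' constant 4.685, OLS start, tolerance 1e-8, at most 50 iterations;
#' non-convergence falls back to the OLS slope with a flag). The estimated
#' magnitude of bias remaining in uncensored data is the slope extrapolated
#' to 100% frames removed: `bias_u = slope * 100`.
#'
#' @param sweep a [sweep_censoring()] result.
#' @param c bisquare tuning constant.
#' @return object of class `"bias_estimate"`: `bias_u` and `slope` per pair,
#'   `converged` flags, `n_fallback`, plus the sweep fingerprint used by
#'   [delta_mse()] to verify grid compatibility.
#' @export
estimate_uncensored_bias <- function(sweep, c = 4.685) {
  stopifnot(inherits(sweep, "sweep_result"))
  x <- sweep$pgrid
  fits <- apply(sweep$rs_delta_bias, 1, function(dbk)
    irls_origin_slope(x, -dbk, c = c))
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  structure(list(bias_u = slope * 100, slope = slope, converged = conv,
                 n_fallback = sum(!conv), n_points = length(x),
                 n_pair = sweep$n_pair, method = sweep$method),
            class = "bias_estimate")
}

# ---- delta-MSE --------------------------------------------------------------

#' Change in mean squared error from censoring (Eqs. 3-12)
#'
#' Per pair k and resampled percent point: the censored squared bias is
#' `bias_c2 = bias_u^2 + [(bias_u + delta_bias)^2 - bias_u^2]`, i.e.
#' `(bias_u + delta_bias)^2`; the per-pair MSE change is
#' `(var_c + bias_c2) / N_S - (var_u + bias_u^2) / N_SU`; the curve is the
#' mean over pairs. The change-in-squared-bias bracket is negative whenever
#' censoring shrinks |bias| (i.e. `|delta_bias| < 2 * bias_u`); cells where
#' the extrapolated bias is overshot (`bias_u + delta_bias < 0`) are counted
#' in `n_overshoot` and propagated as computed, never clamped.
#'
#' @param sweep a [sweep_censoring()] result.
#' @param bias the matching [estimate_uncensored_bias()].
#' @return object of class `"mse_curve"`: data.frame with `percent` and
#'   `delta_mse`, plus attributes `param_map` (percent to parameter),
#'   `n_overshoot`, `n_negative_dbias_sq`, `method`.
#' @export
delta_mse <- function(sweep, bias) {
  stopifnot(inherits(sweep, "sweep_result"), inherits(bias, "bias_estimate"))
  if (bias$n_points != length(sweep$pgrid) || bias$n_pair != sweep$n_pair ||
      length(bias$bias_u) != sweep$n_pair)
    stop("mismatched grids between sweep and bias estimate")
  bu <- bias$bias_u
  bc <- (bu + sweep$rs_delta_bias)^2          # pairs x points
  dmse <- (sweep$rs_var + bc) / rep(sweep$rs_n_s, each = sweep$n_pair) -
    (sweep$var_u + bu^2) / sweep$n_su
  curve <- data.frame(percent = sweep$pgrid, delta_mse = colMeans(dmse))
  ok <- which(is.finite(sweep$percent) & sweep$n_s >= 2)
  pm <- data.frame(percent = sweep$percent[ok], param = sweep$param[ok])
  structure(curve,
            param_map = pm[order(pm$percent), ],
            n_overshoot = sum(bu + sweep$rs_delta_bias < 0),
            n_negative_dbias_sq = sum(bc - bu^2 < 0),
            method = sweep$method,
            class = c("mse_curve", "data.frame"))
}

# ---- optimizers -------------------------------------------------------------

#' Minimize a delta-MSE curve over a percent-removed range
#'
#' Returns the global minimum of the curve within `search_range` (default
#' 0--80% removed, excluding the unstable extreme-censoring region). The
#' corresponding
#' censoring parameter is recovered by inverse linear interpolation of the
#' percent-to-parameter map when the curve carries one. If the curve ends
#' before the upper bound (run exclusion leaves too few subjects at harsher
#' censoring), the search covers the available portion.
#'
#' @param curve an [delta_mse()] `"mse_curve"` or any data.frame with
#'   `percent` and `delta_mse` columns.
#' @param search_range length-2 percent-removed bounds.
#' @return object of class `"optim_result"`: `parameter`, `percent_removed`,
#'   `delta_mse`, `search_range`, `method`, and the curve.
#' @export
optimize_single <- function(curve, search_range = c(0, 80)) {
  stopifnot(is.data.frame(curve), all(c("percent", "delta_mse") %in% names(curve)),
            length(search_range) == 2, search_range[1] < search_range[2])
  sel <- which(curve$percent >= search_range[1] &
                 curve$percent <= search_range[2])
  if (!length(sel)) stop("no curve points inside the search range")
  bad <- sel[!is.finite(curve$delta_mse[sel])]
  if (length(bad))
    stop("non-finite delta-MSE inside the search range at percent removed: ",
         paste(utils::head(round(curve$percent[bad], 2), 5), collapse = ", "))
  i <- sel[which.min(curve$delta_mse[sel])]
  pm <- attr(curve, "param_map")
  par <- if (!is.null(pm) && nrow(pm) >= 2) {
    # interpolate on 1/parameter: thresholds are positive and the
    # no-censoring knot has parameter Inf, where linear interpolation on the
    # raw scale would produce NaN (Inf - Inf); 1/Inf = 0 interpolates cleanly
    recip <- approx(pm$percent, 1 / pm$param, xout = curve$percent[i],
                    ties = mean, rule = 2)$y
    if (is.finite(recip) && recip >= 0) {
      if (recip == 0) Inf else 1 / recip
    } else {
      pm$param[which.min(abs(pm$percent - curve$percent[i]))]
    }
  } else NA_real_
  structure(list(parameter = par, percent_removed = curve$percent[i],
                 delta_mse = curve$delta_mse[i], search_range = search_range,
                 method = attr(curve, "method"), curve = curve),
            class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat(sprintf("optimum: %.2f%% removed, delta-MSE-RSFC = %.6g",
              x$percent_removed, x$delta_mse))
  if (length(x$parameter) == 1 && !is.na(x$parameter))
    cat(sprintf(", parameter = %.6g", x$parameter))
  else if (length(x$parameter) == 2)
    cat(sprintf(", phi_F = %.6g, d_G = %.6g", x$parameter[1], x$parameter[2]))
  if (!is.null(x$method)) cat(sprintf(" [%s]", x$method))
  cat("\n")
  invisible(x)
}

#' End-to-end censoring optimization for one method
#'
#' Convenience driver: [sweep_censoring()], [estimate_uncensored_bias()],
#' [delta_mse()], [optimize_single()].
#'
#' @inheritParams sweep_censoring
#' @param search_range percent-removed bounds for the optimizer.
#' @param ... passed to [sweep_censoring()].
#' @return an `"optim_result"` with the sweep and bias attached
#'   (`$sweep`, `$bias`).
#' @export
optimize_censoring <- function(dataset, method = c("lpf-fd", "gev-dv",
                                                   "combined-ratio"),
                               targets = seq(0, 100, by = 0.5), ratio = NULL,
                               search_range = c(0, 80), ...) {
  method <- match.arg(method)
  sw <- sweep_censoring(dataset, method, targets = targets, ratio = ratio, ...)
  be <- estimate_uncensored_bias(sw)
  cv <- delta_mse(sw, be)
  out <- optimize_single(cv, search_range)
  out$sweep <- sw
  out$bias <- be
  out
}

#' Fixed-ratio combined LPF-FD + GEV-DV optimization
#'
#' One-dimensional sweep in which `phi_F` and `d_G` move together with
#' `phi_F / d_G` fixed at `ratio` (union censoring), then minimized over the
#' search range. Reference ratios: 0.02438 mm without GSR, 11.0277 mm with
#' GSR.
#'
#' @inheritParams optimize_censoring
#' @param ratio `phi_F / d_G` in mm (must be positive).
#' @return an `"optim_result"`; `parameter` is `d_G` at the optimum
#'   (`phi_F = ratio * d_G`), also exposed as `$phi_f` and `$d_g`.
#' @export
optimize_combined_fixed_ratio <- function(dataset, ratio,
                                          targets = seq(0, 100, by = 0.5),
                                          search_range = c(0, 80), ...) {
  out <- optimize_censoring(dataset, "combined-ratio", targets = targets,
                            ratio = ratio, search_range = search_range, ...)
  out$d_g <- out$parameter
  out$phi_f <- ratio * out$parameter
  out$ratio <- ratio
  out
}

#' Two-dimensional grid optimization over (phi_F, d_G)
#'
#' Exhaustive evaluation of the delta-MSE objective over a coarse
#' `phi_grid x dg_grid` of combined (union) censoring plans, restricted to
#' cells with percent removed inside `search_range` and at least 2 retained
#' subjects. The uncensored-bias term is shared across cells; it is
#' estimated once from a fixed-ratio 1D sweep at the grid-median ratio
#' unless a `bias` estimate is supplied. Cost grows with the product of the
#' grids; a message reports the cell count.
#'
#' @param dataset an `"mb_dataset"`.
#' @param phi_grid,dg_grid candidate `phi_F` (mm) and `d_G` values.
#' @param bias optional [estimate_uncensored_bias()] result to reuse.
#' @param bias_targets percent targets of the internal bias sweep.
#' @param search_range percent-removed bounds.
#' @inheritParams sweep_censoring
#' @return an `"optim_result"` with `phi_f`, `d_g`, and the evaluated `cells`
#'   data.frame.
#' @export
optimize_2d_grid <- function(dataset, phi_grid, dg_grid, bias = NULL,
                             bias_targets = seq(0, 60, by = 10),
                             search_range = c(0, 80), n_rand = 10, seed = 1,
                             gsr = FALSE,
                             band = filter_spec("bandpass", c(0.009, 0.08)),
                             trim = 30, min_vol = 167,
                             fd_variant = "lpf", dv_variant = "lpf") {
  dataset <- normalize_dataset(dataset)
  message(length(phi_grid) * length(dg_grid),
          " grid cells to evaluate; this recomputes the full pipeline per cell")
  if (is.null(bias)) {
    ratio0 <- median(phi_grid) / median(dg_grid)
    sw0 <- sweep_censoring(dataset, "combined-ratio", targets = bias_targets,
                           ratio = ratio0, n_rand = n_rand, seed = seed,
                           gsr = gsr, band = band, trim = trim,
                           min_vol = min_vol, fd_variant = fd_variant,
                           dv_variant = dv_variant)
    bias <- estimate_uncensored_bias(sw0)
  }
  bu <- bias$bias_u
  fw <- sweep_framewise(dataset, "combined-ratio", fd_variant, dv_variant)
  caches <- dataset_caches(dataset, gsr, band)
  subjects <- vapply(dataset$runs, `[[`, character(1), "subject")
  runs <- vapply(dataset$runs, `[[`, character(1), "run")
  # uncensored reference
  plan0 <- apply_exclusion(method_masks(fw, "combined-ratio", Inf, 1),
                           subjects, runs, min_vol)
  dz0 <- delta_z_impl(caches, plan0, n_rand, seed, band, trim)
  var_u <- col_vars(dz0$z); n_su <- plan0$n_retained
  ref <- mean((var_u + bu^2)) / n_su
  cells <- expand.grid(phi_f = phi_grid, d_g = dg_grid)
  cells$percent <- NA_real_; cells$n_s <- NA_integer_
  cells$delta_mse <- NA_real_
  for (ci in seq_len(nrow(cells))) {
    masks <- lapply(seq_along(caches), function(i) {
      kf <- fw$fd[[i]] <= cells$phi_f[ci]
      thr <- suppressWarnings(
        gev_dv_threshold(fw$gev[[i]], cells$d_g[ci], fw$dv[[i]]))
      kf & (fw$dv[[i]] <= thr)
    })
    plan <- apply_exclusion(masks, subjects, runs, min_vol)
    cells$percent[ci] <- plan$percent_removed
    cells$n_s[ci] <- plan$n_retained
    if (plan$n_retained < 2 || plan$percent_removed > search_range[2] ||
        plan$percent_removed < search_range[1]) next
    dzt <- delta_z_impl(caches, plan, n_rand, seed, band, trim)
    dbias <- -abs(colMeans(dzt$delta_z))
    cells$delta_mse[ci] <-
      mean((col_vars(dzt$z) + (bu + dbias)^2) / plan$n_retained) - ref
  }
  ok <- which(is.finite(cells$delta_mse))
  if (!length(ok)) stop("no grid cell is inside the search range with >= 2 subjects")
  i <- ok[which.min(cells$delta_mse[ok])]
  structure(list(parameter = c(phi_f = cells$phi_f[i], d_g = cells$d_g[i]),
                 phi_f = cells$phi_f[i], d_g = cells$d_g[i],
                 percent_removed = cells$percent[i],
                 delta_mse = cells$delta_mse[i],
                 search_range = search_range, method = "2d-grid",
                 cells = cells, bias = bias),
            class = "optim_result")
}
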