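# MAC-RSFC: mean absolute change in RSFC produced by targeted censoring
# relative to count-matched random censoring (Eqs. 1-2), with BCa bootstrap
# confidence intervals over subjects.

# internal: per-run caches for a whole dataset (mask-independent pieces)
dataset_caches <- function(dataset, gsr, band) {
  lapply(dataset$runs, run_cache, band = band, gsr = gsr)
}

# internal: delta-z + targeted-z over a dataset given precomputed caches.
# For every retained subject and included run, the targeted mask and n_rand
# count-matched random masks go through the identical pipeline in one batched
# filter call; dz_run = z_targeted - mean(z_random).
delta_z_impl <- function(caches, plan, n_rand, seed, band, trim) {
  subj_ids <- vapply(caches, `[[`, character(1), "subject")
  subjects <- unique(subj_ids)
  dz <- list(); zt <- list(); n_runs <- integer(0)
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    ridx <- which(subj_ids == s & plan$runs$included)
    if (!length(ridx)) next
    run_dz <- vector("list", length(ridx))
    run_zt <- vector("list", length(ridx))
    for (j in seq_along(ridx)) {
      i <- ridx[j]
      keep <- plan$keep[[i]]
      keeps <- c(list(keep),
                 lapply(seq_len(n_rand), function(p)
                   random_mask_like(keep, derive_seed(seed, si, i, p))))
      zs <- run_z_masks(caches[[i]], keeps, band, trim)
      run_zt[[j]] <- zs[[1]]
      # average the per-permutation differences (not the difference of
      # averages) so that identical targeted/random masks give exactly 0
      run_dz[[j]] <- Reduce(`+`, lapply(zs[-1], function(zr) zs[[1]] - zr)) /
        n_rand
    }
    dz[[s]] <- colMeans(do.call(rbind, run_dz))
    zt[[s]] <- colMeans(do.call(rbind, run_zt))
    n_runs[s] <- length(ridx)
  }
  if (!length(dz)) stop("no subject has any included run")
  list(delta_z = do.call(rbind, dz), z = do.call(rbind, zt), n_runs = n_runs)
}

#' Targeted-vs-random censoring change in RSFC (Eq. 1)
#'
#' For every retained subject i and ROI pair k, `delta_z[i, k]` is the mean
#' over the subject's included runs of the targeted-censoring Fisher-z minus
#' the average Fisher-z over `n_rand` random censoring vectors that remove
#' the same number of frames from the same run. Random masks are drawn from
#' seeds derived deterministically from (seed, subject, run, permutation), so
#' results are reproducible. Runs excluded by the targeted plan are excluded
#' from the random arm too; random-censored pipelines re-run interpolation,
#' filtering and trimming identically to the targeted pipeline.
#'
#' @param dataset an `"mb_dataset"`.
#' @param plan a [apply_exclusion()] censor plan for the targeted method.
#' @param n_rand random censoring vectors per run (default 10).
#' @param seed master seed for the random masks.
#' @param gsr,band,trim passed to the RSFC pipeline.
#' @return object of class `"delta_z_table"`: list with `delta_z` (retained
#'   subjects x pairs), `z` (targeted subject-level Fisher-z), `n_rand`,
#'   `n_runs` per subject, `seed`.
#' @export
delta_z <- function(dataset, plan, n_rand = 10, seed = 1, gsr = FALSE,
                    band = filter_spec("bandpass", c(0.009, 0.08)),
                    trim = 30) {
  dataset <- normalize_dataset(dataset)
  caches <- dataset_caches(dataset, gsr, band)
  out <- delta_z_impl(caches, plan, n_rand, seed, band, trim)
  structure(c(out, list(n_rand = n_rand, seed = seed)),
            class = "delta_z_table")
}

#' MAC-RSFC point estimate and BCa confidence interval (Eq. 2)
#'
#' MAC-RSFC is the mean over subjects and ROI pairs of `|delta_z[i, k]|`.
#' The confidence interval resamples subjects with replacement (each
#' subject's contribution is the mean |delta z| over pairs) and applies the
#' bias-corrected and accelerated bootstrap.
#'
#' @param table a [delta_z()] table.
#' @param boot bootstrap resamples (default 10000); 0 skips the interval.
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return object of class `"mac_result"`: `mac`, `ci_low`, `ci_high`, `B`,
#'   `n_subjects`, `degenerate` flag.
#' @export
mac_rsfc <- function(table, boot = 10000, level = 0.95, seed = 1) {
  stopifnot(inherits(table, "delta_z_table"))
  contrib <- rowMeans(abs(table$delta_z))
  mac <- mean(contrib)
  lo <- hi <- NA_real_; degen <- FALSE
  if (boot > 0) {
    ci <- bca_ci(contrib, B = boot, level = level, seed = seed)
    lo <- ci[1]; hi <- ci[2]
    degen <- isTRUE(attr(ci, "degenerate"))
  }
  structure(list(mac = mac, ci_low = lo, ci_high = hi, B = boot,
                 n_subjects = length(contrib), degenerate = degen),
            class = "mac_result")
}

#' @export
print.mac_result <- function(x, ...) {
  cat(sprintf("MAC-RSFC = %.6g", x$mac))
  if (!is.na(x$ci_low))
    cat(sprintf("  [%.6g, %.6g] (BCa, B = %d)", x$ci_low, x$ci_high, x$B))
  cat(sprintf("  n = %d subjects\n", x$n_subjects))
  invisible(x)
}

#' Bias-corrected and accelerated bootstrap interval
#'
#' Hand-rolled BCa over per-subject statistic contributions: resample with
#' replacement, bias correction from the fraction of bootstrap statistics
#' below the point estimate, acceleration from the jackknife. Deterministic
#' given `seed`; the caller's RNG state is preserved. A degenerate
#' (all-equal) input collapses the interval to the point estimate with
#' attribute `"degenerate" = TRUE`.
#'
#' @param x numeric per-subject contributions (length >= 8).
#' @param B bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @param statistic statistic to bootstrap (default [mean()]).
#' @return length-2 numeric `(lo, hi)`.
#' @export
bca_ci <- function(x, B = 10000, level = 0.95, seed = 1, statistic = mean) {
  n <- length(x)
  if (n < 8) stop("BCa interval needs at least 8 subjects; got ", n)
  theta <- statistic(x)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  thetas <- if (identical(statistic, mean)) {
    rowMeans(matrix(x[idx], nrow = B))
  } else {
    apply(idx, 1, function(i) statistic(x[i]))
  }
  if (diff(range(thetas)) == 0 && thetas[1] == theta)
    return(structure(c(theta, theta), degenerate = TRUE))
  prop <- mean(thetas < theta)
  prop <- min(max(prop, 1 / B), 1 - 1 / B)
  z0 <- qnorm(prop)
  tj <- vapply(seq_len(n), function(i) statistic(x[-i]), numeric(1))
  dj <- mean(tj) - tj
  denom <- sum(dj^2)^1.5
  a <- if (denom == 0) 0 else sum(dj^3) / (6 * denom)
  zq <- qnorm(c((1 - level) / 2, (1 + level) / 2))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  structure(quantile(thetas, adj, names = FALSE, type = 7),
            degenerate = FALSE)
}
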