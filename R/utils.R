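#' Upper-triangle ROI pair index table
#'
#' Enumerates the `n * (n - 1) / 2` unordered ROI pairs in the column order
#' produced by `upper.tri()`, the order used for every pair-vector in the
#' package (Fisher-z vectors, QC-FC vectors, pair distances).
#'
#' @param n_roi number of ROIs.
#' @return data.frame with integer columns `i`, `j` (`i < j`).
#' @export
roi_pairs <- function(n_roi) {
  stopifnot(n_roi >= 2)
  idx <- which(upper.tri(diag(n_roi)), arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2])
}

#' Euclidean distances between ROI pair centers
#'
#' @param centers numeric matrix, `n_roi x 3`, world coordinates in mm.
#' @return numeric vector of pair distances (mm) in [roi_pairs()] order.
#' @export
pair_distances <- function(centers) {
  centers <- as.matrix(centers)
  p <- roi_pairs(nrow(centers))
  sqrt(rowSums((centers[p$i, , drop = FALSE] - centers[p$j, , drop = FALSE])^2))
}

# Fisher r-to-z with clamping just inside (-1, 1)
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

# Deterministic per-(subject, run, permutation) seed stream derived from one
# master seed. Kept below .Machine$integer.max so set.seed() accepts it.
derive_seed <- function(master, subject = 0L, run = 0L, p = 0L) {
  as.integer((abs(master) %% 1e6) * 1009 + subject * 7919 + run * 101 + p) %%
    .Machine$integer.max
}

# column variances (denominator n - 1)
col_vars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(NA_real_, ncol(x)))
  mu <- colMeans(x)
  (colSums(x^2) - n * mu^2) / (n - 1)
}

#' Truth-referenced mean squared error of group-mean RSFC
#'
#' For simulation studies where the true Fisher-z connectivity is known:
#' the estimated MSE of the sample-mean estimator per pair,
#' `(mean(z) - truth)^2 + var(z) / n`, averaged over pairs.
#'
#' @param z subjects x pairs Fisher-z matrix.
#' @param truth length-`n_pair` true Fisher-z vector.
#' @return scalar mean over pairs.
#' @export
truth_referenced_mse <- function(z, truth) {
  z <- as.matrix(z)
  stopifnot(ncol(z) == length(truth), nrow(z) >= 2)
  mean((colMeans(z) - truth)^2 + col_vars(z) / nrow(z))
}
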