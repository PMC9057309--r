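# Traditional dataset-quality metrics (DQMs): the QC-FC family, high-low
# tercile differences, two-step GLM metrics, and between-subject variance
# change. Provided for comparison and for reproducing the third-variable
# confound demonstration on synthetic cohorts -- not endorsed as optimization
# targets.

as_z_matrix <- function(rsfc) {
  if (inherits(rsfc, "rsfc_result")) rsfc$z else as.matrix(rsfc)
}

# align a subject quality measure to the rows of z
align_sqm <- function(z, sqm, which) {
  if (is.data.frame(sqm)) {
    stopifnot("subject" %in% names(sqm), which %in% names(sqm))
    idx <- match(rownames(z), sqm$subject)
    if (anyNA(idx))
      stop("subjects missing from SQM table: ",
           paste(rownames(z)[is.na(idx)], collapse = ", "))
    sqm[[which]][idx]
  } else {
    stopifnot(length(sqm) == nrow(z))
    as.numeric(sqm)
  }
}

#' QC-FC correlations
#'
#' Per ROI pair, the Pearson correlation across subjects between the
#' subject-level Fisher-z connectivity and a subject quality measure (SQM):
#' mean FD by default, median FD by flag.
#'
#' @param rsfc an `"rsfc_result"` or subjects x pairs Fisher-z matrix.
#' @param sqm a [subject_fd_summary()] data.frame (matched by subject id) or
#'   numeric vector parallel to the rows of the z matrix.
#' @param which SQM column to use when `sqm` is a data.frame.
#' @return object of class `"qcfc"`: list with `values` (per-pair
#'   correlations), `n` (subjects), `which`.
#' @export
qcfc <- function(rsfc, sqm, which = c("mean_fd", "median_fd")) {
  which <- match.arg(which)
  z <- as_z_matrix(rsfc)
  if (nrow(z) < 3) stop("QC-FC needs at least 3 subjects")
  q <- align_sqm(z, sqm, which)
  if (var(q) == 0) stop("zero-variance SQM: QC-FC undefined")
  qc <- q - mean(q)
  zc <- sweep(z, 2, colMeans(z))
  sz <- sqrt(colSums(zc^2))
  r <- as.numeric(crossprod(qc, zc)) / (sqrt(sum(qc^2)) * pmax(sz, 1e-300))
  r[sz == 0] <- 0
  structure(list(values = r, n = nrow(z), which = which), class = "qcfc")
}

# two-sided p-value of a Pearson correlation on n subjects
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(-tt, df = n - 2)
  p[abs(r) >= 1] <- 0
  p
}

#' QC-FC summary metrics
#'
#' Median absolute QC-FC; fraction of pairs whose QC-FC correlation is
#' significant after Benjamini--Hochberg false-discovery-rate adjustment
#' (null rejection rate); Spearman rank correlation between QC-FC and ROI
#' pair distance (distance-dependence).
#'
#' @param qcfc a [qcfc()] object.
#' @param pair_distances Euclidean distances between ROI sphere centers, mm,
#'   in pair order.
#' @param alpha FDR significance level (default 0.05).
#' @return list with `median_abs`, `null_rejection_rate`, `distance_corr`
#'   (0 with attribute `"undefined" = TRUE` if QC-FC has no variation).
#' @export
qcfc_summaries <- function(qcfc, pair_distances, alpha = 0.05) {
  stopifnot(inherits(qcfc, "qcfc"),
            length(pair_distances) == length(qcfc$values))
  r <- qcfc$values
  p_adj <- p.adjust(cor_pvalue(r, qcfc$n), method = "BH")
  if (length(unique(r)) == 1 || length(unique(pair_distances)) == 1) {
    dc <- structure(0, undefined = TRUE)
  } else {
    dc <- cor(r, pair_distances, method = "spearman")
  }
  list(median_abs = median(abs(r)),
       null_rejection_rate = mean(p_adj < alpha),
       distance_corr = dc)
}

#' High-low null rejection rate
#'
#' Subjects are split into terciles of median FD; per ROI pair, a two-sample
#' Welch t-test compares Fisher-z between the upper and lower terciles. The
#' rejection rate (fraction of pairs with uncorrected p below alpha) is
#' reported over a grid of significance thresholds (default 0.0001 to 0.1 in
#' steps of 1e-5).
#'
#' @param rsfc an `"rsfc_result"` or z matrix.
#' @param sqm SQM table or vector; median FD is used by convention.
#' @param alpha numeric grid of significance levels.
#' @param which SQM column when `sqm` is a data.frame.
#' @return data.frame with `alpha` and `rate`.
#' @export
highlow_rejection <- function(rsfc, sqm, alpha = seq(1e-4, 0.1, by = 1e-5),
                              which = "median_fd") {
  z <- as_z_matrix(rsfc)
  if (nrow(z) < 6) stop("high-low test needs at least 6 subjects")
  q <- align_sqm(z, sqm, which)
  n3 <- floor(nrow(z) / 3)
  if (n3 < 2) stop("tercile size ", n3, " < 2")
  ord <- order(q)
  lo <- z[ord[seq_len(n3)], , drop = FALSE]
  hi <- z[ord[(nrow(z) - n3 + 1):nrow(z)], , drop = FALSE]
  m1 <- colMeans(hi); m2 <- colMeans(lo)
  v1 <- col_vars(hi); v2 <- col_vars(lo)
  se2 <- v1 / nrow(hi) + v2 / nrow(lo)
  df <- se2^2 / (v1^2 / (nrow(hi)^2 * (nrow(hi) - 1)) +
                   v2^2 / (nrow(lo)^2 * (nrow(lo) - 1)))
  tt <- (m1 - m2) / sqrt(se2)
  p <- ifelse(se2 == 0, ifelse(m1 == m2, 1, 0), 2 * pt(-abs(tt), df = df))
  data.frame(alpha = alpha,
             rate = vapply(alpha, function(a) mean(p < a), numeric(1)))
}

#' Two-step GLM metrics
#'
#' Step 1: per ROI pair, OLS regression of Fisher-z on the *centered* SQM;
#' the intercept is the pair's mean RSFC and the slope its QC-FC effect (z
#' per mm of SQM). Step 2: OLS of the step-1 intercepts on pair distance
#' (`mean_rsfc` = intercept, `rsfc_distance_slope` = slope) and of the step-1
#' slopes on distance (`mean_qcfc` = intercept, `qcfc_distance_slope` =
#' slope).
#'
#' @inheritParams qcfc
#' @param pair_distances pair distances, mm.
#' @return list with `mean_qcfc`, `qcfc_distance_slope`, `mean_rsfc`,
#'   `rsfc_distance_slope`.
#' @export
glm_metrics <- function(rsfc, sqm, pair_distances,
                        which = c("mean_fd", "median_fd")) {
  which <- match.arg(which)
  z <- as_z_matrix(rsfc)
  if (nrow(z) < 3) stop("GLM metrics need at least 3 subjects")
  q <- align_sqm(z, sqm, which)
  if (var(q) == 0) stop("zero-variance SQM")
  qc <- q - mean(q)
  slope1 <- as.numeric(crossprod(qc, sweep(z, 2, colMeans(z)))) / sum(qc^2)
  icpt1 <- colMeans(z)
  d <- as.numeric(pair_distances)
  stopifnot(length(d) == ncol(z))
  step2 <- function(y) {
    b <- if (var(d) == 0) 0 else cov(d, y) / var(d)
    c(a = mean(y) - b * mean(d), b = b)
  }
  fr <- step2(icpt1); fq <- step2(slope1)
  list(mean_qcfc = unname(fq["a"]), qcfc_distance_slope = unname(fq["b"]),
       mean_rsfc = unname(fr["a"]), rsfc_distance_slope = unname(fr["b"]))
}

#' Change in between-subject variance due to censoring
#'
#' Mean over ROI pairs of the across-subject variance of Fisher-z after
#' censoring minus before. Subjects dropped by censoring are excluded from
#' both conditions (matched by subject id when available).
#'
#' @param censored,uncensored `"rsfc_result"`s or z matrices.
#' @return scalar variance change (z-squared units).
#' @export
variance_change <- function(censored, uncensored) {
  zc <- as_z_matrix(censored)
  zu <- as_z_matrix(uncensored)
  if (!is.null(rownames(zc)) && !is.null(rownames(zu))) {
    common <- intersect(rownames(zc), rownames(zu))
    if (length(common) < 2) stop("fewer than 2 common subjects")
    zc <- zc[common, , drop = FALSE]
    zu <- zu[common, , drop = FALSE]
  }
  stopifnot(identical(dim(zc), dim(zu)))
  mean(col_vars(zc) - col_vars(zu))
}

#' Assemble the full DQM report
#'
#' Runs [qcfc()], [qcfc_summaries()], [highlow_rejection()] and
#' [glm_metrics()] on one RSFC matrix and (optionally) [variance_change()]
#' against an uncensored counterpart.
#'
#' @param rsfc `"rsfc_result"` or z matrix (censored condition).
#' @param sqm subject FD summary (data.frame from [subject_fd_summary()]).
#' @param pair_distances pair distances, mm.
#' @param uncensored optional uncensored RSFC for `variance_change`.
#' @param alpha FDR level; `alpha_grid` grid for the high-low rate.
#' @return list mirroring the DQM report fields.
#' @export
dqm_report <- function(rsfc, sqm, pair_distances, uncensored = NULL,
                       alpha = 0.05, alpha_grid = seq(1e-4, 0.1, by = 1e-3)) {
  qc <- qcfc(rsfc, sqm, "mean_fd")
  qs <- qcfc_summaries(qc, pair_distances, alpha)
  hl <- highlow_rejection(rsfc, sqm, alpha_grid)
  gm <- glm_metrics(rsfc, sqm, pair_distances)
  out <- list(qcfc = qc$values,
              median_abs_qcfc = qs$median_abs,
              qcfc_null_rejection_rate = qs$null_rejection_rate,
              qcfc_distance_corr = as.numeric(qs$distance_corr),
              highlow = hl,
              glm = gm)
  if (!is.null(uncensored))
    out$delta_between_subject_variance <- variance_change(rsfc, uncensored)
  out
}
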