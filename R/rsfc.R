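#' Mode-1000 intensity normalization
#'
#' Rescales a run so that the modal in-brain intensity equals 1000. The mode
#' is estimated from a 256-bin histogram of the pooled reference intensities
#' between their 1st and 99th percentiles (bin midpoint of the fullest bin).
#'
#' @param x numeric vector/matrix to rescale (e.g. `T x n_roi` run data).
#' @param reference pooled in-brain voxel-by-frame intensities from which the
#'   mode is estimated; defaults to `x` itself.
#' @return rescaled `x` with attribute `"scale"` (= 1000 / mode).
#' @export
mode1000_normalize <- function(x, reference = NULL) {
  ref <- if (is.null(reference)) as.numeric(x) else as.numeric(reference)
  ref <- ref[is.finite(ref)]
  if (length(ref) < 2 || diff(range(ref)) == 0) {
    m <- ref[1]
  } else {
    qs <- quantile(ref, c(0.01, 0.99), names = FALSE)
    if (qs[1] == qs[2]) {
      m <- qs[1]
    } else {
      br <- seq(qs[1], qs[2], length.out = 257)
      cnt <- tabulate(findInterval(ref, br, rightmost.closed = TRUE,
                                   all.inside = TRUE), nbins = 256)
      b <- which.max(cnt)
      m <- (br[b] + br[b + 1]) / 2
    }
  }
  if (!is.finite(m) || m <= 0)
    stop("modal intensity is not positive (", m, "); cannot mode-1000 normalize")
  out <- x * (1000 / m)
  attr(out, "scale") <- 1000 / m
  out
}

#' One step of 6-connected binary erosion
#'
#' A voxel survives only if it and all six face neighbors are in the mask;
#' voxels on the array boundary are eroded (outside counts as background).
#'
#' @param mask 3D logical (or 0/1) array.
#' @return eroded logical array.
#' @export
erode_mask <- function(mask) {
  m <- as.array(mask) != 0
  d <- dim(m)
  stopifnot(length(d) == 3)
  shift <- function(a, ax, by) {
    out <- array(FALSE, d)
    if (ax == 1) {
      if (by > 0) out[(1 + by):d[1], , ] <- a[1:(d[1] - by), , ]
      else out[1:(d[1] + by), , ] <- a[(1 - by):d[1], , ]
    } else if (ax == 2) {
      if (by > 0) out[, (1 + by):d[2], ] <- a[, 1:(d[2] - by), ]
      else out[, 1:(d[2] + by), ] <- a[, (1 - by):d[2], ]
    } else {
      if (by > 0) out[, , (1 + by):d[3]] <- a[, , 1:(d[3] - by)]
      else out[, , 1:(d[3] + by)] <- a[, , (1 - by):d[3]]
    }
    out
  }
  out <- m
  for (ax in 1:3) for (by in c(-1, 1)) out <- out & shift(m, ax, by)
  out
}

#' Nuisance signals from compartment masks
#'
#' Global signal (GS) is the per-frame mean over the brain mask. WM and CSF
#' signals are per-frame means over their masks after iterative 6-connected
#' erosion: up to `max_erosions` erosions are applied, stopping before an
#' erosion that would empty the mask.
#'
#' @param volumes 4D numeric array (x, y, z, t).
#' @param brain_mask,wm_mask,csf_mask 3D binary arrays on the same grid.
#' @param max_erosions maximum erosions for WM/CSF (default 4).
#' @return list with `GS`, `WM`, `CSF` (length-T), and `erosions` (named
#'   integer vector of erosions actually applied per compartment).
#' @export
compute_nuisance_signals <- function(volumes, brain_mask, wm_mask, csf_mask,
                                     max_erosions = 4L) {
  arr <- as.array(volumes)
  stopifnot(length(dim(arr)) == 4)
  mask_mean <- function(mask) {
    sel <- which(as.array(mask) != 0)
    if (!length(sel)) stop("empty mask")
    flat <- matrix(arr, nrow = prod(dim(arr)[1:3]))
    colMeans(flat[sel, , drop = FALSE])
  }
  erode_iter <- function(mask) {
    m <- as.array(mask) != 0
    if (!any(m)) stop("empty input mask")
    it <- 0L
    while (it < max_erosions) {
      nxt <- erode_mask(m)
      if (!any(nxt)) break
      m <- nxt
      it <- it + 1L
    }
    list(mask = m, iterations = it)
  }
  wm <- erode_iter(wm_mask)
  csf <- erode_iter(csf_mask)
  list(GS = mask_mean(brain_mask),
       WM = mask_mean(wm$mask),
       CSF = mask_mean(csf$mask),
       erosions = c(WM = wm$iterations, CSF = csf$iterations))
}

# ---- shared preprocessing primitives ---------------------------------------

# remove per-column mean and least-squares linear trend
detrend_cols <- function(x) {
  x <- as.matrix(x)
  T <- nrow(x)
  tt <- seq_len(T)
  X <- cbind(1, tt)
  x - X %*% qr.coef(qr(X), x)
}

# linear interpolation map over censored frames; edge runs held at nearest
# kept value
interp_map <- function(keep) {
  ci <- which(!keep)
  if (!length(ci)) return(NULL)
  ki <- which(keep)
  if (length(ki) < 2) stop("fewer than 2 kept frames")
  pos <- findInterval(ci, ki)
  lo <- ki[pmax(pos, 1L)]
  hi <- ki[pmin(pos + 1L, length(ki))]
  lo[pos == 0L] <- ki[1L]
  hi[pos == 0L] <- ki[1L]
  w <- ifelse(hi == lo, 0, (ci - lo) / (hi - lo))
  list(ci = ci, lo = lo, hi = hi, w = w)
}

apply_interp <- function(x, im) {
  if (is.null(im)) return(x)
  x[im$ci, ] <- (1 - im$w) * x[im$lo, , drop = FALSE] +
    im$w * x[im$hi, , drop = FALSE]
  x
}

#' Preprocess a run's timeseries for connectivity analysis
#'
#' The per-series path of the RSFC pipeline: demean, remove the
#' least-squares linear trend, linearly interpolate across censored frames
#' (edge runs of censored frames held at the nearest kept value), band-pass
#' filter (0.009--0.08 Hz zero-phase Butterworth by default), discard `trim`
#' frames at each edge (filter edge effects), and finally drop the censored
#' frames inside the retained window.
#'
#' @param x numeric `T x k` matrix (frames in rows) or vector.
#' @param TR repetition time, seconds.
#' @param keep logical keep vector of length `T`; `NULL` = keep all.
#' @param band a [filter_spec()] for the temporal filter.
#' @param trim frames discarded per edge after filtering (default 30).
#' @return list with `data` (retained frames x k), `filtered` (full-length
#'   filtered matrix), `window` (post-trim frame indices), `retained`
#'   (original-frame indices of the rows of `data`).
#' @export
preprocess_run <- function(x, TR, keep = NULL,
                           band = filter_spec("bandpass", c(0.009, 0.08)),
                           trim = 30) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  T <- nrow(X)
  if (is.null(keep)) keep <- rep(TRUE, T)
  stopifnot(length(keep) == T)
  if (sum(keep) < 2) stop("fewer than 2 kept frames")
  X <- detrend_cols(X)
  X <- apply_interp(X, interp_map(keep))
  Xf <- butterworth_zero_phase(X, 1 / TR, band)
  Xf <- as.matrix(Xf)
  if (T <= 2 * trim) stop("run too short for trim = ", trim)
  win <- (trim + 1):(T - trim)
  retained <- win[keep[win]]
  list(data = Xf[retained, , drop = FALSE], filtered = Xf,
       window = win, retained = retained)
}

#' Nuisance design matrix for partial-correlation RSFC
#'
#' Columns: intercept; the six motion parameters band-pass filtered with the
#' same filter as the data; their squares; their backward-difference
#' derivatives; the squared derivatives; processed WM and CSF signals and
#' their derivatives; optionally processed GS and its derivative. Squares
#' are taken *after* filtering and derivatives are of the filtered series
#' (element 1 of every derivative column is 0). WM/CSF/GS pass through the
#' same demean/detrend/interpolate/band-pass path as the data so design and
#' data stay spectrally matched; motion parameters are fully observed, so
#' they are filtered but not interpolated. All columns are then restricted to
#' the trimmed, censoring-surviving frames.
#'
#' @param motion a [motion_trace()].
#' @param wm,csf,gs length-T nuisance series (`gs = NULL` for no GSR).
#' @param keep logical keep vector.
#' @param TR repetition time, seconds.
#' @param band,trim as in [preprocess_run()].
#' @return design matrix (retained frames x p) with column names; p = 29
#'   without GS, 31 with.
#' @export
nuisance_design <- function(motion, wm, csf, gs = NULL, keep = NULL, TR,
                            band = filter_spec("bandpass", c(0.009, 0.08)),
                            trim = 30) {
  stopifnot(inherits(motion, "motion_trace"))
  T <- nrow(motion$values)
  if (is.null(keep)) keep <- rep(TRUE, T)
  mpb <- mp_design_block(motion, band)
  nu <- cbind(WM = wm, CSF = csf)
  if (!is.null(gs)) nu <- cbind(nu, GS = gs)
  pn <- preprocess_run(nu, TR, keep, band, trim)
  nfull <- pn$filtered
  dn <- rbind(0, diff(nfull))
  colnames(dn) <- paste0("d", colnames(nu))
  win <- pn$window
  retained <- pn$retained
  X <- cbind(intercept = 1,
             mpb[retained, , drop = FALSE],
             nfull[retained, , drop = FALSE],
             dn[retained, , drop = FALSE])
  X
}

# 24 motion-parameter design columns on the full run: filtered MPs, their
# squares, derivatives, squared derivatives
mp_design_block <- function(motion, band) {
  fs <- 1 / motion$TR
  mpf <- butterworth_zero_phase(motion$values, fs, band)
  dmp <- rbind(0, diff(mpf))
  out <- cbind(mpf, mpf^2, dmp, dmp^2)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_sq"),
                     paste0("dmp", 1:6), paste0("dmp", 1:6, "_sq"))
  out
}

#' Partial-correlation connectivity with Fisher z
#'
#' For every ROI pair, the Pearson correlation of the two series after
#' least-squares residualization against the full nuisance design (computed
#' on the retained frames only), Fisher r-to-z transformed immediately.
#'
#' @param x `n x n_roi` matrix of (preprocessed, retained-frame) ROI series.
#' @param design `n x p` design matrix including an intercept.
#' @return Fisher-z vector over ROI pairs in [roi_pairs()] order.
#' @export
partial_corr_z <- function(x, design) {
  x <- as.matrix(x)
  design <- as.matrix(design)
  stopifnot(nrow(x) == nrow(design))
  if (nrow(x) < ncol(design) + 2)
    stop("too few retained frames (", nrow(x), ") for ", ncol(design),
         " design columns")
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  E <- qr.resid(qx, x)
  r <- cor(E)
  fisher_z(r[upper.tri(r)])
}

#' Average run-level Fisher-z matrices into a subject-level RSFC vector
#'
#' @param zs list of run-level Fisher-z vectors (or a runs x pairs matrix).
#' @return subject-level Fisher-z vector with attribute `"n_runs"`.
#' @export
subject_rsfc <- function(zs) {
  z <- if (is.list(zs)) do.call(rbind, zs) else rbind(zs)
  if (nrow(z) == 0) stop("no included runs")
  out <- colMeans(z)
  attr(out, "n_runs") <- nrow(z)
  out
}

# ---- dataset-level drivers -------------------------------------------------

#' Mode-1000 normalize every run of a dataset
#'
#' @param dataset an `"mb_dataset"`.
#' @return the dataset with each run's data and nuisance series rescaled and
#'   `normalized = TRUE` (idempotent: already-normalized datasets pass
#'   through).
#' @export
normalize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "mb_dataset"))
  if (isTRUE(dataset$normalized)) return(dataset)
  dataset$runs <- lapply(dataset$runs, function(run) {
    sc <- attr(mode1000_normalize(run$data), "scale")
    run$data <- run$data * sc
    run$nuisance <- lapply(run$nuisance, function(v) v * sc)
    run
  })
  dataset$normalized <- TRUE
  dataset
}

# per-run cache of mask-independent pieces: detrended base matrix
# (ROI columns then WM, CSF[, GS]) and the 24 MP design columns
run_cache <- function(run, band, gsr) {
  nu <- cbind(WM = run$nuisance$WM, CSF = run$nuisance$CSF)
  if (gsr) nu <- cbind(nu, GS = run$nuisance$GS)
  base <- detrend_cols(cbind(run$data, nu))
  list(base = base, n_roi = ncol(run$data),
       mp = mp_design_block(run$motion, band),
       subject = run$subject, run = run$run, TR = run$TR)
}

# z vectors for several censor masks of one cached run, sharing one batched
# zero-phase filter call across masks
run_z_masks <- function(cache, keeps, band, trim) {
  T <- nrow(cache$base)
  nc <- ncol(cache$base)
  stacks <- lapply(keeps, function(keep) apply_interp(cache$base, interp_map(keep)))
  big <- butterworth_zero_phase(do.call(cbind, stacks), 1 / cache$TR, band)
  win <- (trim + 1):(T - trim)
  lapply(seq_along(keeps), function(a) {
    A <- big[, ((a - 1) * nc + 1):(a * nc), drop = FALSE]
    nW <- A[, (cache$n_roi + 1):nc, drop = FALSE]
    dN <- rbind(0, diff(nW))
    kw <- keeps[[a]][win]
    ret <- win[kw]
    X <- cbind(1, cache$mp[ret, , drop = FALSE], nW[ret, , drop = FALSE],
               dN[ret, , drop = FALSE])
    M <- A[ret, seq_len(cache$n_roi), drop = FALSE]
    E <- qr.resid(qr(X), M)
    r <- cor(E)
    fisher_z(r[upper.tri(r)])
  })
}

# masks for a dataset: named by run index; NULL plan = all-keep
plan_masks <- function(dataset, plan) {
  if (is.null(plan))
    return(lapply(dataset$runs, function(r) rep(TRUE, nrow(r$data))))
  plan$keep
}

#' Run the full RSFC pipeline over a dataset
#'
#' Mode-1000 normalizes (if needed), preprocesses every run under the given
#' censor plan (demean/detrend, interpolate censored frames, band-pass, trim,
#' drop censored frames), computes partial-correlation Fisher-z connectivity
#' per run controlling for the nuisance design, and averages run-level z over
#' each subject's included runs.
#'
#' @param dataset an `"mb_dataset"`.
#' @param plan a [apply_exclusion()] censor plan, or `NULL` for no censoring.
#' @param gsr include global signal (and derivative) in the design?
#' @param band,trim see [preprocess_run()].
#' @return object of class `"rsfc_result"`: list with `z` (retained subjects
#'   x pairs Fisher-z matrix, rownames = subject ids), `n_runs` per subject,
#'   `pair_dist`, `subjects`.
#' @export
rsfc_pipeline <- function(dataset, plan = NULL, gsr = FALSE,
                          band = filter_spec("bandpass", c(0.009, 0.08)),
                          trim = 30) {
  dataset <- normalize_dataset(dataset)
  masks <- plan_masks(dataset, plan)
  included <- if (is.null(plan)) rep(TRUE, length(dataset$runs)) else plan$runs$included
  subj_ids <- vapply(dataset$runs, `[[`, character(1), "subject")
  subjects <- unique(subj_ids)
  zs <- list(); n_runs <- integer(0)
  for (s in subjects) {
    ridx <- which(subj_ids == s & included)
    if (!length(ridx)) next
    run_z <- lapply(ridx, function(i) {
      cache <- run_cache(dataset$runs[[i]], band, gsr)
      run_z_masks(cache, masks[i], band, trim)[[1]]
    })
    zs[[s]] <- subject_rsfc(run_z)
    n_runs[s] <- length(ridx)
  }
  if (!length(zs)) stop("no subject has any included run")
  z <- do.call(rbind, zs)
  structure(list(z = z, n_runs = n_runs, pair_dist = dataset$pair_dist,
                 subjects = rownames(z)),
            class = "rsfc_result")
}

#' Framewise statistics for every run of a dataset
#'
#' @param dataset an `"mb_dataset"`.
#' @param statistic `"fd"` or `"dv"` (DV computed over the ROI series of the
#'   mode-1000 normalized data).
#' @param variant,spec passed to [compute_fd()] / [compute_dv()].
#' @return list of numeric framewise value vectors, one per run.
#' @export
dataset_framewise <- function(dataset, statistic = c("fd", "dv"),
                              variant = "lpf", spec = NULL) {
  statistic <- match.arg(statistic)
  if (statistic == "dv") dataset <- normalize_dataset(dataset)
  lapply(dataset$runs, function(run) {
    if (statistic == "fd") compute_fd(run$motion, variant, spec)$values
    else compute_dv(run$data, run$TR, variant, spec)$values
  })
}

#' Per-subject FD summaries (SQMs)
#'
#' Mean and median framewise displacement per subject over all analyzed
#' volumes of all runs -- the subject-level quality metrics used by the
#' QC-FC family.
#'
#' @param dataset an `"mb_dataset"`.
#' @param variant FD variant (default the LPF variant used for censoring).
#' @return data.frame with `subject`, `mean_fd`, `median_fd`.
#' @export
subject_fd_summary <- function(dataset, variant = "lpf") {
  fds <- dataset_framewise(dataset, "fd", variant)
  subj <- vapply(dataset$runs, `[[`, character(1), "subject")
  out <- lapply(unique(subj), function(s) {
    v <- unlist(fds[subj == s])
    data.frame(subject = s, mean_fd = mean(v), median_fd = median(v),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
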