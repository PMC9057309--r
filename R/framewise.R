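#' Framewise displacement (FD), standard / low-pass / notch variants
#'
#' FD at frame `t` is the sum over the six rigid-body parameters of the
#' absolute backward difference from frame `t - 1`, after converting
#' rotations to the arc length they displace a point on a 50 mm radius
#' sphere. `FD[1] = 0` by convention (no predecessor). For the `"lpf"` and
#' `"notch"` variants the six motion-parameter columns are filtered with a
#' zero-phase Butterworth filter *before* differencing: low-pass at 0.2 Hz by
#' default for `"lpf"`, band-stop over the respiratory band (0.31--0.43 Hz by
#' default) for `"notch"`.
#'
#' @param mp a [motion_trace()].
#' @param variant `"standard"`, `"lpf"` or `"notch"`.
#' @param spec optional [filter_spec()] overriding the variant default.
#' @return object of class `"framewise_series"`: list with `values`
#'   (length-T, mm), `statistic = "FD"`, `variant`, `filter`, `TR`.
#' @export
compute_fd <- function(mp, variant = c("standard", "lpf", "notch"),
                       spec = NULL) {
  stopifnot(inherits(mp, "motion_trace"))
  variant <- match.arg(variant)
  v <- mp$values
  rot <- v[, 4:6, drop = FALSE]
  rot <- switch(mp$units,
                degrees = rot * pi / 180,
                radians = rot,
                stop("unknown motion units: ", mp$units))
  v <- cbind(v[, 1:3, drop = FALSE], rot * 50) # arc length on 50 mm sphere
  fs <- 1 / mp$TR
  if (variant != "standard") {
    if (is.null(spec))
      spec <- if (variant == "lpf") filter_spec("lowpass", 0.2)
              else filter_spec("bandstop", c(0.31, 0.43))
    v <- butterworth_zero_phase(v, fs, spec)
  } else {
    spec <- filter_spec("none")
  }
  fd <- c(0, rowSums(abs(diff(v))))
  framewise_series(fd, "FD", variant, spec, mp$TR, run_id = mp$run_id)
}

#' DVARS (DV), standard / low-pass / notch variants
#'
#' DV at frame `t` is the root-mean-square over voxels (or ROIs) of the
#' backward temporal difference of the timeseries; `DV[1] = 0`. The input is
#' expected to be mode-1000 normalized already (see [mode1000_normalize()]).
#' For `"lpf"`/`"notch"` every series is zero-phase filtered before
#' differencing; for `"standard"` the caller may supply spatially smoothed
#' data (smoothing is conventional for standard DV only, never for the
#' filtered variants).
#'
#' @param x numeric `T x V` matrix, frames in rows, voxels/ROIs in columns.
#' @param TR repetition time in seconds.
#' @param variant `"standard"`, `"lpf"` or `"notch"`.
#' @param spec optional [filter_spec()] overriding the variant default.
#' @return a `"framewise_series"` with `statistic = "DV"`.
#' @export
compute_dv <- function(x, TR, variant = c("standard", "lpf", "notch"),
                       spec = NULL) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  if (ncol(x) == 0 || nrow(x) < 2) stop("empty or too-short voxel set")
  fs <- 1 / TR
  if (variant != "standard") {
    if (is.null(spec))
      spec <- if (variant == "lpf") filter_spec("lowpass", 0.2)
              else filter_spec("bandstop", c(0.31, 0.43))
    x <- butterworth_zero_phase(x, fs, spec)
  } else {
    spec <- filter_spec("none")
  }
  dv <- c(0, sqrt(rowMeans(diff(x)^2)))
  framewise_series(dv, "DV", variant, spec, TR)
}

framewise_series <- function(values, statistic, variant, filter, TR,
                             run_id = NA_character_) {
  structure(list(values = as.numeric(values), statistic = statistic,
                 variant = variant, filter = filter, TR = TR,
                 run_id = run_id),
            class = "framewise_series")
}

#' @export
print.framewise_series <- function(x, ...) {
  cat(sprintf("%s (%s), %d frames, median %.4g, max %.4g\n",
              x$statistic, x$variant, length(x$values),
              median(x$values[-1]), max(x$values)))
  invisible(x)
}

#' Gaussian volume smoothing (separable kernel)
#'
#' Smooths each frame of a 4D array with a separable Gaussian kernel of the
#' given full width at half maximum, within an optional mask (values outside
#' the mask neither contribute nor are updated; the kernel is renormalized
#' over in-mask voxels). Used only for standard DV, which is conventionally
#' computed on 4 mm FWHM smoothed data.
#'
#' @param arr 3D or 4D numeric array.
#' @param fwhm full width at half maximum, mm.
#' @param voxdim voxel size in mm (length 1 or 3).
#' @param mask optional 3D logical/0-1 array.
#' @return smoothed array, same shape.
#' @export
smooth_gaussian <- function(arr, fwhm, voxdim = 2, mask = NULL) {
  dims <- dim(arr)
  was3d <- length(dims) == 3
  if (was3d) { arr <- array(arr, c(dims, 1)); dims <- dim(arr) }
  if (length(voxdim) == 1) voxdim <- rep(voxdim, 3)
  sigma <- fwhm / 2.3548 / voxdim
  kerns <- lapply(sigma, function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k / sum(k)
  })
  m <- if (is.null(mask)) array(1, dims[1:3]) else (as.array(mask) != 0) * 1
  conv_axis <- function(a3, k, axis) {
    if (length(k) == 1) return(a3)
    r <- (length(k) - 1L) / 2L
    out <- array(0, dim(a3))
    for (o in -r:r) {
      w <- k[o + r + 1L]
      idx_src <- switch(axis,
        `1` = pmin(pmax(seq_len(dim(a3)[1]) + o, 1L), dim(a3)[1]),
        `2` = pmin(pmax(seq_len(dim(a3)[2]) + o, 1L), dim(a3)[2]),
        `3` = pmin(pmax(seq_len(dim(a3)[3]) + o, 1L), dim(a3)[3]))
      out <- out + w * switch(axis,
        `1` = a3[idx_src, , , drop = FALSE],
        `2` = a3[, idx_src, , drop = FALSE],
        `3` = a3[, , idx_src, drop = FALSE])
    }
    out
  }
  smooth3 <- function(a3) {
    for (ax in 1:3) a3 <- conv_axis(a3, kerns[[ax]], ax)
    a3
  }
  wm <- smooth3(m)
  out <- arr
  for (t in seq_len(dims[4])) {
    num <- smooth3(arr[, , , t] * m)
    st <- num / pmax(wm, 1e-12)
    st[m == 0] <- arr[, , , t][m == 0]
    out[, , , t] <- st
  }
  if (was3d) out <- array(out, dims[1:3])
  out
}
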