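#' Construct a motion trace
#'
#' A per-run rigid-body motion parameter series: columns 1--3 are
#' translations in mm, columns 4--6 rotations in `units`.
#'
#' @param values numeric `T x 6` matrix.
#' @param TR repetition time in seconds.
#' @param units rotation units, `"degrees"` (HCP convention) or `"radians"`.
#' @param subject_id,run_id identifiers.
#' @return object of class `"motion_trace"`.
#' @export
motion_trace <- function(values, TR, units = c("degrees", "radians"),
                         subject_id = NA_character_, run_id = NA_character_) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (ncol(values) != 6) stop("motion trace must have 6 columns")
  if (nrow(values) < 2) stop("motion trace must have at least 2 frames")
  if (anyNA(values)) stop("motion trace contains missing values")
  if (TR <= 0) stop("TR must be positive")
  structure(list(values = unname(values), TR = TR, units = units,
                 subject_id = subject_id, run_id = run_id),
            class = "motion_trace")
}

#' Read an HCP-dialect motion regressors file
#'
#' Reads a whitespace-delimited numeric motion-parameter file in the 12-column
#' HCP `Movement_Regressors.txt` dialect (3 translations in mm, 3 rotations,
#' then 6 backward-difference derivative columns, which are ignored). Only
#' the first six columns are returned.
#'
#' @param path file path.
#' @param units rotation units of the file (HCP writes degrees).
#' @param drop_leading number of leading (equilibration) frames to discard
#'   before any further processing (HCP workflows typically drop 10).
#' @param TR repetition time in seconds to attach.
#' @param subject_id,run_id identifiers to attach.
#' @return a [motion_trace()].
#' @export
read_motion_regressors <- function(path, units = c("degrees", "radians"),
                                   drop_leading = 0L, TR = 0.72,
                                   subject_id = NA_character_,
                                   run_id = NA_character_) {
  units <- match.arg(units)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty motion file: ", path)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  ncols <- lengths(toks)
  if (any(ncols < 6))
    stop("motion file ", path, " has fewer than 6 columns on line ",
         which(ncols < 6)[1])
  vals <- lapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.numeric(toks[[i]][1:6]))
    if (anyNA(v))
      stop("non-numeric motion value on line ", i, " of ", path)
    v
  })
  m <- do.call(rbind, vals)
  if (drop_leading > 0) {
    if (drop_leading >= nrow(m))
      stop("drop_leading (", drop_leading, ") >= number of rows (", nrow(m), ")")
    m <- m[-seq_len(drop_leading), , drop = FALSE]
  }
  motion_trace(m, TR = TR, units = units,
               subject_id = subject_id, run_id = run_id)
}

#' Define a set of spherical ROIs
#'
#' @param centers `n_roi x 3` matrix of sphere centers, world mm coordinates.
#' @param radius sphere radius in mm (default 5, i.e. 10 mm diameter).
#' @param labels optional character labels.
#' @return object of class `"roi_set"`.
#' @export
roi_set <- function(centers, radius = 5, labels = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stop("centers must have 3 columns (x, y, z in mm)")
  if (nrow(centers) < 2) stop("need at least 2 ROIs")
  if (radius <= 0) stop("radius must be positive")
  if (is.null(labels)) labels <- sprintf("ROI%03d", seq_len(nrow(centers)))
  structure(list(centers = unname(centers), radius = radius, labels = labels),
            class = "roi_set")
}

#' Read ROI sphere centers from a TSV file
#'
#' Expects a tab-delimited file with a header containing columns `x`, `y`,
#' `z` (mm) and optionally `label`.
#'
#' @param path file path.
#' @param radius sphere radius in mm.
#' @return a [roi_set()].
#' @export
read_roi_centers <- function(path, radius = 5) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("ROI centers file must have columns x, y, z; found: ",
         paste(names(tab), collapse = ", "))
  bad <- which(!stats::complete.cases(tab[need]) |
                 !vapply(seq_len(nrow(tab)),
                         function(i) all(is.finite(as.numeric(tab[i, need]))),
                         logical(1)))
  if (length(bad)) stop("malformed ROI center row ", bad[1], " in ", path)
  roi_set(as.matrix(tab[need]), radius = radius,
          labels = if ("label" %in% names(tab)) as.character(tab$label) else NULL)
}

#' Write / read a result table (TSV)
#'
#' Tab-delimited with header; floats serialized at 15 significant digits so
#' the round trip is stable well past 12 significant digits.
#'
#' @param x data.frame.
#' @param path file path.
#' @return `write_table` returns `path` invisibly; `read_result_table` the
#'   data.frame.
#' @export
write_table <- function(x, path) {
  stopifnot(is.data.frame(x))
  fmt <- x
  num <- vapply(fmt, is.double, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.15g", v))
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_result_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}

# config schema: name -> list(default or NULL if required, type)
config_schema <- function() {
  list(
    TR            = list(default = NULL,  type = "numeric"),
    gsr           = list(default = FALSE, type = "logical"),
    lpf_cutoff    = list(default = 0.2,   type = "numeric"),
    notch_band    = list(default = c(0.31, 0.43), type = "numeric"),
    band_pass     = list(default = c(0.009, 0.08), type = "numeric"),
    filter_order  = list(default = 2,     type = "numeric"),
    trim          = list(default = 30,    type = "numeric"),
    min_vol       = list(default = 167,   type = "numeric"),
    n_rand        = list(default = 10,    type = "numeric"),
    boot          = list(default = 10000, type = "numeric"),
    search_range  = list(default = c(0, 80), type = "numeric"),
    bisquare_c    = list(default = 4.685, type = "numeric"),
    drop_leading  = list(default = 0,     type = "numeric"),
    seed          = list(default = 1,     type = "numeric")
  )
}

#' Read and validate a pipeline configuration (YAML)
#'
#' Unknown keys are an error; missing keys with defaults are filled in;
#' missing required keys (currently `TR`) raise an error naming the key.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return validated named list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a mapping")
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in names(schema)) {
    if (is.null(cfg[[key]])) {
      if (is.null(schema[[key]]$default))
        stop("config is missing required key: ", key)
      cfg[[key]] <- schema[[key]]$default
    }
  }
  cfg
}

#' Extract mean ROI timeseries from a 4D NIfTI image
#'
#' For each ROI sphere, the unweighted mean over voxels whose *center* lies
#' within `radius` mm of the ROI center (voxel-center membership; no partial
#' volumes). ROIs with no in-image voxels yield an all-`NA` row and are
#' flagged.
#'
#' @param volume a 4D `RNifti` image (or path to one).
#' @param rois a [roi_set()].
#' @param mask optional 3D binary array restricting eligible voxels (e.g. a
#'   brain mask).
#' @return list with `data` (`T x n_roi` matrix, frames in rows), `empty`
#'   (logical vector flagging ROIs with zero voxels), `n_voxels` per ROI.
#' @export
extract_roi_timeseries <- function(volume, rois, mask = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  img <- if (is.character(volume)) RNifti::readNifti(volume) else volume
  arr <- as.array(img)
  if (length(dim(arr)) != 4) stop("expected a 4D volume series")
  dims <- dim(arr)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (inherits(xf, "try-error") || is.null(xf))
    stop("volume has no affine (xform); world coordinates unavailable")
  vox <- as.matrix(expand.grid(i = seq_len(dims[1]), j = seq_len(dims[2]),
                               k = seq_len(dims[3])))
  world <- RNifti::voxelToWorld(vox, img)
  keep_vox <- if (is.null(mask)) rep(TRUE, nrow(vox)) else as.logical(mask)[seq_len(nrow(vox))]
  Tn <- dim(arr)[4]
  flat <- matrix(arr, nrow = prod(dims), ncol = Tn)
  n_roi <- nrow(rois$centers)
  out <- matrix(NA_real_, Tn, n_roi)
  nv <- integer(n_roi)
  r2 <- rois$radius^2
  for (r in seq_len(n_roi)) {
    d2 <- (world[, 1] - rois$centers[r, 1])^2 +
      (world[, 2] - rois$centers[r, 2])^2 +
      (world[, 3] - rois$centers[r, 3])^2
    sel <- which(d2 <= r2 & keep_vox)
    nv[r] <- length(sel)
    if (length(sel) == 1) out[, r] <- flat[sel, ]
    else if (length(sel) > 1) out[, r] <- colMeans(flat[sel, , drop = FALSE])
  }
  if (all(nv == 0)) stop("no ROI contains any voxel")
  list(data = out, empty = nv == 0, n_voxels = nv)
}
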