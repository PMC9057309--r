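#' Keep-mask from a fixed framewise threshold
#'
#' Frames are flagged for censoring when their framewise statistic is
#' *strictly greater* than the threshold; ties at exactly `phi` are kept.
#'
#' @param series a `"framewise_series"` (or plain numeric vector).
#' @param phi positive threshold (mm for FD, signal units for DV). `Inf`
#'   keeps everything.
#' @return logical keep vector (`TRUE` = retain frame).
#' @export
mask_from_threshold <- function(series, phi) {
  stopifnot(phi > 0)
  v <- if (inherits(series, "framewise_series")) series$values else as.numeric(series)
  v <= phi
}

#' Combine censor masks (union of censored sets)
#'
#' Element-wise AND of keep vectors: a frame is kept only if every method
#' keeps it, i.e. the censored sets are unioned. Used when FD- and DV-based
#' censoring run in tandem.
#'
#' @param ... logical keep vectors of equal length (or a single list of them).
#' @return combined logical keep vector.
#' @export
combine_masks <- function(...) {
  masks <- list(...)
  if (length(masks) == 1 && is.list(masks[[1]]) && !is.logical(masks[[1]]))
    masks <- masks[[1]]
  lens <- lengths(masks)
  if (length(unique(lens)) != 1)
    stop("mask length mismatch: ", paste(lens, collapse = ", "))
  Reduce(`&`, masks)
}

#' Count-matched random censor mask
#'
#' Draws a uniformly random keep vector that censors exactly as many frames
#' as the supplied targeted mask, within the same run. This is the random
#' baseline of MAC-RSFC: targeted censoring is compared against removing the
#' same number of randomly selected volumes.
#'
#' @param keep targeted logical keep vector.
#' @param seed integer seed (deterministic output).
#' @return logical keep vector with `sum(!keep)` frames censored at random.
#' @export
random_mask_like <- function(keep, seed) {
  n_cens <- sum(!keep)
  out <- rep(TRUE, length(keep))
  if (n_cens == 0) return(out)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out[sample.int(length(keep), n_cens)] <- FALSE
  out
}

#' Run and subject exclusion with percent-removed accounting
#'
#' A run is included only if at least `min_vol` frames survive censoring
#' (167 frames = 2 minutes at TR 0.72 s); a subject is retained if at least
#' one run survives. `percent_removed` is `100 * flagged / total` where the
#' denominator counts every frame entering censoring consideration in every
#' run (frames of subsequently excluded runs included).
#'
#' @param masks list of logical keep vectors, one per run.
#' @param subjects vector of subject ids parallel to `masks`.
#' @param runs optional vector of run ids parallel to `masks`.
#' @param min_vol minimum surviving frames for run inclusion (default 167).
#' @return object of class `"censor_plan"`: list with `keep` (the masks),
#'   `runs` (data.frame: subject, run, kept, total, included), `subjects`
#'   (data.frame: subject, retained), `frames_flagged`, `frames_total`,
#'   `percent_removed`, `n_retained`, `min_vol`.
#' @export
apply_exclusion <- function(masks, subjects, runs = NULL, min_vol = 167) {
  stopifnot(length(masks) == length(subjects))
  if (is.null(runs)) runs <- seq_along(masks)
  kept <- vapply(masks, sum, integer(1))
  total <- lengths(masks)
  included <- kept >= min_vol
  run_tab <- data.frame(subject = as.character(subjects),
                        run = as.character(runs),
                        kept = kept, total = total, included = included,
                        stringsAsFactors = FALSE)
  subj <- unique(run_tab$subject)
  retained <- vapply(subj, function(s) any(run_tab$included[run_tab$subject == s]),
                     logical(1))
  flagged <- sum(total - kept)
  structure(list(keep = masks, runs = run_tab,
                 subjects = data.frame(subject = subj, retained = retained,
                                       stringsAsFactors = FALSE),
                 frames_flagged = flagged, frames_total = sum(total),
                 percent_removed = 100 * flagged / sum(total),
                 n_retained = sum(retained), min_vol = min_vol),
            class = "censor_plan")
}

#' @export
print.censor_plan <- function(x, ...) {
  cat(sprintf(paste0("censor plan: %d runs (%d included), %d subjects ",
                     "(%d retained), %.2f%% frames removed\n"),
              nrow(x$runs), sum(x$runs$included), nrow(x$subjects),
              x$n_retained, x$percent_removed))
  invisible(x)
}
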