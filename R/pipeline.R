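# Manifest loading and the end-to-end artifact pipeline shared by the CLI.

# 32-bit polynomial rolling hash of the deparsed config, for artifact
# provenance (computed in doubles; all intermediates stay below 2^53)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg[order(names(cfg))]), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Load a dataset from a run manifest
#'
#' The manifest is a tab-delimited file with header columns `subject_id`,
#' `run_id`, `timeseries`, `motion`, `nuisance`, and optionally `TR` and
#' `discard_leading`. Paths are resolved relative to the manifest's
#' directory. `timeseries` is a numeric TSV (frames x ROIs, no header) or a
#' 4D NIfTI (then `rois` is required); `motion` is an HCP-dialect motion
#' regressors file; `nuisance` is a TSV with header columns `WM`, `CSF` and
#' optionally `GS` (when absent, GS falls back to the ROI-mean signal).
#'
#' @param path manifest file path.
#' @param TR default repetition time for rows without a `TR` column, seconds.
#' @param rois optional [roi_set()] for NIfTI extraction and pair distances.
#' @param units rotation units of the motion files.
#' @return an `"mb_dataset"` (without ground truth).
#' @export
load_dataset <- function(path, TR = 0.72, rois = NULL,
                         units = c("degrees", "radians")) {
  units <- match.arg(units)
  man <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("subject_id", "run_id", "timeseries", "motion", "nuisance")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(man$subject_id, man$run_id)
  if (anyDuplicated(key))
    stop("duplicate (subject, run) key in manifest: ", key[duplicated(key)][1])
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  for (col in c("timeseries", "motion", "nuisance")) {
    p <- resolve(man[[col]])
    bad <- which(!file.exists(p))
    if (length(bad))
      stop("missing ", col, " file for (", man$subject_id[bad[1]], ", ",
           man$run_id[bad[1]], "): ", p[bad[1]])
    man[[col]] <- p
  }
  runs <- lapply(seq_len(nrow(man)), function(i) {
    tr <- if ("TR" %in% names(man)) man$TR[i] else TR
    dl <- if ("discard_leading" %in% names(man)) man$discard_leading[i] else 0L
    ts_path <- man$timeseries[i]
    data <- if (grepl("\\.nii(\\.gz)?$", ts_path)) {
      if (is.null(rois)) stop("NIfTI timeseries require a roi_set")
      extract_roi_timeseries(ts_path, rois)$data
    } else {
      as.matrix(read.table(ts_path, header = FALSE))
    }
    if (dl > 0) data <- data[-seq_len(dl), , drop = FALSE]
    nu <- read.table(man$nuisance[i], header = TRUE, sep = "\t")
    if (!all(c("WM", "CSF") %in% names(nu)))
      stop("nuisance file for (", man$subject_id[i], ", ", man$run_id[i],
           ") must have WM and CSF columns")
    motion <- read_motion_regressors(man$motion[i], units = units,
                                     drop_leading = dl, TR = tr,
                                     subject_id = man$subject_id[i],
                                     run_id = man$run_id[i])
    if (nrow(motion$values) != nrow(data))
      stop("frame count mismatch between motion and timeseries for (",
           man$subject_id[i], ", ", man$run_id[i], ")")
    list(data = data, motion = motion,
         nuisance = list(GS = if ("GS" %in% names(nu)) nu$GS else rowMeans(data),
                         WM = nu$WM, CSF = nu$CSF),
         TR = tr, subject = as.character(man$subject_id[i]),
         run = as.character(man$run_id[i]))
  })
  centers <- if (!is.null(rois)) rois$centers else NULL
  structure(list(runs = runs, subjects = unique(as.character(man$subject_id)),
                 ground_truth_z = NULL, subject_truth_z = NULL,
                 roi_centers = centers,
                 pair_dist = if (is.null(centers)) NULL else pair_distances(centers),
                 cfg = list(TR = TR), normalized = FALSE),
            class = "mb_dataset")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

write_tsv_provenance <- function(x, path, hash, seed) {
  con <- file(path, "w")
  writeLines(sprintf("# config=%s seed=%d", hash, as.integer(seed)), con)
  close(con)
  fmt <- x
  num <- vapply(fmt, is.double, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.15g", v))
  suppressWarnings(write.table(fmt, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Run the full artifact pipeline on a dataset
#'
#' Sequencing: framewise statistics, censoring optimization for the chosen
#' method, the optimal censor plan, RSFC under that plan and uncensored,
#' classic DQMs, and the MAC-RSFC curve over the sweep targets. Writes
#' `framewise.tsv`, `plan.json`, `rsfc.tsv`, `dqm.json`, `mac.tsv` and
#' `optim.json` into `out_dir`; every artifact embeds the config hash and
#' seed. Inputs are never mutated.
#'
#' @param dataset an `"mb_dataset"` (e.g. from [load_dataset()] or
#'   [simulate_dataset()]).
#' @param config validated config list (see [read_config()]).
#' @param out_dir output directory (created if needed).
#' @param method censoring method to optimize.
#' @param targets percent-removed sweep targets.
#' @param search_range optimizer bounds, percent removed.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(dataset, config, out_dir,
                         method = c("lpf-fd", "gev-dv", "combined-ratio"),
                         targets = seq(0, 100, by = 0.5),
                         search_range = NULL) {
  method <- match.arg(method)
  config <- read_config(config)
  if (is.null(search_range)) search_range <- config$search_range
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  band <- filter_spec("bandpass", config$band_pass, config$filter_order)
  prov <- list(config_hash = hash, seed = seed)
  paths <- list()

  dataset <- stage("normalize", normalize_dataset(dataset))
  fw <- stage("framewise", {
    fd <- dataset_framewise(dataset, "fd", "lpf")
    dv <- dataset_framewise(dataset, "dv", "lpf")
    do.call(rbind, lapply(seq_along(fd), function(i)
      data.frame(subject = dataset$runs[[i]]$subject,
                 run = dataset$runs[[i]]$run,
                 frame = seq_along(fd[[i]]),
                 lpf_fd = fd[[i]], lpf_dv = dv[[i]])))
  })
  paths$framewise <- file.path(out_dir, "framewise.tsv")
  write_tsv_provenance(fw, paths$framewise, hash, seed)

  opt <- stage("optimize", optimize_censoring(
    dataset, method, targets = targets,
    ratio = if (method == "combined-ratio") 0.02438 else NULL,
    search_range = search_range, n_rand = config$n_rand, seed = seed,
    gsr = config$gsr, band = band, trim = config$trim,
    min_vol = config$min_vol))
  paths$optim <- file.path(out_dir, "optim.json")
  jsonlite::write_json(c(prov, list(
    method = method, parameter = opt$parameter,
    percent_removed = opt$percent_removed, delta_mse = opt$delta_mse,
    search_range = opt$search_range,
    n_gev_fallback = opt$sweep$n_gev_fallback,
    n_overshoot = attr(opt$curve, "n_overshoot"),
    curve = opt$curve[seq(1, nrow(opt$curve), by = 10), ])),
    paths$optim, auto_unbox = TRUE, digits = NA)

  plan <- stage("censor", {
    fwv <- sweep_framewise(dataset, method, "lpf", "lpf")
    masks <- method_masks(fwv, method, opt$parameter,
                          if (method == "combined-ratio") 0.02438 else NULL)
    apply_exclusion(masks,
                    vapply(dataset$runs, `[[`, character(1), "subject"),
                    vapply(dataset$runs, `[[`, character(1), "run"),
                    config$min_vol)
  })
  paths$plan <- file.path(out_dir, "plan.json")
  jsonlite::write_json(c(prov, list(
    method = method, parameter = opt$parameter, runs = plan$runs,
    percent_removed = plan$percent_removed, n_retained = plan$n_retained)),
    paths$plan, auto_unbox = TRUE, digits = NA)

  rs <- stage("rsfc", rsfc_pipeline(dataset, plan, gsr = config$gsr,
                                    band = band, trim = config$trim))
  rs0 <- stage("rsfc", rsfc_pipeline(dataset, NULL, gsr = config$gsr,
                                     band = band, trim = config$trim))
  ztab <- data.frame(subject = rownames(rs$z), rs$z, check.names = FALSE)
  paths$rsfc <- file.path(out_dir, "rsfc.tsv")
  write_tsv_provenance(ztab, paths$rsfc, hash, seed)

  dqm <- stage("dqm", {
    sqm <- subject_fd_summary(dataset)
    pd <- dataset$pair_dist
    if (is.null(pd)) pd <- seq_len(ncol(rs$z))
    dqm_report(rs, sqm, pd, uncensored = rs0)
  })
  paths$dqm <- file.path(out_dir, "dqm.json")
  jsonlite::write_json(c(prov, dqm), paths$dqm, auto_unbox = TRUE, digits = NA)

  mac_tab <- stage("mac", {
    fwv <- sweep_framewise(dataset, method, "lpf", "lpf")
    rows <- lapply(targets[targets <= max(search_range)], function(tg) {
      par <- solve_param(fwv, method, tg,
                         if (method == "combined-ratio") 0.02438 else NULL)
      masks <- method_masks(fwv, method, par,
                            if (method == "combined-ratio") 0.02438 else NULL)
      pl <- apply_exclusion(masks,
                            vapply(dataset$runs, `[[`, character(1), "subject"),
                            vapply(dataset$runs, `[[`, character(1), "run"),
                            config$min_vol)
      if (pl$n_retained < 8) return(NULL)
      tab <- delta_z(dataset, pl, n_rand = config$n_rand, seed = seed,
                     gsr = config$gsr, band = band, trim = config$trim)
      m <- mac_rsfc(tab, boot = config$boot, seed = seed)
      data.frame(target = tg, percent_removed = pl$percent_removed,
                 mac = m$mac, ci_low = m$ci_low, ci_high = m$ci_high)
    })
    do.call(rbind, rows)
  })
  paths$mac <- file.path(out_dir, "mac.tsv")
  write_tsv_provenance(mac_tab, paths$mac, hash, seed)

  invisible(paths)
}

#' End-to-end demo: simulate, censor, optimize
#'
#' Simulates a 12-subject synthetic cohort with motion-coupled artifact and
#' runs the complete [run_pipeline()] on it with a coarse sweep, writing all
#' six artifact types. Deterministic given `seed`.
#'
#' @param seed integer seed driving the simulation and every stochastic step.
#' @param out_dir output directory.
#' @param n_subjects,runs_per_subject,T cohort size knobs (kept small so the
#'   demo finishes in seconds-to-minutes).
#' @param boot bootstrap resamples for the demo's MAC-RSFC intervals.
#' @param artifact_coupling FD-to-signal artifact gain for the simulated
#'   cohort; the default 20 makes the injected bias large enough that an
#'   interior censoring optimum exists (FD is ~0.05 mm, so the artifact
#'   amplitude is roughly `artifact_coupling / 20` signal SDs).
#' @return invisibly, the artifact path list from [run_pipeline()].
#' @export
run_demo <- function(seed = 1, out_dir = "mbcensor-demo", n_subjects = 12,
                     runs_per_subject = 2, T = 300, boot = 2000,
                     artifact_coupling = 20) {
  cfg <- synth_config(n_subjects = n_subjects,
                      runs_per_subject = runs_per_subject, T = T,
                      artifact_coupling = artifact_coupling, seed = seed)
  ds <- simulate_dataset(cfg)
  config <- read_config(list(TR = cfg$TR, seed = seed, boot = boot,
                             search_range = c(0, 30)))
  run_pipeline(ds, config, out_dir, method = "lpf-fd",
               targets = seq(0, 30, by = 5), search_range = c(0, 30))
}
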