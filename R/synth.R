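#' Configuration for the synthetic multiband dataset generator
#'
#' Defines the study conditions emulated by [simulate_dataset()]: a
#' multi-subject, multi-run multiband acquisition whose motion traces contain
#' slow drift, respiratory (pseudo)motion at `resp_freq`, and sparse motion
#' spikes, and whose ROI timeseries follow a known network covariance plus an
#' optional motion-coupled, distance-dependent artifact.
#'
#' Defaults follow typical multiband resting-state conditions: TR = 0.72 s,
#' respiratory rate 0.3 Hz, per-subject motion severity log-normal across
#' subjects, ~1% spike probability per frame, observed signal = network
#' signal + white noise of equal scale (so true correlations of ~0.6 within
#' a network appear as observed correlations of ~0.3).
#'
#' @param n_subjects,runs_per_subject,T,TR,n_roi dataset geometry.
#' @param roi_centers `n_roi x 3` mm coordinates; default: reproducible
#'   uniform draws in a 120 mm box.
#' @param motion_level per-subject severity multipliers (recycled); default:
#'   log-normal (sdlog 0.4) draws from the master seed.
#' @param resp_freq respiratory frequency, Hz (must be below Nyquist).
#' @param resp_amp respiratory displacement amplitude on the phase-encode
#'   translation axis, mm (scaled by subject severity).
#' @param spike_rate per-frame probability of a transient motion spike.
#' @param spike_amp spike displacement scale, mm (scaled by severity).
#' @param drift_sd innovation SD (mm/frame) of the slow AR(1)-velocity drift.
#' @param artifact_coupling gain from the (HRF-convolved) FD series into the
#'   ROI signal; 0 = artifact-free data.
#' @param network_covariance target ROI x ROI covariance of the neural
#'   signal (symmetric PSD, unit diagonal); default: two equal blocks with
#'   within-block correlation 0.6 and between-block 0.1.
#' @param noise_sd white observation noise SD, in signal-SD units.
#' @param seed master integer seed; all per-run random streams are derived
#'   from it by a fixed counter scheme.
#' @return object of class `"synth_config"`.
#' @export
synth_config <- function(n_subjects = 20, runs_per_subject = 4, T = 600,
                         TR = 0.72, n_roi = 10, roi_centers = NULL,
                         motion_level = NULL, resp_freq = 0.3,
                         resp_amp = 0.06, spike_rate = 0.01, spike_amp = 0.3,
                         drift_sd = 0.002, artifact_coupling = 0,
                         network_covariance = NULL, noise_sd = 1, seed = 1) {
  if (T < 240) stop("T must be >= 240")
  if (TR <= 0) stop("TR must be positive")
  if (resp_freq <= 0 || resp_freq >= 1 / (2 * TR))
    stop("resp_freq must lie strictly inside (0, Nyquist = ",
         signif(1 / (2 * TR), 4), " Hz)")
  if (spike_rate < 0 || spike_rate > 1) stop("spike_rate must be in [0, 1]")
  if (is.null(roi_centers)) {
    set.seed(derive_seed(seed, 0L, 0L, 1L))
    roi_centers <- matrix(runif(n_roi * 3, -60, 60), ncol = 3)
  }
  roi_centers <- as.matrix(roi_centers)
  stopifnot(nrow(roi_centers) == n_roi, ncol(roi_centers) == 3)
  if (is.null(network_covariance)) {
    block <- rep(1:2, c(ceiling(n_roi / 2), floor(n_roi / 2)))
    network_covariance <- outer(block, block,
                                function(a, b) ifelse(a == b, 0.6, 0.1))
    diag(network_covariance) <- 1
  }
  network_covariance <- as.matrix(network_covariance)
  if (!isTRUE(all.equal(network_covariance, t(network_covariance))))
    stop("network_covariance must be symmetric")
  ev <- eigen(network_covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("network_covariance must be positive semi-definite")
  if (is.null(motion_level)) {
    set.seed(derive_seed(seed, 0L, 0L, 2L))
    motion_level <- exp(rnorm(n_subjects, 0, 0.4))
  }
  motion_level <- rep_len(motion_level, n_subjects)
  structure(list(n_subjects = n_subjects, runs_per_subject = runs_per_subject,
                 T = T, TR = TR, n_roi = n_roi, roi_centers = roi_centers,
                 motion_level = motion_level, resp_freq = resp_freq,
                 resp_amp = resp_amp, spike_rate = spike_rate,
                 spike_amp = spike_amp, drift_sd = drift_sd,
                 artifact_coupling = artifact_coupling,
                 network_covariance = network_covariance,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate one run's motion trace
#'
#' Motion = slow drift (cumulative AR(1) velocity per axis) + respiratory
#' (pseudo)motion on the phase-encode translation axis + sparse transient
#' spikes on a random translation axis. The respiratory waveform is a mildly
#' asymmetric breath shape, `sin(phase) + 0.5 cos(2 phase)` (inhalation
#' faster than exhalation), whose rectified derivative -- and hence the FD
#' trace -- retains its dominant spectral line at `resp_freq`. Rotations are
#' emitted in degrees (HCP motion-file dialect).
#'
#' @param cfg a [synth_config()].
#' @param subject_severity severity multiplier for respiratory and spike
#'   amplitude.
#' @param seed integer seed; output is a deterministic function of
#'   `(cfg, subject_severity, seed)`.
#' @return a [motion_trace()] of `cfg$T` frames.
#' @export
simulate_motion_trace <- function(cfg, subject_severity = 1, seed = 1) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  T <- cfg$T
  mp <- matrix(0, T, 6)
  for (p in 1:6) {
    innov <- rnorm(T, 0, cfg$drift_sd)
    vel <- as.numeric(stats::filter(innov, 0.995, method = "recursive"))
    mp[, p] <- cumsum(vel) * 0.1
  }
  tsec <- (seq_len(T) - 1) * cfg$TR
  phase <- 2 * pi * cfg$resp_freq * tsec + runif(1, 0, 2 * pi)
  mp[, 2] <- mp[, 2] +
    cfg$resp_amp * subject_severity * (sin(phase) + 0.5 * cos(2 * phase))
  if (cfg$spike_rate > 0 && subject_severity > 0) {
    hit <- which(runif(T) < cfg$spike_rate)
    for (s in hit) {
      ax <- sample.int(3, 1)
      dur <- sample.int(2, 1)
      amp <- cfg$spike_amp * subject_severity * rnorm(1)
      idx <- s:min(T, s + dur - 1)
      mp[idx, ax] <- mp[idx, ax] + amp
    }
  }
  motion_trace(mp, TR = cfg$TR, units = "degrees")
}

# causal exponential (HRF-like) kernel, 6 s decay, unit mass
artifact_from_fd <- function(fd, TR, tau = 6) {
  K <- ceiling(4 * tau / TR)
  h <- exp(-(0:K) * TR / tau)
  h <- h / sum(h)
  padded <- c(rep(0, K), fd)
  out <- as.numeric(stats::filter(padded, h, method = "convolution", sides = 1))
  out[(K + 1):(K + length(fd))]
}

# distance-dependent per-ROI artifact loadings in (0, 1], largest near the
# centroid so nearby ROI pairs share more artifact
artifact_loadings <- function(centers, lambda = 50) {
  ctr <- colMeans(centers)
  d <- sqrt(rowSums(sweep(centers, 2, ctr)^2))
  l <- exp(-d / lambda)
  l / max(l)
}

#' Simulate a full synthetic multiband dataset
#'
#' Per run, the ROI timeseries is a temporally white multivariate Gaussian
#' draw from `network_covariance`, plus white observation noise, plus (when
#' `artifact_coupling > 0`) the run's FD series convolved with a 6 s
#' exponential kernel, scaled per ROI by spatially smooth loadings that
#' decay with distance from the ROI cloud's centroid -- so the injected
#' artifact inflates short-distance connectivity more than long-distance
#' connectivity. Output intensities sit on a baseline of 800 scanner units
#' with ~1% signal amplitude, so mode-1000 normalization behaves as on real
#' data. Nuisance WM/CSF series are independent noise carrying half the
#' artifact gain; GS is the mean over ROI series.
#'
#' The ground-truth Fisher-z vector is `atanh` of the correlation implied by
#' `network_covariance + noise_sd^2 I`, i.e. the true correlation of
#' artifact-free observed data.
#'
#' @param cfg a [synth_config()].
#' @return object of class `"mb_dataset"`: list with `runs` (each: `subject`,
#'   `run`, `data` `T x n_roi` matrix, `motion`, `nuisance`, `TR`),
#'   `subjects` (data.frame with severity), `ground_truth_z`, `roi_centers`,
#'   `pair_dist`, `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  simulate_dataset_impl(cfg, subject_truth_z = NULL)
}

simulate_dataset_impl <- function(cfg, subject_truth_z = NULL,
                                  severity_mult = NULL, trait = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  sigma_obs <- cfg$network_covariance + diag(cfg$noise_sd^2, cfg$n_roi)
  base_z <- fisher_z(stats::cov2cor(sigma_obs)[upper.tri(sigma_obs)])
  load <- artifact_loadings(cfg$roi_centers)
  if (is.null(severity_mult)) severity_mult <- rep(1, cfg$n_subjects)
  runs <- vector("list", cfg$n_subjects * cfg$runs_per_subject)
  idx <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    sev <- cfg$motion_level[s] * severity_mult[s]
    # per-subject signal covariance (confounded cohorts override base)
    if (is.null(subject_truth_z)) {
      chol_sig <- chol(cfg$network_covariance + diag(1e-10, cfg$n_roi))
    } else {
      r_obs <- diag(cfg$n_roi)
      r_obs[upper.tri(r_obs)] <- tanh(subject_truth_z[s, ])
      r_obs <- r_obs + t(r_obs) - diag(cfg$n_roi)
      sig <- r_obs * (1 + cfg$noise_sd^2) - diag(cfg$noise_sd^2, cfg$n_roi)
      e <- eigen((sig + t(sig)) / 2, symmetric = TRUE)
      ev <- pmax(e$values, 1e-8)
      sig <- e$vectors %*% (ev * t(e$vectors))
      chol_sig <- chol(sig)
    }
    for (r in seq_len(cfg$runs_per_subject)) {
      idx <- idx + 1L
      mt <- simulate_motion_trace(cfg, sev, derive_seed(cfg$seed, s, r, 3L))
      mt$subject_id <- sprintf("sub%03d", s)
      mt$run_id <- sprintf("run%d", r)
      set.seed(derive_seed(cfg$seed, s, r, 4L))
      z <- matrix(rnorm(cfg$T * cfg$n_roi), cfg$T, cfg$n_roi) %*% chol_sig
      z <- z + matrix(rnorm(cfg$T * cfg$n_roi, 0, cfg$noise_sd),
                      cfg$T, cfg$n_roi)
      if (cfg$artifact_coupling > 0) {
        fd <- compute_fd(mt, "standard")$values
        art <- artifact_from_fd(fd, cfg$TR)
        z <- z + cfg$artifact_coupling * outer(art, load)
      }
      data <- 800 + 8 * z
      # WM/CSF are artifact-free noise: were they to share the gray-matter
      # artifact time course, the WM/CSF nuisance regression would remove the
      # injected artifact almost completely and no censoring could matter
      nuis <- list(
        GS = rowMeans(data),
        WM = 800 + 8 * rnorm(cfg$T),
        CSF = 800 + 8 * rnorm(cfg$T)
      )
      runs[[idx]] <- list(subject = sprintf("sub%03d", s),
                          run = sprintf("run%d", r),
                          data = data, motion = mt, nuisance = nuis,
                          TR = cfg$TR)
    }
  }
  subjects <- data.frame(subject = sprintf("sub%03d", seq_len(cfg$n_subjects)),
                         severity = cfg$motion_level * severity_mult,
                         stringsAsFactors = FALSE)
  if (!is.null(trait)) subjects$trait <- trait
  structure(list(runs = runs, subjects = subjects,
                 ground_truth_z = base_z,
                 subject_truth_z = subject_truth_z,
                 roi_centers = cfg$roi_centers,
                 pair_dist = pair_distances(cfg$roi_centers),
                 cfg = cfg, normalized = FALSE),
            class = "mb_dataset")
}

#' Simulate a cohort with a "third variable" trait confound
#'
#' Half of the subjects (alternating) carry a latent binary trait that both
#' raises their true connectivity (adding `trait_effect` Fisher-z units to
#' every pair among the first third of ROIs) and multiplies their motion
#' severity by `severity_factor`. With `artifact_coupling = 0` such a cohort
#' has *no* motion artifact in the signal, yet QC-FC style metrics reject
#' their null -- the confound these metrics cannot distinguish from artifact.
#'
#' @param cfg a [synth_config()].
#' @param trait_effect Fisher-z shift added for trait carriers (>= 0).
#' @param severity_factor motion-severity multiplier for carriers.
#' @return an `"mb_dataset"` with `subjects$trait` and per-subject truth in
#'   `$subject_truth_z`.
#' @export
simulate_confounded_cohort <- function(cfg, trait_effect,
                                       severity_factor = 1.5) {
  stopifnot(inherits(cfg, "synth_config"), trait_effect >= 0)
  trait <- rep(c(TRUE, FALSE), length.out = cfg$n_subjects)
  n_pair <- cfg$n_roi * (cfg$n_roi - 1) / 2
  sigma_obs <- cfg$network_covariance + diag(cfg$noise_sd^2, cfg$n_roi)
  base_z <- fisher_z(stats::cov2cor(sigma_obs)[upper.tri(sigma_obs)])
  pr <- roi_pairs(cfg$n_roi)
  hub <- seq_len(max(2, ceiling(cfg$n_roi / 3)))
  sel <- pr$i %in% hub & pr$j %in% hub
  truth <- matrix(rep(base_z, each = cfg$n_subjects), cfg$n_subjects, n_pair)
  truth[trait, sel] <- truth[trait, sel] + trait_effect
  simulate_dataset_impl(cfg, subject_truth_z = truth,
                        severity_mult = ifelse(trait, severity_factor, 1),
                        trait = trait)
}

#' @export
print.mb_dataset <- function(x, ...) {
  cat(sprintf("mb_dataset: %d subjects, %d runs, T = %d, TR = %.3g s, %d ROIs\n",
              nrow(x$subjects), length(x$runs), nrow(x$runs[[1]]$data),
              x$runs[[1]]$TR, ncol(x$runs[[1]]$data)))
  invisible(x)
}
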