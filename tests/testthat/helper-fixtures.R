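# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# small motion-coupled cohort reused across rsfc/mac/mse tests
small_dataset <- function() {
  if (is.null(fixture_env$ds)) {
    cfg <- synth_config(n_subjects = 10, runs_per_subject = 2, T = 300,
                        n_roi = 6, artifact_coupling = 1, seed = 11)
    fixture_env$ds <- simulate_dataset(cfg)
  }
  fixture_env$ds
}

# all-keep censor plan for a dataset
full_plan <- function(ds, min_vol = 167) {
  apply_exclusion(lapply(ds$runs, function(r) rep(TRUE, nrow(r$data))),
                  vapply(ds$runs, `[[`, character(1), "subject"),
                  vapply(ds$runs, `[[`, character(1), "run"), min_vol)
}

# plan from a pooled LPF-FD quantile at `percent` removal
fd_plan <- function(ds, percent, min_vol = 167) {
  fd <- dataset_framewise(ds, "fd", "lpf")
  phi <- if (percent <= 0) Inf else
    unname(quantile(unlist(fd), 1 - percent / 100))
  apply_exclusion(lapply(fd, function(v) v <= phi),
                  vapply(ds$runs, `[[`, character(1), "subject"),
                  vapply(ds$runs, `[[`, character(1), "run"), min_vol)
}
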