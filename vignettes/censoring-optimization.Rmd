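---
title: "Volume censoring and censoring-parameter optimization for multiband fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume censoring and censoring-parameter optimization for multiband fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
# All chunks are illustrative and not evaluated at build time: the workflows
# below run minutes-long simulations that belong in the test suite, not in
# package builds.
knitr::opts_chunk$set(eval = FALSE)
library(mbcensor)
```

## The problem

Head motion produces artifactual, distance-dependent inflation of
resting-state functional connectivity (RSFC) estimates. *Volume censoring*
("scrubbing") removes individual timepoints whose framewise statistics
indicate motion or signal disruption. Two questions drive this package:

1. **Which frames should be flagged in multiband (fast-TR) data?** At sub-second
   TRs, respiration — both true respiratory motion and factitious
   "pseudomotion" in the phase-encode direction — dominates the motion
   parameters. Framewise displacement (FD) computed on raw parameters flags
   respiratory oscillation rather than the transient displacements that
   actually corrupt the signal.
2. **How aggressively should one censor?** Censoring removes artifact
   (reducing bias of group-mean RSFC) but discards data (increasing
   variance). The package treats threshold selection as an explicit
   bias–variance trade-off, minimized on the data at hand.

## Framewise statistics

`compute_fd()` sums the absolute backward differences of the six rigid-body
parameters, converting rotations to arc length on a 50 mm sphere; frame 1 is
0 by convention. `compute_dv()` (DV/DVARS) is the spatial root mean square of
the backward temporal difference of mode-1000-normalized data, 0 at frame 1.

Both statistics support three variants. `"standard"` differences the raw
series. `"lpf"` low-pass filters the motion parameters (or voxel series) at
0.2 Hz *before* differencing, removing respiratory content. `"notch"`
band-stop filters the 0.31–0.43 Hz respiratory band instead. Filtering
always precedes differencing.

```{r framewise}
fd <- compute_fd(motion, variant = "lpf")      # LPF-FD
dv <- compute_dv(run_data, TR = 0.72, variant = "lpf")  # LPF-DV
```

### Zero-phase filtering: a numerical note

Filtered variants require a forward–backward (zero-phase) order-2
Butterworth filter. `butterworth_zero_phase()` implements it in the
frequency domain: the series is reflected to even symmetry (removing edge
discontinuity), transformed with `mvfft`, multiplied by the *analog*
two-pass magnitude response `1 / (1 + g(f)^(2 * order))`, and truncated.

This deliberately differs from a time-domain `filtfilt` with a bilinear-
transform digital filter. The bilinear transform warps the frequency axis,
so a digital two-pass order-2 low-pass at 0.2 Hz has gain about 0.02 at
0.4 Hz, while the analog magnitude response — which is what the filter
specification describes — has gain exactly `1/17 ≈ 0.0588` there and exactly
`0.5` at the cutoff. The frequency-domain implementation reproduces the
analog magnitude at every frequency, has exactly zero phase, and is
vectorized across columns.

## Censoring thresholds

* **LPF-FD / Notch-FD:** flag frames with FD above a threshold `phi_F` (mm).
* **GEV-DV:** DV distributions differ across runs, so a single DV threshold
  is inequitable. `fit_gev()` fits a generalized extreme value distribution
  to each run's DV values (dropping frame 1) by maximum likelihood
  (probability-weighted-moment start, Nelder–Mead refinement). The flagged
  tail mass is `q = (k + 0.3) / d_G`, clamped to [0, 1], where `k` is the
  fitted shape: heavier-tailed (more corrupted) runs are censored more at
  the same `d_G`. The run's threshold is the GEV quantile at `1 - q`. A
  non-converged fit falls back to the empirical quantile with `k = 0`, with
  a warning counted in diagnostics.
* **Combined:** union of the LPF-FD and GEV-DV masks, with the two
  parameters tied by a fixed ratio `phi_F / d_G` during optimization.

Runs with fewer than 167 surviving frames (2 minutes at TR = 0.72 s) are
excluded; subjects retaining at least one run stay in the sample
(`apply_exclusion()`).

## RSFC pipeline

`rsfc_pipeline()` reproduces a standard partial-correlation pipeline in this
order, per run:

1. mode-1000 normalization (`mode1000_normalize()`),
2. demean/detrend (least-squares linear),
3. linear interpolation across censored frames (edges held at the nearest
   kept frame) so filtering does not smear artifact into kept frames,
4. 0.009–0.08 Hz band-pass (the same zero-phase filter),
5. removal of 30 frames at each edge (filter transients),
6. removal of censored frames,
7. partial correlation of each ROI pair given a nuisance design: intercept,
   the filtered motion parameters, their squares, derivatives, and squared
   derivatives (24 columns), white matter and CSF plus derivatives, and
   optionally the global signal plus derivative (29 or 31 columns),
8. Fisher z transform, then unweighted averaging over the subject's runs.

Nuisance derivatives are computed on the full-length filtered series before
the trimming window, so windowing does not bias the derivative estimate at
window edges. Collinear design columns raise an error naming the columns.

## Evaluating censoring: MAC-RSFC

Whether censoring *changed* anything must be judged against removing the
same number of frames at random. For each run, `delta_z()` computes the
Fisher-z RSFC under the targeted mask and under `n_rand = 10`
count-matched random masks, each through the identical pipeline
(re-interpolating, re-filtering, re-trimming). The per-run effect is the
mean over permutations of (targeted minus random) — averaging differences
rather than differencing averages, so identical masks give exactly zero.
`mac_rsfc()` is the mean absolute value of the subject-level effects, with a
bias-corrected and accelerated (BCa) bootstrap interval over subjects
(hand-rolled: resampling, bias correction from the bootstrap CDF at the
point estimate, jackknife acceleration).

## Choosing the threshold: delta-MSE-RSFC

`sweep_censoring()` sweeps percent-removed targets (default 0–100% in 0.5%
steps), realized as pooled-statistic quantiles for LPF-FD and by root
finding on the log parameter for GEV-DV and combined censoring. At each
grid point it records, per ROI pair: the change in bias relative to random
censoring (delta-bias, always the negative of an absolute value), the
across-subject variance, and the surviving subject count `N_S`.

The unobservable uncensored bias is extrapolated by
`estimate_uncensored_bias()`: per pair, a robust slope through the origin of
negative delta-bias against percent removed (IRLS, bisquare weights with
tuning constant 4.685, OLS start, MAD scale, 50 iterations; OLS fallback is
flagged). `delta_mse()` then assembles, per pair and grid point,

* censored squared bias: `(bias_u + delta_bias)^2` (Eqs. 11–12 style
  update), and
* `delta_mse = (var_c + bias_c^2) / N_S - (var_u + bias_u^2) / N_SU`,

averaged over pairs. When `bias_u + delta_bias < 0` (censoring "overshoots"
the estimated bias) the squared term is kept as computed — the estimator
has no clamping rule — and the occurrences are counted in diagnostics.
`optimize_single()` takes the curve minimum inside the 0–80% search range
and inverse-interpolates the percent-to-parameter map. The inverse
interpolation runs on the *reciprocal* of the parameter: the no-censoring
knot carries an infinite threshold, where linear interpolation on the raw
scale is undefined (Inf − Inf), while `1/parameter` passes smoothly
through zero.

Curve values are resampled to a 0.01% grid: delta-bias and variance
linearly, subject counts piecewise-constant (they are integers that change
only at realized knots).

```{r optimize}
opt <- optimize_censoring(dataset, method = "lpf-fd")
opt$percent_removed   # optimal percent of frames removed
opt$parameter         # the LPF-FD threshold realizing it
```

## Classic data-quality metrics, and why they are confounded

`qcfc()` and friends implement the QC-FC family: per-pair correlation of
RSFC with a subject quality measure, BH-FDR rejection rates, QC-FC–distance
correlations, high–low motion tercile tests, and two-step GLM summaries.
They are provided for comparison, not endorsement: a cohort in which a
latent trait raises both true connectivity and motion severity
(`simulate_confounded_cohort()`) produces QC-FC "failures" with *zero*
artifact in the data, while MAC-RSFC comparisons between interchangeable
censoring methods remain null. The test suite reproduces this
qualitatively.

## The synthetic generator: realism and limits

`simulate_dataset()` generates per-run motion as slow AR(1)-velocity drift,
a respiratory waveform (`sin(phase) + 0.5 cos(2 phase)`, mildly asymmetric
so the FD spectrum keeps its line at the respiratory frequency) on the
phase-encode translation axis, and sparse spikes. ROI series are a
multivariate Gaussian draw with known network covariance plus white noise;
`ground_truth_z` stores the Fisher z of the implied observed-data
correlation, the simulation ground truth for truth-referenced MSE.

With `artifact_coupling > 0` the run's standard-FD series, convolved with a
6 s exponential kernel, is added to every ROI with spatially smooth loadings
that decay with distance from the ROI cloud centroid — injecting the
distance-dependent artifact the method is designed to remove. Two scaling
facts matter when choosing the coupling for an experiment:

* FD in this generator is ~0.05 mm, so the injected artifact amplitude is
  roughly `artifact_coupling / 20` signal standard deviations;
* the respiratory component of the artifact lies outside the 0.009–0.08 Hz
  band and the smooth drift component is removed by detrending, so only the
  spike-locked, in-band component is *censorable*.

Consequently small couplings produce data in which censoring cannot help
(the variance cost exceeds the removable bias), which is itself a correct
and useful regime for null testing. The WM/CSF nuisance series are
artifact-free noise by design: if they shared the gray-matter artifact time
course, nuisance regression would remove the injected artifact and no
censoring experiment would be informative.

Known limits: white (rather than 1/f) neural signal, linear artifact
injection, no spatial structure beyond ROI loadings, no true multiband
reconstruction physics.

## Reproducibility

Every stochastic step derives its seed deterministically from a master seed
and the (subject, run, permutation) indices; all derived seeds stay below
2^31. Functions that use the RNG save and restore the caller's RNG state.
`run_demo()` and `run_pipeline()` embed a config hash and the seed in every
output table, and rerunning with the same config and seed reproduces
byte-identical tables.
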