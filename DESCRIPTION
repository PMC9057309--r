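Package: mbcensor
Title: Volume Censoring and Censoring-Parameter Optimization for Multiband
    Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Motion denoising of multiband (fast-TR) resting-state fMRI by
    volume censoring. Implements low-pass-filtered and band-stop-filtered
    framewise displacement (LPF-FD, Notch-FD) and DVARS (LPF-DV, Notch-DV),
    run-adaptive DVARS thresholds from generalized extreme value fits
    (GEV-DV), a partial-correlation resting-state functional connectivity
    (RSFC) pipeline with nuisance regression and Fisher z transformation,
    the classic QC-FC family of data-quality metrics, and two
    censoring-evaluation metrics: MAC-RSFC (mean absolute change in RSFC
    relative to count-matched random censoring, with BCa bootstrap
    confidence intervals) and delta-MSE-RSFC (a bias-variance decomposition
    of the error in group-mean RSFC estimates, used to optimize censoring
    parameters). A synthetic multiband dataset generator with known network
    covariance and motion-coupled artifact makes the full pipeline testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
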