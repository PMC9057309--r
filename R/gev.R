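#' Generalized extreme value (GEV) distribution
#'
#' Density, distribution, quantile and random generation for the GEV
#' distribution with location `mu`, scale `sigma` and shape `k`. The shape
#' convention matches common maximum-likelihood tooling (MATLAB `fitdist`,
#' scipy with negated `c`): `k > 0` gives a heavy right tail (Frechet type),
#' `k = 0` the Gumbel limit, `k < 0` a bounded right tail (Weibull type).
#'
#' @param x,q numeric vector of quantiles.
#' @param p numeric vector of probabilities.
#' @param n number of draws.
#' @param k shape parameter.
#' @param sigma scale parameter (> 0).
#' @param mu location parameter.
#' @param log return log density.
#' @name gev
NULL

#' @rdname gev
#' @export
dgev <- function(x, k, sigma, mu, log = FALSE) {
  stopifnot(sigma > 0)
  z <- 1 + k * (x - mu) / sigma
  ld <- rep(-Inf, length(x))
  if (abs(k) < 1e-12) {
    w <- (x - mu) / sigma
    ld <- -log(sigma) - w - exp(-w)
  } else {
    ok <- z > 0
    ld[ok] <- -log(sigma) - (1 + 1 / k) * log(z[ok]) - z[ok]^(-1 / k)
  }
  if (log) ld else exp(ld)
}

#' @rdname gev
#' @export
pgev <- function(q, k, sigma, mu) {
  stopifnot(sigma > 0)
  z <- 1 + k * (q - mu) / sigma
  if (abs(k) < 1e-12) return(exp(-exp(-(q - mu) / sigma)))
  out <- ifelse(z > 0, exp(-pmax(z, 0)^(-1 / k)), if (k > 0) 0 else 1)
  out
}

#' @rdname gev
#' @export
qgev <- function(p, k, sigma, mu) {
  stopifnot(sigma > 0, all(p >= 0 & p <= 1))
  if (abs(k) < 1e-12) return(mu - sigma * log(-log(p)))
  mu + sigma * ((-log(p))^(-k) - 1) / k
}

#' @rdname gev
#' @export
rgev <- function(n, k, sigma, mu) qgev(runif(n), k, sigma, mu)

# Probability-weighted-moment starting values (Hosking, Wallis & Wood 1985),
# translated to the k-positive-heavy-tail sign convention used here.
gev_pwm <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((j - 1) / (n - 1) * x) / n
  b2 <- sum((j - 1) * (j - 2) / ((n - 1) * (n - 2)) * x) / n
  cc <- (2 * b1 - b0) / (3 * b2 - b0) - log(2) / log(3)
  kH <- 7.8590 * cc + 2.9554 * cc^2
  if (abs(kH) < 1e-8) kH <- 1e-8
  g <- gamma(1 + kH)
  sigma <- (2 * b1 - b0) * kH / (g * (1 - 2^(-kH)))
  mu <- b0 + sigma * (g - 1) / kH
  if (!is.finite(sigma) || sigma <= 0) sigma <- sd(x)
  if (!is.finite(mu)) mu <- mean(x)
  c(k = -kH, sigma = sigma, mu = mu)
}

gev_nll <- function(par, x) {
  k <- par[1]; sigma <- exp(par[2]); mu <- par[3]
  z <- 1 + k * (x - mu) / sigma
  if (sigma <= 0 || any(z <= 1e-12)) return(1e10)
  if (abs(k) < 1e-12) {
    w <- (x - mu) / sigma
    sum(log(sigma) + w + exp(-w))
  } else {
    sum(log(sigma) + (1 + 1 / k) * log(z) + z^(-1 / k))
  }
}

#' Fit a GEV distribution by maximum likelihood
#'
#' Used by GEV-DV censoring to model the within-run distribution of LPF-DV
#' values. Starting values come from probability-weighted moments; the
#' negative log-likelihood is then minimized by Nelder--Mead on
#' `(k, log sigma, mu)` (relative tolerance 1e-8), with a Gumbel-anchored
#' restart if the first attempt fails. The first frame of a framewise series
#' (0 by convention) should be excluded by the caller; [gev_dv_threshold()]
#' and the pipeline drivers do this.
#'
#' @param x numeric vector of observations (>= 50 finite values).
#' @return object of class `"gev_fit"`: list with `k`, `sigma`, `mu`, `n`,
#'   `converged`, `loglik`.
#' @export
fit_gev <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 50)
    stop("fit_gev needs at least 50 finite values, got ", length(x))
  start <- gev_pwm(x)
  par0 <- c(start["k"], log(start["sigma"]), start["mu"])
  opt <- optim(par0, gev_nll, x = x, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-10))
  if (opt$convergence != 0 || opt$value >= 1e10) {
    # fallback initialization: Gumbel moments
    par1 <- c(0, log(sd(x) * sqrt(6) / pi), mean(x) - 0.5772 * sd(x) * sqrt(6) / pi)
    opt2 <- optim(par1, gev_nll, x = x, method = "Nelder-Mead",
                  control = list(maxit = 3000, reltol = 1e-10))
    if (opt2$value < opt$value) opt <- opt2
  }
  structure(list(k = unname(opt$par[1]), sigma = unname(exp(opt$par[2])),
                 mu = unname(opt$par[3]), n = length(x),
                 converged = opt$convergence == 0 && opt$value < 1e10,
                 loglik = -opt$value),
            class = "gev_fit")
}

#' @export
print.gev_fit <- function(x, ...) {
  cat(sprintf("GEV fit (n = %d): k = %.4f, sigma = %.4f, mu = %.4f%s\n",
              x$n, x$k, x$sigma, x$mu,
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' Run-adaptive DV censoring threshold from a GEV fit
#'
#' Converts a within-run GEV fit of LPF-DV values into a censoring threshold:
#' the tail mass to the right of the threshold is set to
#' `q = (k + 0.3) / d_G`, clamped to `[0, 1]`, so runs with heavier right
#' tails (larger shape `k`, i.e. more extreme DV excursions) lose a larger
#' fraction of frames. The `+0.3` floor keeps the tail mass non-negative for
#' any plausible shape; `d_G` is the single dataset-wide aggressiveness
#' parameter (larger `d_G` = more lenient).
#'
#' @param fit a [fit_gev()] result.
#' @param d_G positive tuning parameter.
#' @param dv optional numeric vector of the run's DV values; required as an
#'   empirical fallback when the fit did not converge (the threshold is then
#'   the empirical quantile at `1 - 0.3 / d_G`, i.e. with `k` treated as 0,
#'   and a warning is issued).
#' @return the DV threshold (`phi_D`); `Inf` when the tail mass is 0 (no
#'   censoring), `-Inf` when it is 1 (censor everything).
#' @export
gev_dv_threshold <- function(fit, d_G, dv = NULL) {
  stopifnot(inherits(fit, "gev_fit"), d_G > 0)
  if (!fit$converged) {
    if (is.null(dv))
      stop("GEV fit did not converge and no empirical DV values supplied")
    q <- min(max(0.3 / d_G, 0), 1)
    warning("GEV fit not converged; falling back to empirical quantile with k = 0")
    if (q <= 0) return(Inf)
    if (q >= 1) return(-Inf)
    return(unname(quantile(dv[is.finite(dv)], 1 - q)))
  }
  q <- min(max((fit$k + 0.3) / d_G, 0), 1)
  if (q <= 0) return(Inf)
  if (q >= 1) return(-Inf)
  qgev(1 - q, fit$k, fit$sigma, fit$mu)
}
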