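#' Distribution specification for an uncertain parameter
#'
#' A `dist_spec` describes the second-order uncertainty of one model
#' parameter as a distribution family plus its mean and standard error, the
#' form in which health-economic parameter tables are usually published.
#' Probabilistic sensitivity analysis draws are generated from the
#' method-of-moments fit of the named family (see [fit_beta_moments()],
#' [fit_gamma_moments()], [fit_lognormal_moments()]).
#'
#' Families:
#' * `"beta"` — proportions; requires `0 <= mean <= 1` and
#'   `se^2 < mean * (1 - mean)` (moment-fit feasibility).
#' * `"gamma"` — nonnegative costs; requires `mean > 0`.
#' * `"lognormal"` — positive skewed quantities (days, per-leave costs);
#'   requires `mean > 0`.
#' * `"dirichlet_row"` — reserved for joint row uncertainty of transition
#'   probabilities (see [draw_parameters()]).
#' * `"fixed"` — a point estimate; `se` is ignored and stored as 0.
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"dirichlet_row"`, `"fixed"`.
#' @param mean Parameter mean (a proportion for beta; USD or days otherwise).
#' @param se Standard error on the same scale as `mean`.
#' @return An object of class `"dist_spec"`: a list with elements `family`,
#'   `mean`, `se`.
#' @examples
#' dist_spec("beta", 0.099, 0.0819)   # all-MSKD moderate prevalence
#' dist_spec("gamma", 14.55, 14.26)   # monthly anxiety cost, USD
#' @export
dist_spec <- function(family = c("beta", "gamma", "lognormal",
                                 "dirichlet_row", "fixed"),
                      mean, se = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(se), length(se) == 1L, is.finite(se))
  if (mean < 0 && family != "fixed")
    stop("dist_spec: mean must be nonnegative, got ", mean)
  if (se < 0) stop("dist_spec: se must be nonnegative, got ", se)
  if (family == "fixed") se <- 0
  if (family == "beta") {
    if (mean < 0 || mean > 1)
      stop("dist_spec: beta mean must lie in [0, 1], got ", mean)
    if (se > 0 && se^2 >= mean * (1 - mean))
      stop("dist_spec: beta moment infeasibility, se^2 = ", se^2,
           " >= mean*(1-mean) = ", mean * (1 - mean))
  }
  if (family %in% c("gamma", "lognormal") && mean <= 0)
    stop("dist_spec: ", family, " requires mean > 0, got ", mean)
  structure(list(family = family, mean = mean, se = se),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(mean = %g, se = %g)\n", x$family, x$mean, x$se))
  invisible(x)
}

is_dist_spec <- function(x) inherits(x, "dist_spec")

#' Method-of-moments fit of a beta distribution
#'
#' Solves for the shape parameters of a Beta(alpha, beta) distribution whose
#' mean and standard deviation equal the supplied values, using
#' `nu = mean * (1 - mean) / se^2 - 1`, `alpha = mean * nu`,
#' `beta = (1 - mean) * nu`.
#'
#' @param mean Mean, strictly inside (0, 1).
#' @param se Standard error; must satisfy `0 < se^2 < mean * (1 - mean)`.
#' @return Named numeric vector with elements `alpha` and `beta`.
#' @examples
#' fit_beta_moments(0.5, 0.05)  # alpha = beta = 49.5
#' @export
fit_beta_moments <- function(mean, se) {
  if (!is.numeric(mean) || mean <= 0 || mean >= 1)
    stop("fit_beta_moments: mean must lie strictly in (0, 1), got ", mean)
  if (!is.numeric(se) || se <= 0)
    stop("fit_beta_moments: se must be positive, got ", se)
  if (se^2 >= mean * (1 - mean))
    stop("fit_beta_moments: infeasible se: se^2 = ", se^2,
         " >= mean*(1-mean) = ", mean * (1 - mean))
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments fit of a gamma distribution
#'
#' `shape = mean^2 / se^2`, `rate = mean / se^2`, so the fitted
#' Gamma(shape, rate) has exactly the supplied mean and standard deviation.
#' `mean == se` gives `shape = 1`, i.e. an exponential.
#'
#' @param mean Positive mean (e.g. USD).
#' @param se Positive standard error.
#' @return Named numeric vector with elements `shape` and `rate`.
#' @examples
#' fit_gamma_moments(14.55, 14.26)
#' @export
fit_gamma_moments <- function(mean, se) {
  if (!is.numeric(mean) || mean <= 0)
    stop("fit_gamma_moments: mean must be positive, got ", mean)
  if (!is.numeric(se) || se <= 0)
    stop("fit_gamma_moments: se must be positive, got ", se)
  c(shape = mean^2 / se^2, rate = mean / se^2)
}

#' Method-of-moments fit of a lognormal distribution
#'
#' `sigma^2 = log(1 + se^2 / mean^2)`, `mu = log(mean) - sigma^2 / 2`; the
#' fitted distribution's arithmetic mean and standard deviation equal the
#' inputs. As `se -> 0` the fit degenerates to a point mass at `mean`.
#'
#' @param mean Positive mean.
#' @param se Nonnegative standard error.
#' @return Named numeric vector with elements `mu` (log-scale mean) and
#'   `sigma` (log-scale sd).
#' @examples
#' fit_lognormal_moments(265.69, 0.42)
#' @export
fit_lognormal_moments <- function(mean, se) {
  if (!is.numeric(mean) || mean <= 0)
    stop("fit_lognormal_moments: mean must be positive, got ", mean)
  if (!is.numeric(se) || se < 0)
    stop("fit_lognormal_moments: se must be nonnegative, got ", se)
  sigma2 <- log(1 + se^2 / mean^2)
  c(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Draw random variates from a distribution specification
#'
#' Samples `n` independent draws from the method-of-moments fit of `spec`.
#' `fixed` specs (and any spec with `se == 0`) return the mean repeated.
#' Draws consume the current RNG stream; seed management for the PSA lives
#' in [run_psa()].
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n = 1L) {
  stopifnot(is_dist_spec(spec), n >= 0)
  if (spec$family == "fixed" || spec$se == 0) return(rep(spec$mean, n))
  switch(spec$family,
    beta = {
      p <- fit_beta_moments(spec$mean, spec$se)
      stats::rbeta(n, p[["alpha"]], p[["beta"]])
    },
    gamma = {
      p <- fit_gamma_moments(spec$mean, spec$se)
      stats::rgamma(n, shape = p[["shape"]], rate = p[["rate"]])
    },
    lognormal = {
      p <- fit_lognormal_moments(spec$mean, spec$se)
      stats::rlnorm(n, meanlog = p[["mu"]], sdlog = p[["sigma"]])
    },
    stop("draw_dist: no sampler for family ", spec$family)
  )
}

# Analytic mean/sd of the fitted distribution; used to verify round-trips.
dist_moments <- function(spec) {
  if (spec$family == "fixed" || spec$se == 0)
    return(c(mean = spec$mean, sd = 0))
  switch(spec$family,
    beta = {
      p <- fit_beta_moments(spec$mean, spec$se)
      a <- p[["alpha"]]; b <- p[["beta"]]
      c(mean = a / (a + b),
        sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = {
      p <- fit_gamma_moments(spec$mean, spec$se)
      c(mean = p[["shape"]] / p[["rate"]],
        sd = sqrt(p[["shape"]]) / p[["rate"]])
    },
    lognormal = {
      p <- fit_lognormal_moments(spec$mean, spec$se)
      m <- exp(p[["mu"]] + p[["sigma"]]^2 / 2)
      c(mean = m, sd = m * sqrt(exp(p[["sigma"]]^2) - 1))
    },
    stop("dist_moments: no moments for family ", spec$family)
  )
}
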