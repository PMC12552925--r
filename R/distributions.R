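#' Distribution specification for a model input
#'
#' A `dist_spec` captures how an input parameter is represented in the
#' probabilistic analysis: a distribution family (`beta`, `gamma`, `lognormal`
#' or `fixed`), the published point estimate, the 95% uncertainty interval it
#' was fitted from, and the fitted family-specific shape parameters.
#'
#' Probability and utility parameters are given beta distributions, costs gamma
#' distributions, and hazard ratios lognormal distributions; parameters without
#' quantified uncertainty are `fixed` and always reproduce their point
#' estimate.
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param point_estimate Published point estimate (probability, utility, 2023
#'   USD cost, or hazard ratio).
#' @param ui_low,ui_high 95% uncertainty interval bounds on the same scale as
#'   the point estimate (`NA` when none was published).
#' @param shape Named list of fitted shape parameters (family-specific).
#' @return An object of class `dist_spec`.
#' @seealso [fit_beta()], [fit_gamma()], [fit_lognormal()]
#' @export
dist_spec <- function(family, point_estimate, ui_low = NA_real_,
                      ui_high = NA_real_, shape = list()) {
  family <- match.arg(family, c("beta", "gamma", "lognormal", "fixed"))
  stopifnot(is.numeric(point_estimate), length(point_estimate) == 1L)
  if (!is.na(ui_low) && !is.na(ui_high)) {
    if (!(ui_low <= point_estimate && point_estimate <= ui_high)) {
      stop("uncertainty interval [", ui_low, ", ", ui_high,
           "] does not bracket the point estimate ", point_estimate)
    }
  }
  structure(
    list(family = family, point_estimate = point_estimate,
         ui_low = ui_low, ui_high = ui_high, shape = shape),
    class = "dist_spec"
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  sh <- if (length(x$shape)) {
    paste(names(x$shape), signif(unlist(x$shape), 5), sep = "=", collapse = ", ")
  } else "none"
  cat(sprintf("<dist_spec %s> point=%g UI=(%g, %g) shape: %s\n",
              x$family, x$point_estimate, x$ui_low, x$ui_high, sh))
  invisible(x)
}

# Normal-approximation sd implied by a 95% interval.
.ui_sd <- function(ui_low, ui_high) (ui_high - ui_low) / (2 * stats::qnorm(0.975))

#' Fit a beta distribution from a point estimate and 95% interval
#'
#' Method-of-moments fit: the interval width gives `sd = (hi - lo)/(2 * 1.96)`
#' and the shape parameters are `alpha = mean * k`, `beta = (1 - mean) * k`
#' with `k = mean * (1 - mean) / sd^2 - 1`. A zero-width interval yields a
#' degenerate `fixed` spec. An interval too wide to be consistent with a beta
#' distribution (implied `k <= 0`) is rejected.
#'
#' @param mean Point estimate in (0, 1).
#' @param ui_low,ui_high 95% uncertainty interval bounds in \[0, 1\].
#' @return A [dist_spec()] with `family = "beta"` (or `"fixed"` when the
#'   interval is degenerate).
#' @examples
#' fit_beta(0.7512, 0.7105, 0.7880) # detection probability, base case
#' @export
fit_beta <- function(mean, ui_low, ui_high) {
  stopifnot(mean > 0, mean < 1, ui_low <= mean, mean <= ui_high,
            ui_low >= 0, ui_high <= 1)
  sd <- .ui_sd(ui_low, ui_high)
  if (sd == 0) {
    return(dist_spec("fixed", mean, ui_low, ui_high))
  }
  k <- mean * (1 - mean) / sd^2 - 1
  if (k <= 0) {
    stop("interval (", ui_low, ", ", ui_high, ") is too wide for a beta ",
         "distribution with mean ", mean, " (implied concentration k = ",
         signif(k, 4), " <= 0)")
  }
  dist_spec("beta", mean, ui_low, ui_high,
            shape = list(alpha = mean * k, beta = (1 - mean) * k))
}

#' Fit a gamma distribution for a cost parameter
#'
#' When an uncertainty interval is published, `sd = (hi - lo)/(2 * 1.96)`;
#' otherwise the default coefficient of variation (20%, reflecting the assumed
#' cost uncertainty) supplies `sd = default_cv * mean`. Moment matching gives
#' `shape = mean^2/sd^2`, `scale = sd^2/mean`.
#'
#' @param mean Point estimate (> 0), 2023 USD.
#' @param ui_low,ui_high Optional 95% interval bounds; `NA` to use the CV rule.
#' @param default_cv Coefficient of variation used when no interval is given.
#' @return A [dist_spec()] with `family = "gamma"` (scale parameterisation),
#'   or `"fixed"` when the implied sd is zero.
#' @examples
#' fit_gamma(1898)                 # 20% CV rule: shape 25, scale 75.92
#' fit_gamma(1898, 1242, 2727)     # interval-based fit
#' @export
fit_gamma <- function(mean, ui_low = NA_real_, ui_high = NA_real_,
                      default_cv = 0.20) {
  stopifnot(mean > 0)
  sd <- if (!is.na(ui_low) && !is.na(ui_high)) {
    stopifnot(ui_low <= mean, mean <= ui_high, ui_low >= 0)
    .ui_sd(ui_low, ui_high)
  } else {
    default_cv * mean
  }
  if (sd == 0) {
    return(dist_spec("fixed", mean, ui_low, ui_high))
  }
  dist_spec("gamma", mean, ui_low, ui_high,
            shape = list(shape = mean^2 / sd^2, scale = sd^2 / mean))
}

#' Fit a lognormal distribution for a hazard ratio
#'
#' The fit anchors the median at the published point estimate
#' (`meanlog = log(point)`) and takes the log-scale sd from the interval
#' width: `sdlog = (log(hi) - log(lo))/(2 * 1.96)`. Published hazard-ratio
#' intervals are not always log-symmetric about the point estimate; the fit
#' uses the log-width regardless and keeps the median anchored.
#'
#' @param point Point estimate (> 0), a hazard ratio.
#' @param ui_low,ui_high 95% interval bounds (> 0).
#' @return A [dist_spec()] with `family = "lognormal"`, or `"fixed"` for a
#'   degenerate interval.
#' @examples
#' fit_lognormal(0.56, 0.49, 0.92) # early- vs delayed-treatment progression HR
#' @export
fit_lognormal <- function(point, ui_low, ui_high) {
  stopifnot(point > 0, ui_low > 0, ui_high > 0,
            ui_low <= point, point <= ui_high)
  sdlog <- (log(ui_high) - log(ui_low)) / (2 * stats::qnorm(0.975))
  if (sdlog == 0) {
    return(dist_spec("fixed", point, ui_low, ui_high))
  }
  dist_spec("lognormal", point, ui_low, ui_high,
            shape = list(meanlog = log(point), sdlog = sdlog))
}

#' Draw random samples from a fitted distribution spec
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Fixed specs repeat the point
#'   estimate. Uses the current RNG state (seed management happens in
#'   [sample_parameters()]).
#' @export
draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"), n >= 1)
  switch(spec$family,
    fixed     = rep(spec$point_estimate, n),
    beta      = stats::rbeta(n, spec$shape$alpha, spec$shape$beta),
    gamma     = stats::rgamma(n, shape = spec$shape$shape,
                              scale = spec$shape$scale),
    lognormal = stats::rlnorm(n, meanlog = spec$shape$meanlog,
                              sdlog = spec$shape$sdlog)
  )
}

# Fit the right family given a table row. family == "beta" with no UI is an
# error except when the value is meant to be fixed.
.fit_from_row <- function(family, mean, ui_low, ui_high) {
  have_ui <- !is.na(ui_low) && !is.na(ui_high)
  switch(family,
    fixed = dist_spec("fixed", mean, ui_low, ui_high),
    beta = {
      if (!have_ui) stop("beta parameter needs an uncertainty interval")
      fit_beta(mean, ui_low, ui_high)
    },
    gamma = if (have_ui) fit_gamma(mean, ui_low, ui_high) else fit_gamma(mean),
    lognormal = {
      if (!have_ui) stop("lognormal parameter needs an uncertainty interval")
      fit_lognormal(mean, ui_low, ui_high)
    },
    stop("unknown distribution family: ", family)
  )
}
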