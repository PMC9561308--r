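#' Parametric survival laws
#'
#' A `parametric_survival` object is a fully specified survival law
#' `S(t)` on a time axis measured in months. Six families are supported;
#' the work-horse is the log-logistic law
#' \deqn{S(t) = 1 / (1 + \lambda t^\gamma)}
#' with scale \eqn{\lambda > 0} and shape \eqn{\gamma > 0}, the form in
#' which progression-free and overall survival are parameterised
#' throughout this package. The remaining families use conventional
#' parameterisations (see Details).
#'
#' @details
#' Family-specific meaning of `shape` and `scale`:
#' \describe{
#'   \item{loglogistic}{`shape` = \eqn{\gamma}, `scale` = \eqn{\lambda}
#'     in \eqn{S(t) = 1/(1+\lambda t^\gamma)}. Note this differs from
#'     [flexsurv::pllogis()], whose scale \eqn{b} relates to ours by
#'     \eqn{\lambda = b^{-\gamma}}.}
#'   \item{weibull}{`shape` and `scale` as in [stats::pweibull()]:
#'     \eqn{S(t) = \exp(-(t/scale)^{shape})}.}
#'   \item{lognormal}{`scale` = median \eqn{\exp(\mu)}, `shape` =
#'     \eqn{\sigma} (sdlog); both positive.}
#'   \item{gompertz}{`shape` = \eqn{a} (may be negative, in which case
#'     the law is improper with a surviving fraction), `scale` = rate
#'     \eqn{b > 0}: \eqn{S(t) = \exp(-b/a\,(e^{at}-1))}.}
#'   \item{exponential}{`scale` = rate \eqn{\lambda}; `shape` is fixed
#'     at 1 and carries no information (the family has one parameter).}
#'   \item{gamma}{`shape` and `scale` = rate as in
#'     [stats::pgamma()]'s `shape`/`rate`.}
#' }
#'
#' @param family One of `"loglogistic"`, `"weibull"`, `"lognormal"`,
#'   `"gompertz"`, `"exponential"`, `"gamma"`.
#' @param shape,scale Family-specific parameters (see Details).
#' @return An object of class `parametric_survival`.
#' @examples
#' lp_os <- parametric_survival("loglogistic", shape = 1.5396, scale = 0.01375)
#' survival_prob(lp_os, c(0, 6, 12, 24))
#' median_time(lp_os)
#' @export
parametric_survival <- function(family, shape, scale) {
  family <- match.arg(family, surv_families())
  stopifnot(is.numeric(shape), length(shape) == 1L, is.finite(shape),
            is.numeric(scale), length(scale) == 1L, is.finite(scale))
  if (family == "exponential") shape <- 1
  if (scale <= 0)
    stop("'scale' must be positive for family '", family, "'")
  if (shape <= 0 && family != "gompertz")
    stop("'shape' must be positive for family '", family, "'")
  if (family == "gompertz" && shape == 0)
    stop("gompertz 'shape' must be non-zero; use the exponential family instead")
  structure(list(family = family, shape = shape, scale = scale,
                 time_unit = "months"),
            class = "parametric_survival")
}

#' Supported survival families
#'
#' Enumerates the six parametric families in their canonical order,
#' which is also the final tie-break order used by [select_model()].
#' @return Character vector of family names.
#' @export
surv_families <- function() {
  c("loglogistic", "weibull", "lognormal", "gompertz", "exponential", "gamma")
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("<parametric_survival> %s (shape = %g, scale = %g, time in %s)\n",
              x$family, x$shape, x$scale, x$time_unit))
  cat(sprintf("  median survival: %.3f months\n", median_time(x)))
  invisible(x)
}

stopifnot_model <- function(model) {
  if (!inherits(model, "parametric_survival"))
    stop("expected a 'parametric_survival' object")
}

#' Survival probability S(t)
#'
#' @param model A [parametric_survival()] object.
#' @param t Time(s) in months, non-negative.
#' @return `S(t)`, a probability in `[0, 1]`, vectorised over `t`.
#' @export
survival_prob <- function(model, t) {
  stopifnot_model(model)
  if (any(!is.finite(t) | t < 0)) stop("'t' must be finite and >= 0")
  sh <- model$shape; sc <- model$scale
  switch(model$family,
    loglogistic = 1 / (1 + sc * t^sh),
    weibull     = stats::pweibull(t, sh, sc, lower.tail = FALSE),
    lognormal   = stats::plnorm(t, log(sc), sh, lower.tail = FALSE),
    gompertz    = exp(-sc / sh * (exp(sh * t) - 1)),
    exponential = exp(-sc * t),
    gamma       = stats::pgamma(t, sh, rate = sc, lower.tail = FALSE)
  )
}

#' Event-time density f(t)
#'
#' @inheritParams survival_prob
#' @return Density values, vectorised over `t`.
#' @export
survival_dens <- function(model, t) {
  stopifnot_model(model)
  if (any(!is.finite(t) | t < 0)) stop("'t' must be finite and >= 0")
  sh <- model$shape; sc <- model$scale
  switch(model$family,
    loglogistic = sc * sh * t^(sh - 1) / (1 + sc * t^sh)^2,
    weibull     = stats::dweibull(t, sh, sc),
    lognormal   = stats::dlnorm(t, log(sc), sh),
    gompertz    = sc * exp(sh * t) * exp(-sc / sh * (exp(sh * t) - 1)),
    exponential = sc * exp(-sc * t),
    gamma       = stats::dgamma(t, sh, rate = sc)
  )
}

#' Survival quantile (inverse CDF of the event time)
#'
#' Returns the time `t` at which the cumulative event probability
#' reaches `p`, i.e. `S(t) = 1 - p`.
#'
#' @inheritParams survival_prob
#' @param p Cumulative event probability in `[0, 1)`.
#' @return Time in months.
#' @export
survival_quantile <- function(model, p) {
  stopifnot_model(model)
  if (any(p < 0 | p >= 1)) stop("'p' must be in [0, 1)")
  sh <- model$shape; sc <- model$scale
  switch(model$family,
    loglogistic = (p / ((1 - p) * sc))^(1 / sh),
    weibull     = stats::qweibull(p, sh, sc),
    lognormal   = stats::qlnorm(p, log(sc), sh),
    gompertz    = {
      # improper for shape < 0: plateau at exp(scale/shape)
      arg <- 1 - sh / sc * log1p(-p)
      ifelse(arg > 0, log(arg) / sh, Inf)
    },
    exponential = stats::qexp(p, sc),
    gamma       = stats::qgamma(p, sh, rate = sc)
  )
}

#' Median survival time
#'
#' Closed-form where available; for the log-logistic law the median is
#' \eqn{(1/\lambda)^{1/\gamma}}, a convenient sanity check that the
#' time unit of a fitted or declared law is months.
#'
#' @inheritParams survival_prob
#' @return Median survival time in months.
#' @export
median_time <- function(model) {
  stopifnot_model(model)
  if (model$family == "loglogistic")
    return((1 / model$scale)^(1 / model$shape))
  survival_quantile(model, 0.5)
}

#' Draw random event times
#'
#' Inverse-CDF sampling from the law; used by the pseudo-IPD simulator.
#'
#' @inheritParams survival_prob
#' @param n Number of draws.
#' @return Vector of `n` event times in months.
#' @export
survival_rand <- function(model, n) {
  survival_quantile(model, stats::runif(n))
}
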