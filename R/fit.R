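#' Maximum-likelihood fit of a parametric survival family
#'
#' Fits one of the six supported families to right-censored records by
#' maximising the censored log-likelihood
#' \deqn{\ell = \sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i),}
#' via [flexsurv::flexsurvreg()], and reports the fit together with
#' AIC and BIC. The exponential family is fitted in closed form
#' (\eqn{\hat\lambda =} events / total follow-up time), which is its
#' exact MLE under right censoring.
#'
#' Fitted parameters are returned in this package's parameterisations
#' (see [parametric_survival()]); in particular log-logistic fits are
#' reported as \eqn{(\gamma, \lambda)} of \eqn{S(t)=1/(1+\lambda
#' t^\gamma)}.
#'
#' @param ipd A [pseudo_ipd()] with at least two observed events.
#' @param family A family name from [surv_families()].
#' @return A `fit_result` list: `model` ([parametric_survival()]),
#'   `log_likelihood`, `aic`, `bic`, `n` (records), `k` (parameters).
#' @examples
#' spec <- sim_spec(parametric_survival("loglogistic", 1.5396, 0.01375),
#'                  n = 300, seed = 7)
#' fit_parametric(generate_pseudo_ipd(spec), "loglogistic")
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, surv_families())
  if (!inherits(ipd, "pseudo_ipd")) ipd <- pseudo_ipd(ipd$time, ipd$event)
  n <- nrow(ipd)
  if (sum(ipd$event) < 2L) stop("need at least 2 observed events to fit")

  if (family == "exponential") {
    rate <- sum(ipd$event) / sum(ipd$time)
    model <- parametric_survival("exponential", 1, rate)
    ll <- sum(ipd$event) * log(rate) - rate * sum(ipd$time)
    return(new_fit_result(model, ll, n, k = 1L, data_id = ipd_id(ipd)))
  }

  dist <- c(loglogistic = "llogis", weibull = "weibull",
            lognormal = "lnorm", gompertz = "gompertz",
            gamma = "gamma")[[family]]
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(ipd), dist = dist),
    error = function(e) {
      stop("fit of family '", family, "' did not converge (n = ", n,
           ", events = ", sum(ipd$event), "): ", conditionMessage(e),
           call. = FALSE)
    })
  if (!is.null(fit$opt$convergence) && fit$opt$convergence != 0)
    stop("fit of family '", family, "' did not converge (optim code ",
         fit$opt$convergence, ")", call. = FALSE)
  est <- fit$res[, "est"]
  model <- switch(family,
    loglogistic = parametric_survival("loglogistic", est[["shape"]],
                                      est[["scale"]]^(-est[["shape"]])),
    weibull     = parametric_survival("weibull", est[["shape"]], est[["scale"]]),
    lognormal   = parametric_survival("lognormal", est[["sdlog"]],
                                      exp(est[["meanlog"]])),
    gompertz    = parametric_survival("gompertz", est[["shape"]], est[["rate"]]),
    gamma       = parametric_survival("gamma", est[["shape"]], est[["rate"]]))
  new_fit_result(model, fit$loglik, n, k = 2L, data_id = ipd_id(ipd))
}

new_fit_result <- function(model, log_likelihood, n, k, data_id) {
  structure(list(model = model,
                 log_likelihood = log_likelihood,
                 aic = 2 * k - 2 * log_likelihood,
                 bic = k * log(n) - 2 * log_likelihood,
                 n = n, k = k, data_id = data_id),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: shape = %.5g, scale = %.5g\n",
              x$model$family, x$model$shape, x$model$scale))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, BIC = %.3f (n = %d, k = %d)\n",
              x$log_likelihood, x$aic, x$bic, x$n, x$k))
  invisible(x)
}

#' Fit every supported family to the same records
#'
#' Families whose optimisation fails (e.g. a Gompertz fit on strongly
#' log-logistic data) are dropped with a warning rather than aborting
#' the comparison.
#'
#' @inheritParams fit_parametric
#' @param families Families to try; defaults to all six.
#' @return Named list of `fit_result` objects.
#' @export
fit_all_families <- function(ipd, families = surv_families()) {
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_parametric(ipd, fam), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits)) stop("no family could be fitted")
  fits
}

#' Select the best-fitting family
#'
#' Picks the candidate with the lowest AIC; ties are broken by lowest
#' BIC, then by the family order of [surv_families()]. All candidates
#' must have been fitted to the same records.
#'
#' @param fits A list of `fit_result` objects (e.g. from
#'   [fit_all_families()]).
#' @return The selected `fit_result`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "fit_result")) fits <- list(fits)
  if (!length(fits)) stop("'fits' must be a non-empty list")
  ok <- vapply(fits, inherits, logical(1), what = "fit_result")
  if (!all(ok)) stop("all candidates must be 'fit_result' objects")
  ids <- vapply(fits, `[[`, character(1), "data_id")
  if (length(unique(ids)) > 1L)
    stop("candidates were fitted to different datasets")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  fam <- match(vapply(fits, function(f) f$model$family, character(1)),
               surv_families())
  fits[[order(aic, bic, fam)[1L]]]
}

#' Fit-comparison table
#'
#' @param fits Named list of `fit_result` objects.
#' @return Data frame with one row per family, sorted by AIC.
#' @export
fit_table <- function(fits) {
  d <- do.call(rbind, lapply(fits, function(f)
    data.frame(family = f$model$family, shape = f$model$shape,
               scale = f$model$scale, log_likelihood = f$log_likelihood,
               aic = f$aic, bic = f$bic, n = f$n, k = f$k)))
  rownames(d) <- NULL
  d[order(d$aic), ]
}
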