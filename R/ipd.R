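#' Pseudo individual-patient data
#'
#' A `pseudo_ipd` object holds right-censored time-to-event records:
#' one row per subject with a positive time (months) and an event flag
#' (`TRUE` = death/progression observed, `FALSE` = right-censored).
#' These records are either simulated ([generate_pseudo_ipd()]) or
#' reconstructed from digitized survival-curve coordinates
#' ([reconstruct_ipd()]), and feed the parametric fitting stage.
#'
#' @param time Positive event/censoring times in months.
#' @param event Logical (or 0/1) event indicator.
#' @return A data frame of class `pseudo_ipd` with columns `time`,
#'   `event` (integer 0/1).
#' @examples
#' ipd <- pseudo_ipd(c(2.1, 3.5, 8), c(1, 0, 1))
#' km_estimate(ipd)
#' @export
pseudo_ipd <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1L)
  if (any(!is.finite(time) | time <= 0))
    stop("all times must be finite and > 0")
  event <- as.integer(as.logical(event))
  if (anyNA(event)) stop("'event' must be logical or 0/1")
  structure(data.frame(time = as.numeric(time), event = event),
            class = c("pseudo_ipd", "data.frame"))
}

#' Read / write pseudo-IPD as CSV
#'
#' The on-disk format is a plain CSV with columns `time` and `event`
#' (0/1).
#'
#' @param path File path.
#' @return `read_ipd()` returns a [pseudo_ipd()]; `write_ipd()` returns
#'   `path` invisibly.
#' @export
read_ipd <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "event") %in% names(d)))
    stop("IPD CSV must have columns 'time' and 'event'")
  pseudo_ipd(d$time, d$event)
}

#' @rdname read_ipd
#' @param ipd A [pseudo_ipd()] object.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(as.data.frame(ipd)[c("time", "event")], path,
                   row.names = FALSE)
  invisible(path)
}

# fingerprint used to refuse model selection across different datasets
ipd_id <- function(ipd) {
  paste(nrow(ipd), sum(ipd$event),
        format(sum(ipd$time), digits = 15), sep = "/")
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function, computed with
#' [survival::survfit()]. Steps occur only at event times; censored
#' records shrink the risk set without a step. The returned curve
#' starts at `(0, 1)`.
#'
#' @param ipd A [pseudo_ipd()] object.
#' @return A `km_curve`: data frame with columns `time`, `survival`,
#'   `n_risk`, plus Greenwood standard errors in `std_err`.
#' @export
km_estimate <- function(ipd) {
  if (!inherits(ipd, "pseudo_ipd")) ipd <- pseudo_ipd(ipd$time, ipd$event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(ipd))
  s <- summary(fit, censored = FALSE)   # rows at event times only
  km_curve(time = c(0, s$time), survival = c(1, s$surv),
           n_risk = c(nrow(ipd), s$n.risk),
           std_err = c(0, s$std.err))
}

#' Kaplan-Meier step curve container
#'
#' Ordered `(time, survival)` step coordinates with the optional
#' numbers-at-risk column. The first coordinate must be `(0, 1)`,
#' times must be strictly increasing and survival non-increasing.
#'
#' @param time,survival Step coordinates.
#' @param n_risk,std_err Optional numbers at risk / Greenwood standard
#'   errors at the same times.
#' @return A data frame of class `km_curve`.
#' @export
km_curve <- function(time, survival, n_risk = NULL, std_err = NULL) {
  stopifnot(length(time) == length(survival), length(time) >= 1L)
  if (any(diff(time) <= 0)) stop("times must be strictly increasing")
  if (any(diff(survival) > 1e-12)) stop("survival must be non-increasing")
  if (abs(time[1]) > 1e-12 || abs(survival[1] - 1) > 1e-12)
    stop("curve must start at (0, 1)")
  if (any(survival < -1e-12 | survival > 1 + 1e-12))
    stop("survival values must lie in [0, 1]")
  d <- data.frame(time = time, survival = pmin(pmax(survival, 0), 1))
  if (!is.null(n_risk)) d$n_risk <- n_risk
  if (!is.null(std_err)) d$std_err <- std_err
  structure(d, class = c("km_curve", "data.frame"))
}

#' Evaluate a step curve
#'
#' Right-continuous step-function interpolation of a [km_curve()] (or
#' digitized curve) at arbitrary times.
#'
#' @param curve A `km_curve` or `digitized_curve`.
#' @param t Times in months.
#' @return Survival probabilities at `t`.
#' @export
km_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  out <- rep(1, length(t))
  out[idx >= 1] <- curve$survival[idx[idx >= 1]]
  out
}

#' Read / write a survival step curve as CSV
#'
#' Columns `time,survival` with optional `n_risk`.
#' @param path File path.
#' @return `read_km_curve()` returns a [km_curve()].
#' @export
read_km_curve <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "survival") %in% names(d)))
    stop("curve CSV must have columns 'time' and 'survival'")
  km_curve(d$time, d$survival, n_risk = d$n_risk)
}

#' @rdname read_km_curve
#' @param curve A [km_curve()].
#' @export
write_km_curve <- function(curve, path) {
  keep <- intersect(c("time", "survival", "n_risk"), names(curve))
  utils::write.csv(as.data.frame(curve)[keep], path, row.names = FALSE)
  invisible(path)
}
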