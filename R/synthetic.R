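#' Simulation specification for pseudo-IPD
#'
#' Describes a simulated cohort: the generating survival law, cohort
#' size, an administrative censoring horizon (emulating end of trial
#' follow-up) and a per-subject random loss-to-follow-up probability.
#' Defaults emulate a phase-3 oncology cohort followed for about two
#' and a half years with occasional drop-out.
#'
#' @param model A [parametric_survival()] generating law.
#' @param n Cohort size.
#' @param admin_censor_time Administrative censoring time in months.
#' @param random_censor_rate Probability that a subject is at risk of
#'   early random censoring (uniform over the follow-up window).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(model, n, admin_censor_time = 30,
                     random_censor_rate = 0.05, seed = 1L) {
  stopifnot_model(model)
  stopifnot(n >= 1, admin_censor_time > 0,
            random_censor_rate >= 0, random_censor_rate <= 1)
  structure(list(model = model, n = as.integer(n),
                 admin_censor_time = admin_censor_time,
                 random_censor_rate = random_censor_rate,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate pseudo individual-patient data
#'
#' Event times are drawn by inverse-CDF sampling from the generating
#' law. Each subject's censoring time is the administrative horizon,
#' or -- with probability `random_censor_rate` -- a uniform draw on
#' `(0, admin_censor_time)`. The observed record is
#' `min(event, censor)` with the event flag set when the event comes
#' first.
#'
#' @param spec A [sim_spec()].
#' @return A [pseudo_ipd()] with `spec$n` records.
#' @export
generate_pseudo_ipd <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    t_event <- survival_rand(spec$model, spec$n)
    cens <- rep(spec$admin_censor_time, spec$n)
    early <- stats::runif(spec$n) < spec$random_censor_rate
    cens[early] <- stats::runif(sum(early), 0, spec$admin_censor_time)
    time <- pmin(t_event, cens)
    # guard against zero times from extreme quantiles
    time <- pmax(time, .Machine$double.eps)
    pseudo_ipd(time, t_event <= cens)
  })
}

# evaluate 'expr' under a local RNG state seeded with 'seed'
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Emulate graphical digitization of a survival curve
#'
#' Samples a Kaplan-Meier step curve at `n_points` equally spaced
#' times over its observed range, adds bounded uniform reading noise
#' (`± noise`), clips to `[0, 1]` and restores monotonicity by
#' running-minimum (isotonic) clipping -- the post-processing a
#' careful analyst applies to hand-digitized coordinates.
#'
#' @param curve A [km_curve()].
#' @param n_points Number of sampled coordinates (>= 2), including
#'   time 0.
#' @param noise Half-width of the uniform reading error.
#' @param seed Integer seed.
#' @return A data frame of class `digitized_curve` with columns
#'   `time`, `survival`.
#' @export
digitize <- function(curve, n_points = 60, noise = 0.005, seed = 1L) {
  stopifnot(inherits(curve, "km_curve"), n_points >= 2, noise >= 0)
  tt <- seq(0, max(curve$time), length.out = n_points)
  s <- km_survival_at(curve, tt)
  with_seed(seed, {
    s <- s + stats::runif(n_points, -noise, noise)
  })
  s <- pmin(pmax(s, 0), 1)
  s <- cummin(s)
  structure(data.frame(time = tt, survival = s),
            class = c("digitized_curve", "data.frame"))
}

#' Reconstruct pseudo-IPD from digitized curve coordinates
#'
#' Interval-allocation reconstruction: between consecutive coordinates
#' the survival drop `S_i - S_{i+1}` corresponds to
#' `assumed_n * (S_i - S_{i+1})` events. The `d` events of an interval
#' are spread over it at the times `t_i + (j - 1/2)/d (t_{i+1} - t_i)`,
#' `j = 1..d` -- the step positions implied by a locally linear
#' survival decline. Spreading, rather than stacking all events at an
#' interval endpoint, avoids the systematic half-interval time shift
#' that endpoint allocation would imprint on densely digitized curves
#' (and which demonstrably biases downstream family selection).
#' Because every allocated time stays within its interval, the
#' Kaplan-Meier curve of the reconstruction still agrees with the
#' digitized coordinates exactly at the coordinate times. Fractional
#' counts are resolved by largest-remainder rounding so the total
#' number of records is conserved exactly. Subjects still alive after the last coordinate
#' are censored there. If a numbers-at-risk table is supplied,
#' per-interval censoring counts are calibrated so the implied risk
#' set matches it (censoring placed at interval midpoints), in the
#' spirit of standard curve-to-IPD reconstruction.
#'
#' @param curve A `digitized_curve` or [km_curve()] (monotone
#'   coordinates, at least 2).
#' @param assumed_n Assumed cohort size behind the curve.
#' @param risk_table Optional data frame with columns `time`,
#'   `n_risk`.
#' @return A [pseudo_ipd()] with exactly `assumed_n` records.
#' @export
reconstruct_ipd <- function(curve, assumed_n, risk_table = NULL) {
  stopifnot(assumed_n >= 1)
  if (nrow(curve) < 2L)
    stop("need at least 2 coordinates to reconstruct")
  tt <- curve$time; s <- curve$survival
  if (any(diff(tt) <= 0)) stop("coordinate times must be strictly increasing")
  if (any(diff(s) > 1e-12)) stop("coordinates must be non-increasing")

  drops <- pmax(-diff(s), 0) * assumed_n        # expected events per interval
  d <- largest_remainder(drops)

  time <- unlist(lapply(seq_along(d), function(i) {
    if (d[i] == 0L) return(numeric(0))
    tt[i] + (seq_len(d[i]) - 0.5) / d[i] * (tt[i + 1L] - tt[i])
  }))
  event <- rep(1L, sum(d))

  n_left <- assumed_n - sum(d)
  if (!is.null(risk_table)) {
    stopifnot(all(c("time", "n_risk") %in% names(risk_table)))
    rt <- risk_table[order(risk_table$time), ]
    at_risk <- assumed_n
    cens_t <- numeric(0); cens_n <- integer(0)
    for (j in seq_len(nrow(rt) - 1L)) {
      lo <- rt$time[j]; hi <- rt$time[j + 1L]
      ev_in <- sum(time > lo & time <= hi)
      c_j <- max(0L, at_risk - ev_in - rt$n_risk[j + 1L])
      c_j <- min(c_j, n_left - length(cens_t))      # cannot exceed remainder
      if (c_j > 0) {
        cens_t <- c(cens_t, rep((lo + hi) / 2, c_j))
        cens_n <- c(cens_n, rep(1L, c_j))
      }
      at_risk <- at_risk - ev_in - c_j
    }
    used <- length(cens_t)
    if (used > n_left) { cens_t <- cens_t[seq_len(n_left)]; used <- n_left }
    time <- c(time, cens_t, rep(tt[length(tt)], n_left - used))
    event <- c(event, rep(0L, n_left))
  } else if (n_left > 0) {
    time <- c(time, rep(tt[length(tt)], n_left))
    event <- c(event, rep(0L, n_left))
  }
  time <- pmax(time, .Machine$double.eps)
  pseudo_ipd(time, event)
}

# integer allocation preserving round(sum(x))
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    idx <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}
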