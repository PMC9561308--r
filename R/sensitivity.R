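#' One-way deterministic sensitivity specifications
#'
#' Extracts the DSA parameter list from a configuration's
#' `sensitivity` section: each entry carries a dot-path into the
#' configuration, its base value (read from the configuration), and
#' the low/high range. Parameters without a tabulated range default
#' to base +/- 25%.
#'
#' @param cfg A configuration.
#' @return Data frame with columns `path`, `base`, `low`, `high`,
#'   `dist`.
#' @export
dsa_specs <- function(cfg) {
  out <- do.call(rbind, lapply(cfg$sensitivity, function(e) {
    base <- cfg_get(cfg, e$path)
    low <- if (is.null(e$low) || is.na(e$low)) base * 0.75 else e$low
    high <- if (is.null(e$high) || is.na(e$high)) base * 1.25 else e$high
    data.frame(path = e$path, base = base, low = low, high = high,
               dist = if (is.null(e$dist)) NA_character_ else
                 as.character(e$dist))
  }))
  bad <- out$low > out$base | out$base > out$high
  if (any(bad))
    stop("invalid range (need low <= base <= high) for: ",
         paste(out$path[bad], collapse = ", "))
  out
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full two-arm model twice per parameter -- once at the
#' lower and once at the upper end of its range, all other parameters
#' held at base case -- and records the resulting ICERs. The output
#' is sorted by bar width (tornado order).
#'
#' @param cfg A configuration.
#' @param specs Parameter specification data frame from
#'   [dsa_specs()]; defaults to all configured parameters.
#' @return Data frame of class `dsa_result`: `path`, `base`, `low`,
#'   `high`, `icer_base`, `icer_at_low`, `icer_at_high`, `width`,
#'   sorted by decreasing `width`.
#' @examples
#' dsa <- one_way_dsa(base_config())
#' head(dsa[, c("path", "icer_at_low", "icer_at_high")])
#' @export
one_way_dsa <- function(cfg = base_config(), specs = dsa_specs(cfg)) {
  base_icer <- run_base_case(cfg)$icer
  icer_at <- function(path, value) {
    v <- cfg_get(cfg, path)        # errors on unknown path
    run_base_case(cfg_set(cfg, path, value))$icer
  }
  lo <- mapply(icer_at, specs$path, specs$low)
  hi <- mapply(icer_at, specs$path, specs$high)
  out <- data.frame(path = specs$path, base = specs$base,
                    low = specs$low, high = specs$high,
                    icer_base = base_icer,
                    icer_at_low = lo, icer_at_high = hi,
                    width = abs(hi - lo))
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  structure(out, class = c("dsa_result", "data.frame"))
}

#' Probabilistic sensitivity distributions
#'
#' Builds the sampling distribution for every configuration parameter
#' with an assigned family: gamma for costs and prices, beta for
#' utilities, disutilities, body surface area and the discount rate.
#' Moments follow the rule mean = base, sd = (high - low) /
#' (2 * 1.96), reading the tabulated range as an approximate 95%
#' interval. Gamma is parameterised by shape/rate from these moments;
#' beta is fitted on the rescaled interval `[low, high]` so draws
#' respect the tabulated support. When the base value sits on a range
#' boundary a mean-matched beta on `[low, high]` does not exist, and
#' a natural-scale beta on `[0, 1]` with the same moments is used
#' instead.
#'
#' @param cfg A configuration.
#' @param sd_scale Divisor turning the range into an sd (default
#'   `2 * 1.96`).
#' @return List of `psa_distribution` objects.
#' @export
psa_distributions <- function(cfg, sd_scale = 2 * 1.96) {
  sp <- dsa_specs(cfg)
  sp <- sp[!is.na(sp$dist), ]
  lapply(seq_len(nrow(sp)), function(i)
    psa_distribution(sp$path[i], sp$base[i], sp$low[i], sp$high[i],
                     sp$dist[i], sd_scale))
}

#' @rdname psa_distributions
#' @param path,base,low,high,family Parameter location, base value,
#'   range and distribution family (`"gamma"` or `"beta"`).
#' @export
psa_distribution <- function(path, base, low, high, family,
                             sd_scale = 2 * 1.96) {
  family <- match.arg(family, c("gamma", "beta"))
  sd <- (high - low) / sd_scale
  if (sd == 0 || base == 0) {
    pars <- list(degenerate = TRUE)
  } else if (family == "gamma") {
    pars <- list(shape = (base / sd)^2, rate = base / sd^2)
  } else {
    # beta rescaled to [low, high]
    m <- (base - low) / (high - low)
    s <- sd / (high - low)
    if (m <= 0 || m >= 1) { # boundary base: natural [0,1] scale
      m <- base; s <- sd; low <- 0; high <- 1
      if (m <= 0 || m >= 1)
        stop("infeasible beta moments for parameter '", path, "'")
    }
    if (s^2 >= m * (1 - m))
      stop("infeasible beta moments (sd too large) for parameter '",
           path, "'")
    nu <- m * (1 - m) / s^2 - 1
    pars <- list(alpha = m * nu, beta = (1 - m) * nu,
                 lo = low, hi = high)
  }
  structure(list(path = path, base = base, low = low, high = high,
                 family = family, sd = sd, pars = pars),
            class = "psa_distribution")
}

#' Draw one parameter set for the PSA
#'
#' Deterministic given the seed; degenerate distributions (zero sd)
#' return the base value.
#'
#' @param distributions List from [psa_distributions()].
#' @param seed Integer seed (omit to draw from the current RNG
#'   stream, as [run_psa()] does across iterations).
#' @return Named numeric vector of parameter values (names are
#'   config dot-paths).
#' @export
sample_psa_params <- function(distributions, seed = NULL) {
  draw <- function() {
    vapply(distributions, function(d) {
      if (isTRUE(d$pars$degenerate)) return(d$base)
      if (d$family == "gamma")
        stats::rgamma(1, shape = d$pars$shape, rate = d$pars$rate)
      else
        d$pars$lo + (d$pars$hi - d$pars$lo) *
          stats::rbeta(1, d$pars$alpha, d$pars$beta)
    }, numeric(1), USE.NAMES = FALSE) |>
      stats::setNames(vapply(distributions, `[[`, character(1), "path"))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n` Monte-Carlo iterations: each draws a full parameter set
#' from [psa_distributions()], rebuilds both arms and records the
#' incremental cost and QALY. The cost-effectiveness acceptability
#' curve (CEAC) gives, at each willingness-to-pay value, the fraction
#' of iterations with positive net monetary benefit.
#'
#' @param cfg A configuration.
#' @param distributions Sampling distributions; defaults to
#'   [psa_distributions()] of `cfg`.
#' @param n Number of iterations (default 10000).
#' @param seed Integer seed; results are reproducible given it.
#' @param wtp_grid WTP grid for the CEAC; always augmented with the
#'   configured threshold.
#' @return A list of class `psa_result`: `iterations` (data frame
#'   with `delta_cost`, `delta_qaly`, `icer`), `ceac` (data frame
#'   `wtp`, `probability`), `prob_ce_at_wtp`, `n`, `seed`, `wtp`.
#' @export
run_psa <- function(cfg = base_config(),
                    distributions = psa_distributions(cfg),
                    n = 10000, seed = 1L,
                    wtp_grid = seq(0, 150000, by = 5000)) {
  if (n < 1) stop("'n' must be >= 1")
  validate_config(cfg)
  wtp <- cfg$model$wtp_per_qaly
  wtp_grid <- sort(unique(c(wtp_grid, wtp)))
  dc <- dq <- numeric(n)
  with_seed(seed, {
    for (i in seq_len(n)) {
      draw <- sample_psa_params(distributions)
      cfg_i <- cfg
      for (p in names(draw)) cfg_i <- cfg_set(cfg_i, p, draw[[p]])
      res <- run_base_case(cfg_i)
      dc[i] <- res$delta_cost; dq[i] <- res$delta_qaly
    }
  })
  nmb <- outer(dq, wtp_grid) - dc
  ceac <- data.frame(wtp = wtp_grid, probability = colMeans(nmb > 0))
  structure(list(iterations = data.frame(delta_cost = dc, delta_qaly = dq,
                                         icer = ifelse(abs(dq) < 1e-12,
                                                       NA_real_, dc / dq)),
                 ceac = ceac,
                 prob_ce_at_wtp = ceac$probability[match(wtp, ceac$wtp)],
                 n = n, seed = seed, wtp = wtp),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n, x$seed))
  cat(sprintf("  mean incremental cost  $%.2f\n", mean(x$iterations$delta_cost)))
  cat(sprintf("  mean incremental QALY  %.4f\n", mean(x$iterations$delta_qaly)))
  cat(sprintf("  P(cost-effective) at WTP $%.2f: %.3f\n",
              x$wtp, x$prob_ce_at_wtp))
  invisible(x)
}
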