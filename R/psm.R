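#' Economic settings of the cohort model
#'
#' @param cycle_days Model cycle length in days (21: the q3w
#'   treatment rhythm).
#' @param horizon_years Model horizon in years; the number of cycles
#'   is `round(horizon_years * 365.25 / cycle_days)` (174 for the
#'   defaults; the trailing partial cycle is truncated).
#' @param discount_rate Annual discount rate applied to costs and
#'   effects, compounded annually at cycle-start time.
#' @param wtp_per_qaly Willingness-to-pay threshold, USD per QALY.
#' @param bsa_m2 Body surface area used for mg/m2 dosing.
#' @param month_days Days per month used to convert cycle time to the
#'   month axis of the survival laws.
#' @param half_cycle_correction If `TRUE`, per-cycle rewards use the
#'   mean of cycle-start and cycle-end occupancy instead of the
#'   cycle-start value.
#' @return A list of class `econ_params`.
#' @export
econ_params <- function(cycle_days = 21, horizon_years = 10,
                        discount_rate = 0.05, wtp_per_qaly = 37663.26,
                        bsa_m2 = 1.64, month_days = 30.4375,
                        half_cycle_correction = FALSE) {
  stopifnot(cycle_days > 0, horizon_years >= 0,
            discount_rate >= 0, discount_rate <= 1, bsa_m2 > 0)
  structure(list(cycle_days = cycle_days, horizon_years = horizon_years,
                 discount_rate = discount_rate, wtp_per_qaly = wtp_per_qaly,
                 bsa_m2 = bsa_m2, month_days = month_days,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 n_cycles = as.integer(round(horizon_years * 365.25 / cycle_days))),
            class = "econ_params")
}

econ_id <- function(econ) paste(unlist(econ), collapse = "|")

#' Discount factor at a time point
#'
#' Annual compounding: `1 / (1 + r)^t` with `t` in years.
#'
#' @param t_years Time in years (>= 0), vectorised.
#' @param econ An [econ_params()].
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(t_years, econ) {
  if (any(t_years < 0)) stop("'t_years' must be >= 0")
  (1 + econ$discount_rate)^(-t_years)
}

#' Drug component of a treatment strategy
#'
#' @param name Drug name.
#' @param price_per_mg Acquisition price, USD per mg.
#' @param rule Dosing rule: `"per_day_fixed_mg"` (oral daily dosing,
#'   `dose` mg/day), `"per_cycle_fixed_mg"` (fixed dose per model
#'   cycle), or `"per_admin_bsa_mg_per_m2"` (`dose` mg/m2 per
#'   administration, `admin_per_cycle` administrations per model
#'   cycle).
#' @param dose Dose under the rule's unit.
#' @param admin_per_cycle Administrations per 21-day model cycle
#'   (only used by the BSA rule; may be fractional for schedules that
#'   do not align with the model cycle).
#' @param weight Probability that a patient on this strategy receives
#'   the component (1 for combination partners; 0.5/0.5 for an
#'   either/or chemotherapy choice).
#' @return A list of class `drug_component`.
#' @export
drug_component <- function(name, price_per_mg, rule, dose,
                           admin_per_cycle = 1, weight = 1) {
  rule <- match.arg(rule, c("per_day_fixed_mg", "per_cycle_fixed_mg",
                            "per_admin_bsa_mg_per_m2"))
  if (price_per_mg < 0) stop("price_per_mg must be >= 0")
  stopifnot(dose > 0, admin_per_cycle > 0, weight >= 0, weight <= 1)
  structure(list(name = name, price_per_mg = price_per_mg, rule = rule,
                 dose = dose, admin_per_cycle = admin_per_cycle,
                 weight = weight),
            class = "drug_component")
}

#' Adverse-event profile of a strategy
#'
#' Grade >= 3 events with their incidence over the treatment course,
#' per-cycle management cost, and utility decrement. The model
#' applies the incidence-weighted expected cost and disutility during
#' on-treatment cycles.
#'
#' @param incidence,cost_per_cycle,disutility Named numeric vectors
#'   over the same event names.
#' @return A list of class `ae_profile` with `expected_cost` and
#'   `expected_disutility` precomputed.
#' @export
ae_profile <- function(incidence, cost_per_cycle, disutility) {
  ev <- names(incidence)
  stopifnot(!is.null(ev), setequal(ev, names(cost_per_cycle)),
            setequal(ev, names(disutility)))
  incidence <- unlist(incidence)[ev]
  cost_per_cycle <- unlist(cost_per_cycle)[ev]
  disutility <- unlist(disutility)[ev]
  if (any(incidence < 0 | incidence > 1)) stop("incidences must be in [0,1]")
  if (any(cost_per_cycle < 0)) stop("AE costs must be >= 0")
  if (any(disutility < 0 | disutility > 1)) stop("disutilities must be in [0,1]")
  structure(list(incidence = incidence, cost_per_cycle = cost_per_cycle,
                 disutility = disutility,
                 expected_cost = sum(incidence * cost_per_cycle),
                 expected_disutility = sum(incidence * disutility)),
            class = "ae_profile")
}

#' Treatment strategy (model arm)
#'
#' @param name Arm label.
#' @param components List of [drug_component()]s.
#' @param duration_cycles Number of model cycles over which drug
#'   acquisition and AE burden apply, derived from the median
#'   treatment duration.
#' @param ae An [ae_profile()].
#' @param os,pfs [parametric_survival()] laws on the month axis.
#' @return A list of class `strategy`.
#' @export
strategy <- function(name, components, duration_cycles, ae, os, pfs) {
  stopifnot(duration_cycles >= 0, inherits(ae, "ae_profile"))
  stopifnot_model(os); stopifnot_model(pfs)
  ok <- vapply(components, inherits, logical(1), what = "drug_component")
  if (!all(ok)) stop("'components' must be drug_component objects")
  structure(list(name = name, components = components,
                 duration_cycles = duration_cycles, ae = ae,
                 os = os, pfs = pfs),
            class = "strategy")
}

#' Drug acquisition cost per model cycle
#'
#' Sums each component's per-cycle milligram consumption times its
#' per-mg price, weighted by the component's receipt probability:
#' daily dosing contributes `dose * cycle_days` mg, fixed q3w dosing
#' `dose` mg, and BSA dosing `dose * bsa * admin_per_cycle` mg.
#'
#' @param strat A [strategy()].
#' @param econ An [econ_params()].
#' @return Cost in USD per cycle.
#' @export
drug_cost_per_cycle <- function(strat, econ) {
  sum(vapply(strat$components, function(cp) {
    mg <- switch(cp$rule,
      per_day_fixed_mg = cp$dose * econ$cycle_days,
      per_cycle_fixed_mg = cp$dose * 1,
      per_admin_bsa_mg_per_m2 = cp$dose * econ$bsa_m2 * cp$admin_per_cycle)
    cp$weight * cp$price_per_mg * mg
  }, numeric(1)))
}

#' Cohort trace of the partitioned-survival model
#'
#' State occupancy at each cycle start: progression-free
#' `pfd = min(S_pfs, S_os)`, dead `= 1 - S_os`, progressed
#' `pd = 1 - pfd - dead` (floored at zero). The `min()` guards the
#' occasional crossing of independently fitted curves.
#'
#' @param os,pfs [parametric_survival()] laws (month axis).
#' @param econ An [econ_params()].
#' @return A data frame of class `psm_trace` with columns `cycle`,
#'   `t_months`, `t_years`, `pfd`, `pd`, `dead`.
#' @export
compute_trace <- function(os, pfs, econ) {
  k <- seq_len(econ$n_cycles) - 1L
  t_months <- k * econ$cycle_days / econ$month_days
  s_os <- survival_prob(os, t_months)
  s_pfs <- survival_prob(pfs, t_months)
  pfd <- pmin(s_pfs, s_os)
  dead <- 1 - s_os
  pd <- pmax(1 - pfd - dead, 0)
  tr <- data.frame(cycle = k, t_months = t_months,
                   t_years = k * econ$cycle_days / 365.25,
                   pfd = pfd, pd = pd, dead = dead)
  stopifnot(all(abs(tr$pfd + tr$pd + tr$dead - 1) < 1e-9),
            all(diff(tr$dead) >= -1e-12), all(diff(tr$pfd) <= 1e-12))
  structure(tr, class = c("psm_trace", "data.frame"))
}

#' Run one model arm
#'
#' Accumulates, cycle by cycle and discounted at cycle-start time:
#' drug acquisition and expected adverse-event management cost while
#' on treatment (weighted by progression-free occupancy), follow-up
#' cost for all alive states, best-supportive-care cost for the
#' progressed state, life years, and utility-weighted QALYs (with the
#' expected AE disutility subtracted from the progression-free
#' utility during on-treatment cycles).
#'
#' @param strat A [strategy()].
#' @param costs List with `followup_per_cycle`, `bsc_per_cycle` (USD).
#' @param utilities List with `pfd`, `pd` utilities in `[0, 1]`.
#' @param econ An [econ_params()].
#' @return A list of class `arm_result`: discounted `total_cost`,
#'   `total_life_years`, `total_qalys`; an `undiscounted` twin;
#'   a `cost_breakdown` by component; and the `trace`.
#' @export
run_arm <- function(strat, costs, utilities, econ) {
  stopifnot(costs$followup_per_cycle >= 0, costs$bsc_per_cycle >= 0,
            utilities$pfd >= 0, utilities$pfd <= 1,
            utilities$pd >= 0, utilities$pd <= 1)
  tr <- compute_trace(strat$os, strat$pfs, econ)
  n <- econ$n_cycles
  if (n == 0L)
    return(new_arm_result(strat$name, rep(0, 3), rep(0, 3),
                          c(drug = 0, ae = 0, followup = 0, bsc = 0), tr, econ))
  pfd <- tr$pfd; pd <- tr$pd
  if (econ$half_cycle_correction) {
    # mean of cycle-start and cycle-end occupancy
    t_end <- n * econ$cycle_days / econ$month_days
    pfd_end <- c(pfd[-1L], min(survival_prob(strat$pfs, t_end),
                               survival_prob(strat$os, t_end)))
    pd_end <- c(pd[-1L], max(survival_prob(strat$os, t_end) -
                             pfd_end[n], 0))
    pfd <- (pfd + pfd_end) / 2
    pd <- (pd + pd_end) / 2
  }
  disc <- discount_factor(tr$t_years, econ)
  on_tx <- as.numeric(tr$cycle < strat$duration_cycles)
  cyc_yr <- econ$cycle_days / 365.25

  drug_c <- drug_cost_per_cycle(strat, econ) * pfd * on_tx
  ae_c <- strat$ae$expected_cost * pfd * on_tx
  fu_c <- costs$followup_per_cycle * (pfd + pd)
  bsc_c <- costs$bsc_per_cycle * pd
  ly <- (pfd + pd) * cyc_yr
  qaly <- ((utilities$pfd - strat$ae$expected_disutility * on_tx) * pfd +
           utilities$pd * pd) * cyc_yr

  disc_tot <- c(cost = sum(disc * (drug_c + ae_c + fu_c + bsc_c)),
                ly = sum(disc * ly), qaly = sum(disc * qaly))
  undisc_tot <- c(cost = sum(drug_c + ae_c + fu_c + bsc_c),
                  ly = sum(ly), qaly = sum(qaly))
  breakdown <- c(drug = sum(disc * drug_c), ae = sum(disc * ae_c),
                 followup = sum(disc * fu_c), bsc = sum(disc * bsc_c))
  new_arm_result(strat$name, disc_tot, undisc_tot, breakdown, tr, econ)
}

new_arm_result <- function(name, disc, undisc, breakdown, trace, econ) {
  structure(list(strategy = name,
                 total_cost = unname(disc[1]),
                 total_life_years = unname(disc[2]),
                 total_qalys = unname(disc[3]),
                 undiscounted = list(total_cost = unname(undisc[1]),
                                     total_life_years = unname(undisc[2]),
                                     total_qalys = unname(undisc[3])),
                 cost_breakdown = breakdown,
                 trace = trace,
                 econ_id = econ_id(econ)),
            class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> %s\n", x$strategy))
  cat(sprintf("  discounted:   $%.2f | %.3f LY | %.3f QALY\n",
              x$total_cost, x$total_life_years, x$total_qalys))
  cat(sprintf("  undiscounted: $%.2f | %.3f LY | %.3f QALY\n",
              x$undiscounted$total_cost, x$undiscounted$total_life_years,
              x$undiscounted$total_qalys))
  invisible(x)
}

#' Write a cohort trace as CSV
#'
#' @param trace A `psm_trace`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Build the two model arms from a configuration
#'
#' @param cfg A [base_config()]-shaped configuration.
#' @return List with elements `lp` and `chemo`, both [strategy()]s.
#' @export
build_strategies <- function(cfg) {
  sv <- lapply(cfg$survival, function(s)
    parametric_survival(s$family, s$shape, s$scale))
  dis <- cfg$utilities$ae_disutility
  lp <- strategy(
    name = "lenvatinib_pembrolizumab",
    components = list(
      drug_component("lenvatinib", cfg$prices_per_mg$lenvatinib,
                     "per_day_fixed_mg", cfg$dosing$lenvatinib_mg_per_day),
      drug_component("pembrolizumab", cfg$prices_per_mg$pembrolizumab,
                     "per_cycle_fixed_mg", cfg$dosing$pembrolizumab_mg_per_cycle)),
    duration_cycles = cfg$treatment$lp_duration_cycles,
    ae = ae_profile(cfg$ae_incidence$lp, cfg$costs$ae, dis),
    os = sv$lp_os, pfs = sv$lp_pfs)
  w <- cfg$treatment$chemo_doxorubicin_weight
  chemo <- strategy(
    name = "chemotherapy",
    components = list(
      drug_component("doxorubicin", cfg$prices_per_mg$doxorubicin,
                     "per_admin_bsa_mg_per_m2", cfg$dosing$doxorubicin_mg_per_m2,
                     admin_per_cycle = 1, weight = w),
      drug_component("paclitaxel", cfg$prices_per_mg$paclitaxel,
                     "per_admin_bsa_mg_per_m2", cfg$dosing$paclitaxel_mg_per_m2,
                     admin_per_cycle = cfg$dosing$paclitaxel_admin_per_cycle,
                     weight = 1 - w)),
    duration_cycles = cfg$treatment$chemo_duration_cycles,
    ae = ae_profile(cfg$ae_incidence$chemo, cfg$costs$ae, dis),
    os = sv$chemo_os, pfs = sv$chemo_pfs)
  list(lp = lp, chemo = chemo)
}

econ_from_config <- function(cfg) {
  m <- cfg$model
  econ_params(cycle_days = m$cycle_days, horizon_years = m$horizon_years,
              discount_rate = m$discount_rate, wtp_per_qaly = m$wtp_per_qaly,
              bsa_m2 = m$bsa_m2, month_days = m$month_days,
              half_cycle_correction = m$half_cycle_correction)
}

#' Run the base-case analysis from a configuration
#'
#' Evaluates both arms over the full horizon and performs the
#' incremental analysis of the combination arm against chemotherapy.
#'
#' @param cfg A configuration (defaults to [base_config()]).
#' @return A `ce_result` (see [incremental_analysis()]).
#' @examples
#' res <- run_base_case(base_config())
#' res$icer
#' @export
run_base_case <- function(cfg = base_config()) {
  validate_config(cfg)
  econ <- econ_from_config(cfg)
  arms <- build_strategies(cfg)
  lp <- run_arm(arms$lp, cfg$costs, cfg$utilities, econ)
  chemo <- run_arm(arms$chemo, cfg$costs, cfg$utilities, econ)
  incremental_analysis(lp, chemo, econ)
}
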