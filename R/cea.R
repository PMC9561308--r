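#' Incremental cost-effectiveness analysis
#'
#' Computes incremental cost and QALYs of an intervention over a
#' comparator, the ICER, the net monetary benefit at the
#' willingness-to-pay threshold, a dominance flag, and the
#' cost-effectiveness verdict. When the incremental QALY gain is
#' numerically zero the ICER is undefined (`NA`); when the
#' intervention is dominant (cheaper and more effective) or dominated
#' (dearer and less effective) the quadrant is reported via the flag
#' rather than as a meaningless negative ratio.
#'
#' @param intervention,comparator `arm_result`s computed under the
#'   same [econ_params()].
#' @param econ The shared [econ_params()].
#' @return A list of class `ce_result`: `arms`, `delta_cost`,
#'   `delta_qaly`, `delta_life_years`, `icer`, `nmb`, `dominance`
#'   (`"none"`, `"dominant"`, `"dominated"`), `cost_effective`, `wtp`.
#' @export
incremental_analysis <- function(intervention, comparator, econ) {
  stopifnot(inherits(intervention, "arm_result"),
            inherits(comparator, "arm_result"),
            inherits(econ, "econ_params"))
  if (intervention$econ_id != comparator$econ_id ||
      intervention$econ_id != econ_id(econ))
    stop("arms were computed under different economic settings")
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qalys - comparator$total_qalys
  dly <- intervention$total_life_years - comparator$total_life_years
  dominance <- if (dc < 0 && dq > 0) "dominant"
               else if (dc > 0 && dq < 0) "dominated"
               else "none"
  icer <- if (abs(dq) < 1e-9 || dominance != "none") NA_real_ else dc / dq
  nmb <- econ$wtp_per_qaly * dq - dc
  cost_effective <- dominance == "dominant" ||
    (dominance == "none" && !is.na(icer) && icer <= econ$wtp_per_qaly)
  structure(list(arms = list(intervention = intervention,
                             comparator = comparator),
                 delta_cost = dc, delta_qaly = dq, delta_life_years = dly,
                 icer = icer, nmb = nmb, dominance = dominance,
                 cost_effective = cost_effective,
                 wtp = econ$wtp_per_qaly),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  print(x$arms$intervention); print(x$arms$comparator)
  cat(sprintf("incremental: $%.2f / %.4f QALY", x$delta_cost, x$delta_qaly))
  if (!is.na(x$icer)) cat(sprintf(" -> ICER $%.2f/QALY", x$icer))
  if (x$dominance != "none") cat(" [", x$dominance, "]", sep = "")
  cat(sprintf("\nNMB at WTP $%.2f: $%.2f -> %scost-effective\n",
              x$wtp, x$nmb, if (x$cost_effective) "" else "NOT "))
  invisible(x)
}

#' Tabulate a cost-effectiveness result
#'
#' One row per arm in the conventional results-table layout: total
#' cost, total life years, total QALYs, incremental cost, incremental
#' QALY, ICER (incremental columns empty on the comparator row).
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.ce_result <- function(x, ...) {
  iv <- x$arms$intervention; cp <- x$arms$comparator
  data.frame(
    treatment = c(iv$strategy, cp$strategy),
    total_cost = c(iv$total_cost, cp$total_cost),
    total_life_years = c(iv$total_life_years, cp$total_life_years),
    total_qalys = c(iv$total_qalys, cp$total_qalys),
    incremental_cost = c(x$delta_cost, NA),
    incremental_qaly = c(x$delta_qaly, NA),
    icer = c(x$icer, NA))
}
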