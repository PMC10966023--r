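# Incremental cost-effectiveness -------------------------------------------

#' Compare two arms
#'
#' Pairwise incremental analysis of an intervention arm against a comparator
#' run under the same scenario: incremental cost and QALYs, the incremental
#' cost-effectiveness ratio (ICER), net monetary benefit at the
#' willingness-to-pay threshold, and a dominance classification.
#'
#' Deltas are intervention minus comparator. Dominance: lower cost and
#' higher effect is `comparator_dominated` (the intervention is dominant and
#' the ICER is reported without a number); higher cost and lower effect is
#' `intervention_dominated`; both deltas zero is `indifferent`; anything
#' else is a `tradeoff` with `icer = delta_cost / delta_qaly`.
#'
#' @param intervention,comparator `lpi_arm_result` objects from the same
#'   scenario.
#' @param wtp willingness-to-pay threshold in JPY per QALY.
#' @param jpy_per_gbp exchange rate used for the reported GBP conversion.
#' @return an object of class `lpi_cea`: `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` when `delta_qaly == 0`), `icer_gbp`, `nmb`, `dominance`,
#'   `icer_label`, plus the arm labels and scenario.
#' @examples
#' ps <- default_parameters()
#' cea <- compare_arms(run_cohort(ps, "lpi"), run_cohort(ps, "observation"))
#' cea$dominance
#' @export
compare_arms <- function(intervention, comparator, wtp = 5e6,
                         jpy_per_gbp = 160) {
  stopifnot(inherits(intervention, "lpi_arm_result"),
            inherits(comparator, "lpi_arm_result"))
  si <- intervention$scenario
  sc <- comparator$scenario
  if (si$entry_age != sc$entry_age || si$horizon != sc$horizon ||
      si$perspective != sc$perspective)
    stop("arm results come from different scenarios", call. = FALSE)
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  dominance <-
    if (dc == 0 && dq == 0) "indifferent"
    else if (dc < 0 && dq > 0) "comparator_dominated"
    else if (dc > 0 && dq < 0) "intervention_dominated"
    else "tradeoff"
  icer <- if (dq != 0) dc / dq else NA_real_
  label <-
    if (dominance == "comparator_dominated") "dominant"
    else if (dominance == "intervention_dominated") "dominated"
    else if (is.na(icer)) "undefined"
    else format(round(icer), big.mark = ",")
  structure(list(
    delta_cost = dc, delta_qaly = dq, icer = icer,
    icer_gbp = if (is.na(icer)) NA_real_ else to_gbp(icer, jpy_per_gbp),
    nmb = wtp * dq - dc, wtp = wtp,
    dominance = dominance, icer_label = label,
    intervention = intervention$arm, comparator = comparator$arm,
    scenario = si),
    class = "lpi_cea")
}

#' Convert JPY to pounds sterling
#'
#' @param jpy amount in Japanese Yen.
#' @param rate JPY per pound sterling (> 0).
#' @return rounded GBP amount for reporting.
#' @examples
#' to_gbp(2287662, 160)  # 14298
#' @export
to_gbp <- function(jpy, rate = 160) {
  if (any(rate <= 0)) stop("exchange rate must be > 0", call. = FALSE)
  round(jpy / rate)
}

#' Net monetary benefit
#'
#' @param delta_cost incremental cost (JPY).
#' @param delta_qaly incremental QALYs.
#' @param wtp willingness-to-pay (JPY/QALY); vectorised.
#' @return `wtp * delta_qaly - delta_cost`.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  wtp * delta_qaly - delta_cost
}

#' @export
print.lpi_cea <- function(x, ...) {
  cat("<lpi_cea> ", x$intervention, " vs ", x$comparator, ", ",
      x$scenario$label, "\n", sep = "")
  cat(sprintf("  incremental cost: %s JPY, incremental QALYs: %.5f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  cat("  ICER: ", x$icer_label,
      if (!is.na(x$icer)) sprintf(" JPY/QALY (GBP %s)",
                                  format(x$icer_gbp, big.mark = ",")),
      "\n", sep = "")
  cat(sprintf("  NMB at WTP %s: %s JPY\n",
              format(x$wtp, big.mark = ",", scientific = FALSE),
              format(round(x$nmb), big.mark = ",")))
  invisible(x)
}

#' One-row CSV serialisation of a comparison
#'
#' @param cea an `lpi_cea` object.
#' @param file optional output path.
#' @return single-row data frame (scenario, deltas, ICER in JPY and GBP,
#'   NMB, dominance).
#' @export
cea_table <- function(cea, file = NULL) {
  out <- data.frame(
    scenario = cea$scenario$label,
    delta_cost = cea$delta_cost, delta_qaly = cea$delta_qaly,
    icer_jpy = cea$icer, icer_gbp = cea$icer_gbp,
    nmb = cea$nmb, dominance = cea$dominance)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
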