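# Deterministic sensitivity analysis ---------------------------------------

#' Default scenario list
#'
#' The base case (ages 40-59, 20 one-year cycles) plus the six entry/exit
#' age variants: 40-54, 40-49, 50-69, 50-64, 50-59 and the lifetime 40-99
#' horizon.
#'
#' @return list of `lpi_scenario` objects.
#' @export
default_scenarios <- function() {
  list(
    base_case_scenario(),
    scenario_config(40, 54), scenario_config(40, 49),
    scenario_config(50, 69), scenario_config(50, 64),
    scenario_config(50, 59), scenario_config(40, 99))
}

#' Scenario sweep
#'
#' Runs both arms and the incremental comparison for each scenario.
#'
#' @param ps an `lpi_params` object.
#' @param scenarios list of `lpi_scenario` objects.
#' @param wtp willingness-to-pay (JPY/QALY).
#' @return data frame with one row per scenario: arm totals, incremental
#'   cost and QALYs, ICER in JPY and GBP, NMB and dominance. The full
#'   `lpi_arm_result`/`lpi_cea` objects are attached as attribute
#'   `"results"`.
#' @examples
#' sweep <- scenario_sweep(default_parameters(),
#'                         list(base_case_scenario()))
#' sweep$icer_jpy
#' @export
scenario_sweep <- function(ps, scenarios = default_scenarios(),
                           wtp = ps$values$wtp) {
  results <- lapply(scenarios, function(sc) {
    lpi <- run_cohort(ps, "lpi", sc)
    obs <- run_cohort(ps, "observation", sc)
    list(scenario = sc, lpi = lpi, obs = obs,
         cea = compare_arms(lpi, obs, wtp, ps$values$jpy_per_gbp))
  })
  out <- do.call(rbind, lapply(results, function(r) {
    data.frame(
      scenario = r$scenario$label,
      entry_age = r$scenario$entry_age, exit_age = r$scenario$exit_age,
      horizon = r$scenario$horizon,
      cost_lpi = r$lpi$total_cost, qaly_lpi = r$lpi$total_qaly,
      cost_obs = r$obs$total_cost, qaly_obs = r$obs$total_qaly,
      delta_cost = r$cea$delta_cost, delta_qaly = r$cea$delta_qaly,
      icer_jpy = r$cea$icer, icer_gbp = r$cea$icer_gbp,
      nmb = r$cea$nmb, dominance = r$cea$dominance)
  }))
  attr(out, "results") <- results
  out
}

#' One-way excursion of a single parameter
#'
#' Re-runs both arms with the parameter set to its lower and then its upper
#' one-way bound, all other inputs at default, and records the two ICERs.
#' Parameters sharing one input row (e.g. a cost paid in both arms) move
#' together automatically because both arms read the same parameter;
#' arm-specific probabilities are separate registry entries and hence
#' separate excursions.
#'
#' @param ps an `lpi_params` object (not modified).
#' @param parameter_id registry name of a varied parameter.
#' @param scenario an `lpi_scenario`.
#' @param wtp willingness-to-pay (JPY/QALY).
#' @return one-row data frame: parameter, low/high values, ICER at each
#'   bound, NMB at each bound, span `|icer_high - icer_low|`, and a
#'   direction flag (`+1` when the ICER rises with the parameter).
#' @export
one_way <- function(ps, parameter_id, scenario = base_case_scenario(),
                    wtp = ps$values$wtp) {
  i <- match(parameter_id, ps$meta$name)
  if (is.na(i)) stop("unknown parameter: ", parameter_id, call. = FALSE)
  if (is.na(ps$meta$dsa_low[i]))
    stop("parameter has no one-way range: ", parameter_id, call. = FALSE)
  run_at <- function(value) {
    ps2 <- set_parameter(ps, parameter_id, value)
    lpi <- run_cohort(ps2, "lpi", scenario)
    obs <- run_cohort(ps2, "observation", scenario)
    compare_arms(lpi, obs, wtp, ps$values$jpy_per_gbp)
  }
  lo <- run_at(ps$meta$dsa_low[i])
  hi <- run_at(ps$meta$dsa_high[i])
  data.frame(
    parameter = parameter_id,
    low = ps$meta$dsa_low[i], high = ps$meta$dsa_high[i],
    icer_low = lo$icer, icer_high = hi$icer,
    nmb_low = lo$nmb, nmb_high = hi$nmb,
    dominance_low = lo$dominance, dominance_high = hi$dominance,
    span = abs(hi$icer - lo$icer),
    direction = sign(hi$icer - lo$icer))
}

#' Tornado analysis
#'
#' One-way excursions for every varied parameter (transition probabilities
#' at +/-30%, utilities at +/-8%, costs at +/-20%, discount rate 0-4%),
#' ranked by the absolute ICER span. Ties keep registry order (stable sort).
#'
#' @param ps an `lpi_params` object.
#' @param scenario an `lpi_scenario`.
#' @param top_k number of entries to keep (>= 1); the full table is attached
#'   as attribute `"full"`.
#' @param wtp willingness-to-pay (JPY/QALY).
#' @return data frame of the `top_k` largest-span entries with a `rank`
#'   column.
#' @examples
#' \donttest{
#' torn <- tornado(default_parameters(), top_k = 3)
#' torn$parameter
#' }
#' @export
tornado <- function(ps, scenario = base_case_scenario(), top_k = 12,
                    wtp = ps$values$wtp) {
  if (top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  varied <- ps$meta$name[!is.na(ps$meta$dsa_low)]
  full <- do.call(rbind, lapply(varied, one_way, ps = ps,
                                scenario = scenario, wtp = wtp))
  ord <- order(-full$span)  # stable: ties keep registry order
  full <- full[ord, , drop = FALSE]
  full$rank <- seq_len(nrow(full))
  rownames(full) <- NULL
  out <- utils::head(full, top_k)
  attr(out, "full") <- full
  out
}

#' Write the tornado table as CSV
#'
#' @param torn result of [tornado()].
#' @param file output path.
#' @export
tornado_csv <- function(torn, file) {
  utils::write.csv(
    torn[, c("parameter", "low", "high", "icer_low", "icer_high",
             "span", "rank")],
    file, row.names = FALSE)
  invisible(file)
}

#' Tornado diagram
#'
#' Horizontal bars from the base-case ICER to the ICER at each one-way
#' bound, largest span on top.
#'
#' @param torn result of [tornado()].
#' @param base_icer base-case ICER (JPY/QALY) used as the bar origin.
#' @return a ggplot object.
#' @export
plot_tornado <- function(torn, base_icer) {
  d <- torn
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  d$lo <- pmin(d$icer_low, d$icer_high)
  d$hi <- pmax(d$icer_low, d$icer_high)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = lo, xend = hi,
                                       y = parameter, yend = parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (JPY/QALY)", y = NULL) +
    ggplot2::theme_minimal()
}
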