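# Markov cohort engine ------------------------------------------------------
#
# Two arms share the irreversible progression chain
#   PACS -> PAC -> PACG -> unilateral blindness -> bilateral blindness
# with one-year cycles and no dead state. First-year "tunnel" states carry
# the first-year costs (LPI procedure or initial work-up; lens extraction on
# PAC entry). The observation arm additionally has the one-cycle acute
# angle-closure crisis (AACC) state, after which the emergency iridotomy
# leaves the angle open and the patient follows LPI-arm probabilities from a
# dedicated post-AACC PACS state. Bilateral blindness is absorbing.

.STATES_LPI <- c("PACS_y1", "PACS", "PAC_y1", "PAC", "PACG",
                 "UNIBLIND", "BIBLIND")
.STATES_OBS <- c(.STATES_LPI, "AACC", "PACS_LPIOPEN")

#' Scenario configuration
#'
#' @param entry_age age at entry into the cohort (years, >= 40).
#' @param exit_age age in the final model year; the horizon is
#'   `exit_age - entry_age + 1` yearly cycles (20 in the base case, ages
#'   40-59).
#' @param label optional scenario label.
#' @param perspective `"payer"` (default) or `"societal"`.
#' @return an object of class `lpi_scenario`.
#' @examples
#' base_case_scenario()
#' @export
scenario_config <- function(entry_age = 40, exit_age = 59, label = NULL,
                            perspective = c("payer", "societal")) {
  perspective <- match.arg(perspective)
  if (entry_age < 40) stop("entry_age must be >= 40", call. = FALSE)
  horizon <- exit_age - entry_age + 1
  if (horizon < 1) stop("horizon must be >= 1 (exit_age >= entry_age)", call. = FALSE)
  if (is.null(label))
    label <- sprintf("%d-%d (%d-year horizon)", entry_age, exit_age, horizon)
  structure(list(entry_age = entry_age, exit_age = exit_age,
                 horizon = horizon, label = label,
                 perspective = perspective),
            class = "lpi_scenario")
}

#' @rdname scenario_config
#' @export
base_case_scenario <- function() {
  scenario_config(40, 59, label = "40-59 (20-year horizon, base-case)")
}

#' State space of one model arm
#'
#' @param arm `"lpi"` or `"observation"`.
#' @return character vector of state names in model order. The `_y1` states
#'   are tunnels: `PACS_y1` is occupied only at cycle 0 and `PAC_y1` only in
#'   the cycle of PAC entry.
#' @export
build_state_space <- function(arm = c("lpi", "observation")) {
  arm <- match.arg(arm)
  if (arm == "lpi") .STATES_LPI else .STATES_OBS
}

#' Annual transition matrix
#'
#' Row-stochastic matrix over [build_state_space()] for one arm. The post-
#' AACC state uses the LPI-arm progression probability (the emergency
#' iridotomy opens the angle exactly as the prophylactic one does); tunnel
#' states exit to their established twin with the same clinical transition
#' probabilities as the twin. Transition probabilities do not depend on age
#' (the age-bracketed trabeculectomy risk enters the cycle rewards, not the
#' state transitions); the `age` argument is kept for interface symmetry
#' with [cycle_rewards()].
#'
#' @param ps an `lpi_params` object.
#' @param arm `"lpi"` or `"observation"`.
#' @param age attained age in years (>= 40).
#' @return named row-stochastic matrix.
#' @export
transition_matrix <- function(ps, arm = c("lpi", "observation"), age = 40) {
  arm <- match.arg(arm)
  if (any(age < 40)) stop("age must be >= 40", call. = FALSE)
  v <- ps$values
  states <- build_state_space(arm)
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(states, states))
  pp <- if (arm == "lpi") v$p_pacs_pac_lpi else v$p_pacs_pac_obs
  pg <- if (arm == "lpi") v$p_pac_pacg_lpi else v$p_pac_pacg_obs
  pa <- if (arm == "lpi") 0 else v$p_pacs_aacc_obs
  for (s in c("PACS_y1", "PACS")) {
    M[s, "PAC_y1"] <- pp
    if (arm == "observation") M[s, "AACC"] <- pa
    M[s, "PACS"] <- 1 - pp - pa
  }
  for (s in c("PAC_y1", "PAC")) {
    M[s, "PACG"] <- pg
    M[s, "PAC"] <- 1 - pg
  }
  M["PACG", "UNIBLIND"] <- v$p_pacg_uniblind
  M["PACG", "PACG"] <- 1 - v$p_pacg_uniblind
  M["UNIBLIND", "BIBLIND"] <- v$p_uni_biblind
  M["UNIBLIND", "UNIBLIND"] <- 1 - v$p_uni_biblind
  M["BIBLIND", "BIBLIND"] <- 1
  if (arm == "observation") {
    M["AACC", "PACS_LPIOPEN"] <- v$p_aacc_pacs_lpiopen
    M["AACC", "AACC"] <- 1 - v$p_aacc_pacs_lpiopen
    M["PACS_LPIOPEN", "PAC_y1"] <- v$p_pacs_pac_lpi
    M["PACS_LPIOPEN", "PACS_LPIOPEN"] <- 1 - v$p_pacs_pac_lpi
  }
  if (any(M < 0))
    stop("transition probabilities in a row sum above 1", call. = FALSE)
  M
}

# Reward vectors (cost JPY, utility weight) for every state of an arm at one
# attained age. The trabeculectomy event is folded into the PACG rewards in
# expectation: cost + p_trab * c_trab and utility (1 - p_trab) * u_pacg +
# p_trab * u_trab. Vectorised over states; used by both the cohort engine
# and the microsimulation oracle.
.reward_vectors <- function(ps, arm, age, perspective = "payer") {
  v <- ps$values
  states <- build_state_space(arm)
  ptr <- age_bracket_value(ps, "trab_prob", age)
  cost <- stats::setNames(numeric(length(states)), states)
  util <- stats::setNames(rep(1, length(states)), states)
  cost["PACS_y1"] <- if (arm == "lpi") v$c_pacs_lpi_y1 else v$c_pacs_obs_y1
  cost["PACS"] <- if (arm == "lpi") v$c_pacs_lpi_follow else v$c_pacs_obs_follow
  cost["PAC_y1"] <- v$c_pac_y1
  cost["PAC"] <- v$c_pac_follow
  cost["PACG"] <- age_bracket_value(ps, "pacg_cost", age) + ptr * v$c_trab
  cost["UNIBLIND"] <- age_bracket_value(ps, "uniblind_cost", age)
  cost["BIBLIND"] <- age_bracket_value(ps, "biblind_cost", age)
  util["PACS_y1"] <- util["PACS"] <- v$u_pacs
  util["PAC_y1"] <- util["PAC"] <- v$u_pac
  util["PACG"] <- (1 - ptr) * v$u_pacg + ptr * v$u_trab
  util["UNIBLIND"] <- v$u_uniblind
  util["BIBLIND"] <- v$u_biblind
  if (arm == "observation") {
    cost["AACC"] <- v$c_aacc
    util["AACC"] <- v$u_aacc
    cost["PACS_LPIOPEN"] <- v$c_pacs_lpi_follow
    util["PACS_LPIOPEN"] <- v$u_pacs
  }
  if (perspective == "societal") {
    soc <- ps$societal
    if (is.null(soc$indirect_cost_biblind) || is.null(soc$visits_per_state))
      stop("societal perspective requires indirect_cost_biblind and ",
           "visits_per_state in the societal block", call. = FALSE)
    cost["BIBLIND"] <- cost["BIBLIND"] + soc$indirect_cost_biblind
    cost["UNIBLIND"] <- cost["UNIBLIND"] +
      soc$uniblind_fraction * soc$indirect_cost_biblind
    visits <- soc$visits_per_state[states]
    visits[is.na(visits)] <- 0
    cost <- cost + soc$travel_cost_per_visit * visits
  }
  list(cost = cost, utility = util)
}

#' Per-cycle state rewards
#'
#' Cost (JPY) and utility weight accrued during one cycle spent in `state`
#' at the given attained age. PACG rewards include the trabeculectomy event
#' in expectation over its age-bracketed annual probability.
#'
#' @param ps an `lpi_params` object.
#' @param arm `"lpi"` or `"observation"`.
#' @param state a state name from [build_state_space()].
#' @param cycle_index 0-based cycle (kept for interface completeness;
#'   rewards depend on the cycle only through the attained age).
#' @param age attained age in years.
#' @param perspective `"payer"` or `"societal"`.
#' @return named numeric vector `c(cost =, utility =)`.
#' @examples
#' ps <- default_parameters()
#' cycle_rewards(ps, "lpi", "PACS_y1", 0, 40)  # cost 98393, utility 1
#' @export
cycle_rewards <- function(ps, arm = c("lpi", "observation"), state,
                          cycle_index = 0, age = 40,
                          perspective = c("payer", "societal")) {
  arm <- match.arg(arm)
  perspective <- match.arg(perspective)
  rv <- .reward_vectors(ps, arm, age, perspective)
  if (!state %in% names(rv$cost)) stop("unknown state: ", state, call. = FALSE)
  c(cost = unname(rv$cost[state]), utility = unname(rv$utility[state]))
}

#' Run the cohort model for one arm
#'
#' Advances the cohort occupancy vector over the scenario horizon and
#' accrues discounted costs and QALYs. Rewards accrue at cycle start with
#' the first cycle undiscounted (annuity-due convention) and no half-cycle
#' correction: cycle `t` contributes
#' `sum(occupancy[t, ] * reward) * (1 + r)^(-t)`.
#'
#' @param ps an `lpi_params` object.
#' @param arm `"lpi"` or `"observation"`.
#' @param scenario an `lpi_scenario`; defaults to the base case.
#' @return an object of class `lpi_arm_result`: list with `total_cost`,
#'   `total_qaly`, their undiscounted twins, the occupancy `trace` (one row
#'   per cycle), per-cycle discounted cost/QALY vectors, `arm` and
#'   `scenario`.
#' @examples
#' res <- run_cohort(default_parameters(), "lpi")
#' round(res$total_qaly, 2)
#' @export
run_cohort <- function(ps, arm = c("lpi", "observation"),
                       scenario = base_case_scenario()) {
  arm <- match.arg(arm)
  stopifnot(inherits(scenario, "lpi_scenario"))
  v <- ps$values
  h <- scenario$horizon
  states <- build_state_space(arm)
  M <- transition_matrix(ps, arm, scenario$entry_age)
  occ <- stats::setNames(numeric(length(states)), states)
  occ["PACS_y1"] <- 1
  trace <- matrix(NA_real_, h, length(states),
                  dimnames = list(NULL, states))
  cyc_cost <- cyc_qaly <- numeric(h)
  disc <- (1 + v$discount_rate)^(-(0:(h - 1)))
  # rewards change only at the age-50 bracket boundary; cache per bracket
  rv_cache <- list()
  for (t in 0:(h - 1)) {
    age <- scenario$entry_age + t
    key <- if (age < 50) "b40" else "b50"
    if (is.null(rv_cache[[key]]))
      rv_cache[[key]] <- .reward_vectors(ps, arm, age, scenario$perspective)
    rv <- rv_cache[[key]]
    trace[t + 1, ] <- occ
    cyc_cost[t + 1] <- sum(occ * rv$cost)
    cyc_qaly[t + 1] <- sum(occ * rv$utility)
    occ <- as.vector(occ %*% M)
    names(occ) <- states
  }
  structure(list(
    total_cost = sum(cyc_cost * disc),
    total_qaly = sum(cyc_qaly * disc),
    undiscounted_cost = sum(cyc_cost),
    undiscounted_qaly = sum(cyc_qaly),
    cycle_cost = cyc_cost * disc,
    cycle_qaly = cyc_qaly * disc,
    trace = trace, arm = arm, scenario = scenario),
    class = "lpi_arm_result")
}

#' @export
print.lpi_arm_result <- function(x, ...) {
  cat("<lpi_arm_result> ", x$arm, " arm, ", x$scenario$label, "\n", sep = "")
  cat(sprintf("  discounted cost: %s JPY, QALYs: %.4f\n",
              format(round(x$total_cost), big.mark = ","), x$total_qaly))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' One row per cycle: cycle index, attained age, occupancy per state, and
#' the discounted cost and QALYs accrued in that cycle.
#'
#' @param result an `lpi_arm_result`.
#' @param file optional output path.
#' @return the trace data frame.
#' @export
trace_table <- function(result, file = NULL) {
  h <- nrow(result$trace)
  out <- data.frame(cycle = 0:(h - 1),
                    age = result$scenario$entry_age + 0:(h - 1),
                    result$trace,
                    disc_cost = result$cycle_cost,
                    disc_qaly = result$cycle_qaly,
                    check.names = FALSE)
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
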