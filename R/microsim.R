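# Individual-level microsimulation oracle ----------------------------------
#
# Simulates patient trajectories with per-cycle multinomial draws under the
# same state space, transition matrix, rewards and discounting as the
# cohort engine, so cohort totals and per-cycle occupancies can be checked
# against Monte Carlo means. The trabeculectomy event, folded into the PACG
# rewards in expectation by the cohort engine, is drawn explicitly here —
# either memorylessly each PACG cycle or at most once per patient — which
# quantifies the cost of the cohort model's memoryless approximation.

#' Simulate individual patient trajectories
#'
#' @param ps an `lpi_params` object.
#' @param arm `"lpi"` or `"observation"`.
#' @param scenario an `lpi_scenario`.
#' @param n_patients number of simulated patients (>= 1).
#' @param seed integer RNG seed; the global RNG state is restored on exit.
#' @param trab_mode `"memoryless"` (a trabeculectomy can recur in any PACG
#'   cycle, matching the cohort engine's expectation) or `"once_only"`
#'   (at most one surgery per patient).
#' @param return_trajectories keep the per-patient state and event matrices.
#' @return object of class `lpi_microsim`: `mean_cost`, `mean_qaly`,
#'   `se_cost`, `se_qaly`, per-patient `cost` and `qaly` vectors, and (when
#'   retained) `states` (n x horizon integer matrix indexing
#'   [build_state_space()]) and `trab_events` (logical matrix).
#' @examples
#' sim <- simulate_patients(default_parameters(), "lpi",
#'                          n_patients = 100, seed = 1)
#' sim$mean_qaly
#' @export
simulate_patients <- function(ps, arm = c("lpi", "observation"),
                              scenario = base_case_scenario(),
                              n_patients = 50000, seed = 1,
                              trab_mode = c("memoryless", "once_only"),
                              return_trajectories = TRUE) {
  arm <- match.arg(arm)
  trab_mode <- match.arg(trab_mode)
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  stopifnot(inherits(scenario, "lpi_scenario"))
  v <- ps$values
  states <- build_state_space(arm)
  ns <- length(states)
  M <- transition_matrix(ps, arm, scenario$entry_age)
  cum <- t(apply(M, 1, cumsum))
  h <- scenario$horizon
  n <- n_patients
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  pacg_id <- match("PACG", states)
  s <- rep(match("PACS_y1", states), n)
  had_trab <- logical(n)
  cost <- qaly <- numeric(n)
  traj <- if (return_trajectories) matrix(NA_integer_, n, h) else NULL
  trab_ev <- if (return_trajectories) matrix(FALSE, n, h) else NULL
  for (t in 0:(h - 1)) {
    age <- scenario$entry_age + t
    rv <- .reward_vectors(ps, arm, age, scenario$perspective)
    d <- (1 + v$discount_rate)^(-t)
    cyc_cost <- rv$cost[s]
    cyc_qaly <- rv$utility[s]
    # draw the trabeculectomy event instead of using its expectation
    in_pacg <- which(s == pacg_id)
    if (length(in_pacg)) {
      ptr <- age_bracket_value(ps, "trab_prob", age)
      ev <- stats::runif(length(in_pacg)) < ptr
      if (trab_mode == "once_only") ev <- ev & !had_trab[in_pacg]
      had_trab[in_pacg[ev]] <- TRUE
      c_pacg <- age_bracket_value(ps, "pacg_cost", age)
      cyc_cost[in_pacg] <- c_pacg + ifelse(ev, v$c_trab, 0)
      cyc_qaly[in_pacg] <- ifelse(ev, v$u_trab, v$u_pacg)
      if (return_trajectories) trab_ev[in_pacg[ev], t + 1] <- TRUE
    }
    cost <- cost + d * cyc_cost
    qaly <- qaly + d * cyc_qaly
    if (return_trajectories) traj[, t + 1] <- s
    # multinomial transition draw, state groups visited in fixed order
    if (t < h - 1) {
      s_new <- s
      for (k in seq_len(ns)) {
        idx <- which(s == k)
        if (!length(idx)) next
        r <- stats::runif(length(idx))
        s_new[idx] <- findInterval(r, cum[k, ]) + 1L
      }
      s <- s_new
    }
  }
  structure(list(
    mean_cost = mean(cost), mean_qaly = mean(qaly),
    se_cost = stats::sd(cost) / sqrt(n), se_qaly = stats::sd(qaly) / sqrt(n),
    cost = cost, qaly = qaly,
    states = traj, trab_events = trab_ev,
    state_names = states, n_patients = n, seed = seed,
    trab_mode = trab_mode, arm = arm, scenario = scenario),
    class = "lpi_microsim")
}

#' @export
print.lpi_microsim <- function(x, ...) {
  cat("<lpi_microsim> ", x$arm, " arm, ", format(x$n_patients, big.mark = ","),
      " patients (", x$trab_mode, " trabeculectomy)\n", sep = "")
  cat(sprintf("  mean cost %.0f (SE %.0f), mean QALY %.5f (SE %.5f)\n",
              x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}

#' Empirical occupancy trace from simulated trajectories
#'
#' Tabulates the per-cycle state occupancy fractions of a simulated patient
#' set, in the same layout as the cohort `trace`, for direct comparison.
#'
#' @param sim an `lpi_microsim` run with `return_trajectories = TRUE`.
#' @return matrix with one row per cycle and one column per state; rows sum
#'   to 1.
#' @export
trajectories_to_trace <- function(sim) {
  stopifnot(inherits(sim, "lpi_microsim"))
  if (is.null(sim$states) || nrow(sim$states) == 0)
    stop("no trajectories retained (empty set)", call. = FALSE)
  ns <- length(sim$state_names)
  occ <- apply(sim$states, 2, function(col) tabulate(col, nbins = ns))
  trace <- t(occ) / nrow(sim$states)
  colnames(trace) <- sim$state_names
  trace
}

#' Long-format trajectory table
#'
#' One row per patient-cycle with the state and event flags — the package's
#' synthetic trajectory data format. Intended for modest `n_patients`.
#'
#' @param sim an `lpi_microsim` run with `return_trajectories = TRUE`.
#' @param file optional CSV output path.
#' @return data frame `patient`, `cycle`, `age`, `state`, `aacc`, `trab`.
#' @export
trajectories_table <- function(sim, file = NULL) {
  stopifnot(inherits(sim, "lpi_microsim"))
  if (is.null(sim$states)) stop("no trajectories retained", call. = FALSE)
  n <- nrow(sim$states); h <- ncol(sim$states)
  out <- data.frame(
    patient = rep(seq_len(n), times = h),
    cycle = rep(0:(h - 1), each = n),
    age = rep(sim$scenario$entry_age + 0:(h - 1), each = n),
    state = sim$state_names[as.vector(sim$states)],
    aacc = sim$state_names[as.vector(sim$states)] == "AACC",
    trab = as.vector(sim$trab_events))
  out <- out[order(out$patient, out$cycle), ]
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' Cohort-versus-microsimulation validation report
#'
#' Runs the cohort engine and the microsimulation under identical inputs
#' and reports the agreement of the discounted totals in Monte Carlo
#' standard errors, for both arms.
#'
#' @param ps an `lpi_params` object.
#' @param scenario an `lpi_scenario`.
#' @param n_patients patients per arm.
#' @param seed RNG seed.
#' @return data frame with one row per arm and quantity: cohort value,
#'   microsimulation mean, standard error and z-score.
#' @export
validate_oracle <- function(ps, scenario = base_case_scenario(),
                            n_patients = 50000, seed = 1) {
  rows <- lapply(c("lpi", "observation"), function(arm) {
    coh <- run_cohort(ps, arm, scenario)
    sim <- simulate_patients(ps, arm, scenario, n_patients, seed,
                             return_trajectories = FALSE)
    data.frame(
      arm = arm,
      quantity = c("total_cost", "total_qaly"),
      cohort = c(coh$total_cost, coh$total_qaly),
      microsim = c(sim$mean_cost, sim$mean_qaly),
      se = c(sim$se_cost, sim$se_qaly),
      z = c((sim$mean_cost - coh$total_cost) / sim$se_cost,
            (sim$mean_qaly - coh$total_qaly) / sim$se_qaly))
  })
  do.call(rbind, rows)
}
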