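# Probabilistic sensitivity analysis ---------------------------------------

#' Method-of-moments beta fit
#'
#' Solves for the beta shape parameters that reproduce a requested mean and
#' standard deviation:
#' `alpha = mean * (mean * (1 - mean) / sd^2 - 1)`,
#' `beta  = (1 - mean) * (mean * (1 - mean) / sd^2 - 1)`.
#'
#' @param mean distribution mean in (0, 1).
#' @param sd standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return named vector `c(alpha =, beta =)`.
#' @examples
#' fit_beta(0.75, 0.0375)
#' @export
fit_beta <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("beta mean must be in (0, 1)", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (sd^2 >= mean * (1 - mean))
    stop("infeasible moments: sd^2 must be < mean * (1 - mean)", call. = FALSE)
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Method-of-moments gamma fit
#'
#' `shape = (mean / sd)^2`, `scale = sd^2 / mean`; with `sd = 0.10 * mean`
#' the shape is always 100.
#'
#' @param mean distribution mean (> 0).
#' @param sd standard deviation (> 0).
#' @return named vector `c(shape =, scale =)`.
#' @examples
#' fit_gamma(98393, 9839.3)  # shape 100, scale 983.93
#' @export
fit_gamma <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("gamma mean and sd must be > 0", call. = FALSE)
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Distribution specifications of the varied parameters
#'
#' Transition probabilities draw from beta distributions with SD equal to
#' 10% of the mean, utilities from betas with SD 5% of the mean, and costs
#' from gammas with SD 10% of the mean; structurally fixed inputs (the
#' utilities of 1, the AACC-resolution probability, the discount rate and
#' the analysis constants) never vary.
#'
#' @param ps an `lpi_params` object.
#' @return data frame: `name`, `family`, `mean`, `sd`.
#' @export
psa_specs <- function(ps) {
  m <- ps$meta[ps$meta$psa_family != "fixed", ]
  data.frame(name = m$name, family = m$psa_family, mean = m$value,
             sd = m$psa_sd_frac * m$value, stringsAsFactors = FALSE)
}

# Draw one n-vector for a parameter spec (beta or gamma, method of moments).
.draw_param <- function(spec, n) {
  if (spec$family == "beta") {
    ab <- fit_beta(spec$mean, spec$sd)
    stats::rbeta(n, ab["alpha"], ab["beta"])
  } else {
    ks <- fit_gamma(spec$mean, spec$sd)
    stats::rgamma(n, shape = ks["shape"], scale = ks["scale"])
  }
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo re-analysis of the incremental comparison. Each iteration
#' draws every varied parameter independently from its method-of-moments
#' distribution ([psa_specs()]), re-runs both arms and records the
#' incremental cost and QALYs. A parameter used by both arms receives a
#' single draw per iteration, so the deltas reflect parameter uncertainty
#' only. The draw order is fixed: parameters in registry order, all
#' `n_iterations` draws of one parameter taken consecutively; together with
#' `seed` this makes the result bit-reproducible. If the sampled exit
#' probabilities of the observation-arm PACS row exceed 1, that iteration's
#' row is redrawn and the occurrence counted (`resample_count`).
#'
#' @param ps an `lpi_params` object.
#' @param scenario an `lpi_scenario`.
#' @param n_iterations number of Monte Carlo iterations.
#' @param seed integer RNG seed; the global RNG state is restored on exit.
#' @param wtp reference willingness-to-pay for the stored NMB column.
#' @param retain_draws keep the parameter draw matrix in the result.
#' @return object of class `lpi_psa`: `samples` (data frame with
#'   `iteration`, `delta_cost`, `delta_qaly`, `nmb`, `quadrant`),
#'   `n_iterations`, `seed`, `wtp`, `resample_count`, optionally `draws`.
#' @examples
#' psa <- run_psa(default_parameters(), n_iterations = 50, seed = 1)
#' mean(psa$samples$nmb > 0)
#' @export
run_psa <- function(ps, scenario = base_case_scenario(),
                    n_iterations = 10000, seed = 1,
                    wtp = ps$values$wtp, retain_draws = FALSE) {
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  specs <- psa_specs(ps)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  n <- n_iterations
  draws <- matrix(NA_real_, n, nrow(specs),
                  dimnames = list(NULL, specs$name))
  for (j in seq_len(nrow(specs)))
    draws[, j] <- .draw_param(specs[j, ], n)
  # feasibility of the multi-exit observation PACS row; single-exit rows are
  # feasible by construction (beta support)
  resample_count <- 0L
  multi_exit <- all(c("p_pacs_pac_obs", "p_pacs_aacc_obs") %in% specs$name)
  repeat {
    if (!multi_exit) break
    bad <- draws[, "p_pacs_pac_obs"] + draws[, "p_pacs_aacc_obs"] > 1
    if (!any(bad)) break
    resample_count <- resample_count + sum(bad)
    draws[bad, "p_pacs_pac_obs"] <-
      .draw_param(specs[specs$name == "p_pacs_pac_obs", ], sum(bad))
    draws[bad, "p_pacs_aacc_obs"] <-
      .draw_param(specs[specs$name == "p_pacs_aacc_obs", ], sum(bad))
  }
  dc <- dq <- numeric(n)
  ps_i <- ps
  for (i in seq_len(n)) {
    ps_i$values[specs$name] <- as.list(draws[i, ])
    lpi <- run_cohort(ps_i, "lpi", scenario)
    obs <- run_cohort(ps_i, "observation", scenario)
    dc[i] <- lpi$total_cost - obs$total_cost
    dq[i] <- lpi$total_qaly - obs$total_qaly
  }
  nmb <- wtp * dq - dc
  quadrant <- ifelse(dq > 0 & dc < 0, "dominant",
              ifelse(dq > 0 & dc >= 0, "tradeoff_ne",
              ifelse(dq <= 0 & dc < 0, "tradeoff_sw", "dominated")))
  structure(list(
    samples = data.frame(iteration = seq_len(n), delta_cost = dc,
                         delta_qaly = dq, nmb = nmb, quadrant = quadrant),
    n_iterations = n, seed = seed, wtp = wtp,
    resample_count = resample_count,
    draws = if (retain_draws) draws else NULL,
    scenario = scenario),
    class = "lpi_psa")
}

#' Probability of cost-effectiveness at one threshold
#'
#' Fraction of iterations with positive net monetary benefit at `wtp`.
#'
#' @param psa an `lpi_psa` object.
#' @param wtp willingness-to-pay (JPY/QALY).
#' @export
prob_cost_effective <- function(psa, wtp = psa$wtp) {
  s <- psa$samples
  mean(wtp * s$delta_qaly - s$delta_cost > 0)
}

#' Cost-effectiveness acceptability curve
#'
#' Empirical probability that the intervention is cost-effective —
#' `P(lambda * dQ - dC > 0)` — over a grid of willingness-to-pay values.
#'
#' @param psa an `lpi_psa` object.
#' @param wtp_grid non-empty numeric vector of thresholds (JPY/QALY).
#' @return data frame `wtp`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 1e7, by = 1e5)) {
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty", call. = FALSE)
  if (nrow(psa$samples) == 0) stop("empty PSA result", call. = FALSE)
  s <- psa$samples
  prob <- vapply(wtp_grid,
                 function(l) mean(l * s$delta_qaly - s$delta_cost > 0),
                 numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Threshold at which the acceptability curve crosses a level
#'
#' Linear interpolation of the first upward crossing of `level`.
#'
#' @param curve result of [ceac()].
#' @param level probability level (default 0.5).
#' @return the interpolated willingness-to-pay, or `NA` if never crossed.
#' @export
ceac_crossing <- function(curve, level = 0.5) {
  above <- curve$probability >= level
  if (all(above)) return(curve$wtp[1])
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(curve$wtp[1])
  x0 <- curve$wtp[i - 1]; x1 <- curve$wtp[i]
  y0 <- curve$probability[i - 1]; y1 <- curve$probability[i]
  x0 + (level - y0) / (y1 - y0) * (x1 - x0)
}

#' @export
print.lpi_psa <- function(x, ...) {
  cat("<lpi_psa> ", x$n_iterations, " iterations, seed ", x$seed, "\n", sep = "")
  cat(sprintf("  P(cost-effective at WTP %s): %.3f\n",
              format(x$wtp, big.mark = ",", scientific = FALSE),
              prob_cost_effective(x)))
  cat(sprintf("  dominant quadrant: %.3f, resampled rows: %d\n",
              mean(x$samples$quadrant == "dominant"), x$resample_count))
  invisible(x)
}

#' Write the PSA samples / CEAC as CSV
#'
#' @param psa an `lpi_psa` object.
#' @param file output path.
#' @export
psa_csv <- function(psa, file) {
  utils::write.csv(psa$samples, file, row.names = FALSE)
  invisible(file)
}

#' @rdname psa_csv
#' @param curve result of [ceac()].
#' @export
ceac_csv <- function(curve, file) {
  utils::write.csv(curve, file, row.names = FALSE)
  invisible(file)
}

#' Incremental-plane scatter plot
#'
#' @param psa an `lpi_psa` object.
#' @param wtp threshold drawn as a line through the origin.
#' @return a ggplot object.
#' @export
plot_psa_scatter <- function(psa, wtp = psa$wtp) {
  ggplot2::ggplot(psa$samples,
                  ggplot2::aes(x = delta_qaly, y = delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0) + ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (JPY)") +
    ggplot2::theme_minimal()
}

#' Acceptability-curve plot
#'
#' @param curve result of [ceac()].
#' @return a ggplot object.
#' @export
plot_ceac <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = wtp, y = probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (JPY/QALY)",
                  y = "P(cost-effective)") +
    ggplot2::theme_minimal()
}
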