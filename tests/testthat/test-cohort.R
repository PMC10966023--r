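test_that("state spaces match the arm structures", {
  lpi <- build_state_space("lpi")
  obs <- build_state_space("observation")
  expect_length(lpi, 7)
  expect_length(obs, 9)
  expect_false("AACC" %in% lpi)
  expect_true(all(c("AACC", "PACS_LPIOPEN") %in% obs))
  expect_error(build_state_space("surgery"))
  # bilateral blindness is absorbing: a single outgoing self-loop
  for (arm in c("lpi", "observation")) {
    M <- transition_matrix(default_parameters(), arm)
    expect_equal(unname(M["BIBLIND", "BIBLIND"]), 1)
    expect_equal(sum(M["BIBLIND", ] > 0), 1)
  }
})

test_that("transition matrices are row-stochastic with the tabulated rates", {
  ps <- default_parameters()
  for (arm in c("lpi", "observation")) {
    M <- transition_matrix(ps, arm)
    expect_true(all(abs(rowSums(M) - 1) < 1e-12), info = arm)
    expect_true(all(M >= 0 & M <= 1), info = arm)
  }
  M <- transition_matrix(ps, "lpi")
  expect_equal(unname(M["PACS", c("PAC_y1", "PACS")]), c(0.0117, 0.9883))
  Mo <- transition_matrix(ps, "observation")
  expect_equal(unname(Mo["PACS", "PACS"]), 1 - 0.0218 - 0.00097)
  expect_equal(unname(Mo["AACC", "PACS_LPIOPEN"]), 1)
  # post-AACC patients progress at the LPI-arm rate
  expect_equal(unname(Mo["PACS_LPIOPEN", "PAC_y1"]), 0.0117)
  # zeroed clinical probabilities: established states self-loop, while the
  # structural one-cycle exits remain (tunnels to their established twins,
  # AACC to the post-LPI state)
  Mz <- transition_matrix(zeroed_transitions(), "observation")
  est <- c("PACS", "PAC", "PACG", "UNIBLIND", "BIBLIND", "PACS_LPIOPEN")
  expect_equal(unname(diag(Mz[est, est])), rep(1, 6))
  expect_equal(unname(Mz["PACS_y1", "PACS"]), 1)
  expect_equal(unname(Mz["PAC_y1", "PAC"]), 1)
  expect_equal(unname(Mz["AACC", "PACS_LPIOPEN"]), 1)
})

test_that("cycle rewards follow the tabulated costs and utilities", {
  ps <- default_parameters()
  expect_equal(cycle_rewards(ps, "lpi", "PACS_y1", 0, 40),
               c(cost = 98393, utility = 1))
  expect_equal(cycle_rewards(ps, "observation", "PACS_y1", 0, 40),
               c(cost = 19560, utility = 1))
  expect_equal(cycle_rewards(ps, "lpi", "PACS", 3, 43),
               c(cost = 23780, utility = 1))
  expect_equal(cycle_rewards(ps, "observation", "PACS_LPIOPEN", 5, 45)[["cost"]],
               23780)
  # PACG folds the trabeculectomy event in expectation
  expect_equal(cycle_rewards(ps, "observation", "PACG", 5, 45),
               c(cost = 48545 + 0.0088 * 697008,
                 utility = (1 - 0.0088) * 0.75 + 0.0088 * 0.74))
  expect_equal(cycle_rewards(ps, "observation", "PACG", 5, 45)[["utility"]],
               0.75 - 0.0088 * 0.01)
  expect_equal(cycle_rewards(ps, "observation", "AACC", 2, 42),
               c(cost = 107167, utility = 0.99))
  # age bracket switches at 50
  expect_equal(cycle_rewards(ps, "lpi", "BIBLIND", 12, 52)[["cost"]], 43753)
  expect_error(cycle_rewards(ps, "lpi", "AACC", 0, 40), "unknown state")
})

test_that("an event-free cohort accrues the closed-form annuity-due QALYs", {
  ps <- zeroed_transitions()
  res <- run_cohort(ps, "lpi")
  expect_equal(res$total_qaly, annuity_due(20, 0.02), tolerance = 1e-12)
  expect_equal(round(res$total_qaly, 4), 16.6785)
  expect_equal(res$undiscounted_qaly, 20)
  # costs: first-year cost once, follow-up for the remaining 19 cycles
  expect_equal(res$total_cost,
               98393 + 23780 * (annuity_due(20, 0.02) - 1), tolerance = 1e-12)
})

test_that("single-cycle horizon accrues the first-year rewards undiscounted", {
  ps <- default_parameters()
  res <- run_cohort(ps, "lpi", scenario_config(40, 40))
  expect_equal(res$total_cost, 98393)
  expect_equal(res$total_qaly, 1)
})

test_that("cohort traces conserve mass and absorb into blindness", {
  ps <- default_parameters()
  for (arm in c("lpi", "observation")) {
    res <- run_cohort(ps, arm, scenario_config(40, 99))
    tr <- res$trace
    expect_true(all(abs(rowSums(tr) - 1) < 1e-12), info = arm)
    expect_true(all(tr >= 0 & tr <= 1), info = arm)
    expect_true(all(diff(tr[, "BIBLIND"]) >= 0), info = arm)
    # tunnel states: PACS_y1 only at cycle 0
    expect_equal(unname(tr[1, "PACS_y1"]), 1)
    expect_true(all(tr[-1, "PACS_y1"] == 0), info = arm)
    expect_true(res$total_qaly <= res$scenario$horizon)
  }
})

test_that("discounting can be switched off and only lowers totals", {
  ps0 <- lpicea:::set_parameter(default_parameters(), "discount_rate", 0)
  res0 <- run_cohort(ps0, "observation")
  expect_equal(res0$total_cost, res0$undiscounted_cost)
  expect_equal(res0$total_qaly, res0$undiscounted_qaly)
  res2 <- run_cohort(default_parameters(), "observation")
  expect_lt(res2$total_cost, res2$undiscounted_cost)
  expect_lt(res2$total_qaly, res2$undiscounted_qaly)
})

test_that("totals respond monotonically to risks and prices", {
  ps <- default_parameters()
  base_lpi <- run_cohort(ps, "lpi")
  base_obs <- run_cohort(ps, "observation")
  # worse progression or blindness risk weakly lowers QALYs
  for (nm in c("p_pacs_pac_obs", "p_pac_pacg_obs", "p_pacg_uniblind",
               "p_uni_biblind")) {
    up <- lpicea:::set_parameter(ps, nm, ps$values[[nm]] * 2)
    expect_lte(run_cohort(up, "observation")$total_qaly,
               base_obs$total_qaly, label = nm)
  }
  # dearer care weakly raises costs
  for (nm in c("c_pacs_lpi_y1", "c_pacg_50_59", "c_trab")) {
    up <- lpicea:::set_parameter(ps, nm, ps$values[[nm]] * 1.5)
    expect_gte(run_cohort(up, "lpi")$total_cost,
               base_lpi$total_cost, label = nm)
  }
  # prophylaxis weakly dominates on effectiveness at defaults
  expect_gte(base_lpi$total_qaly, base_obs$total_qaly)
})

test_that("trace export carries cycles, ages and per-cycle accruals", {
  res <- run_cohort(default_parameters(), "observation")
  tab <- trace_table(res)
  expect_equal(nrow(tab), 20)
  expect_equal(tab$age, 40:59)
  expect_equal(sum(tab$disc_cost), res$total_cost)
  expect_equal(sum(tab$disc_qaly), res$total_qaly)
})
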