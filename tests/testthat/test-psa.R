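test_that("beta moment-matching solves the closed form and round-trips", {
  ab <- fit_beta(0.75, 0.0375)
  expect_equal(unname(ab), c(99.25, 33 + 1 / 12), tolerance = 1e-12)
  # the fitted distribution reproduces the requested moments analytically
  for (m in c(0.0117, 0.26, 0.75, 0.99)) {
    sd <- 0.05 * m
    ab <- fit_beta(m, sd)
    a <- ab[["alpha"]]; b <- ab[["beta"]]
    expect_equal(a / (a + b), m, tolerance = 1e-12)
    expect_equal(a * b / ((a + b)^2 * (a + b + 1)), sd^2, tolerance = 1e-12)
  }
  # vanishing sd concentrates the distribution at the mean
  ab <- fit_beta(0.3, 1e-6)
  expect_equal(ab[["alpha"]] / sum(ab), 0.3, tolerance = 1e-12)
  expect_gt(ab[["alpha"]], 1e9)
  # feasibility: sd^2 < mean (1 - mean)
  expect_silent(fit_beta(0.0117, 0.00117))
  expect_error(fit_beta(0.5, 0.5), "infeasible")
  expect_error(fit_beta(1.2, 0.1), "mean")
})

test_that("gamma moment-matching gives shape 100 at a 10% SD", {
  ks <- fit_gamma(98393, 9839.3)
  expect_equal(unname(ks), c(100, 983.93), tolerance = 1e-12)
  ks <- fit_gamma(697008, 69700.8)
  expect_equal(unname(ks), c(100, 6970.08), tolerance = 1e-12)
  for (m in c(19560, 107167)) {
    ks <- fit_gamma(m, 0.37 * m)
    expect_equal(ks[["shape"]] * ks[["scale"]], m, tolerance = 1e-12)
  }
  expect_error(fit_gamma(-1, 1), "> 0")
})

test_that("the distribution roster varies exactly the sampled inputs", {
  specs <- psa_specs(default_parameters())
  expect_equal(nrow(specs), 27)  # 28 varied in DSA minus the discount rate
  expect_false("discount_rate" %in% specs$name)
  expect_false(any(c("u_pacs", "u_pac", "u_aacc",
                     "p_aacc_pacs_lpiopen") %in% specs$name))
  expect_equal(sort(unique(specs$family)), c("beta", "gamma"))
  expect_true(all(specs$sd[specs$family == "gamma"] ==
                  0.10 * specs$mean[specs$family == "gamma"]))
  ut <- specs$name %in% c("u_pacg", "u_trab", "u_uniblind", "u_biblind")
  expect_true(all(specs$sd[ut] == 0.05 * specs$mean[ut]))
  expect_true(all(specs$sd[specs$family == "beta" & !ut] ==
                  0.10 * specs$mean[specs$family == "beta" & !ut]))
})

test_that("the PSA is bit-reproducible from its seed", {
  ps <- default_parameters()
  a <- run_psa(ps, n_iterations = 40, seed = 11, retain_draws = TRUE)
  b <- run_psa(ps, n_iterations = 40, seed = 11, retain_draws = TRUE)
  expect_identical(a$samples, b$samples)
  expect_identical(a$draws, b$draws)
  c <- run_psa(ps, n_iterations = 40, seed = 12)
  expect_false(identical(a$samples$delta_cost, c$samples$delta_cost))
  # the global RNG stream is left untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(run_psa(ps, n_iterations = 3, seed = 5))
  expect_identical(runif(3), before)
})

test_that("an all-fixed roster collapses the PSA onto the base case", {
  ps <- default_parameters()
  ps$meta$psa_family[] <- "fixed"
  psa <- run_psa(ps, n_iterations = 5, seed = 3)
  base <- compare_arms(run_cohort(ps, "lpi"), run_cohort(ps, "observation"))
  expect_equal(psa$samples$delta_cost, rep(base$delta_cost, 5))
  expect_equal(psa$samples$delta_qaly, rep(base$delta_qaly, 5))
})

test_that("sampled parameters recover their specified means", {
  ps <- default_parameters()
  n <- 4000
  psa <- run_psa(ps, n_iterations = n, seed = 7, retain_draws = TRUE)
  specs <- psa_specs(ps)
  for (j in seq_len(nrow(specs))) {
    xbar <- mean(psa$draws[, specs$name[j]])
    expect_lt(abs(xbar - specs$mean[j]), 3.5 * specs$sd[j] / sqrt(n),
              label = specs$name[j])
  }
  expect_gte(psa$resample_count, 0)
})

test_that("acceptability probabilities follow their definition", {
  # three hand-fixed iterations with NMB {+,-,+} at the reference threshold
  psa <- structure(list(
    samples = data.frame(iteration = 1:3,
                         delta_cost = c(100, 300, -50),
                         delta_qaly = c(0.0001, 0.00002, 0.00001)),
    wtp = 5e6, n_iterations = 3), class = "lpi_psa")
  expect_equal(prob_cost_effective(psa, 5e6), 2 / 3)
  # lambda = 0: probability equals the fraction of cost-saving iterations
  expect_equal(ceac(psa, 0)$probability, 1 / 3)
  curve <- ceac(psa, c(0, 1e6, 5e6, 2e7))
  expect_equal(curve$probability, c(1 / 3, 1 / 3, 2 / 3, 3 / 3))
  # monotone non-decreasing when every iteration has dQ > 0
  expect_true(all(diff(curve$probability) >= 0))
  expect_error(ceac(psa, numeric(0)), "non-empty")
})

test_that("the acceptability curve of a real PSA rises to the dQ>0 mass", {
  psa <- run_psa(default_parameters(), n_iterations = 60, seed = 2)
  grid <- seq(0, 1e9, length.out = 41)
  curve <- ceac(psa, grid)
  expect_equal(curve$probability[41], mean(psa$samples$delta_qaly > 0),
               tolerance = 0.05)
  f <- tempfile(fileext = ".csv")
  ceac_csv(curve, f)
  expect_equal(read.csv(f)$probability, curve$probability)
})

test_that("curve crossings interpolate linearly", {
  curve <- data.frame(wtp = c(0, 1e6, 2e6, 3e6),
                      probability = c(0.1, 0.3, 0.7, 0.9))
  expect_equal(ceac_crossing(curve, 0.5), 1.5e6)
  expect_equal(ceac_crossing(curve, 0.3), 1e6)
  expect_true(is.na(ceac_crossing(curve, 0.95)))
  expect_equal(ceac_crossing(curve, 0.05), 0)
})
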