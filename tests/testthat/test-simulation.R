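test_that("the decision score is the stated linear trade-off", {
  expect_equal(decision_score(0.8, 0.1, 120, 120, 1, 0.5), 0.7)
  expect_equal(decision_score(1, 0, 0, 120, 1, 0.5), 1.5)
  # one patient of EN is worth beta2 / N_max units of power
  delta <- decision_score(0.8, 0.1, 119, 120, 1, 0.5) -
    decision_score(0.8, 0.1, 120, 120, 1, 0.5)
  expect_equal(delta, 0.5 / 120)
  expect_error(decision_score(0.8, 0.1, 100, 0), "n_max")
})

test_that("estimation metrics are finite and well-shaped in a smoke run", {
  sc <- scenario_library()$scenario8
  for (m in c("independent", "bhm", "ibis")) {
    est <- estimation_study(sc, m, n_sim = 1, seed = 5,
                            mcmc = sim_mcmc_settings(n_iterations = 400,
                                                     n_burnin = 150))
    expect_true(all(is.finite(est$mse)))
    expect_true(all(est$mse >= 0))
    expect_true(all(is.finite(est$bias)))
    expect_true(all(est$width > 0))
    expect_identical(dim(est$mse), c(3L, 4L))
  }
})

test_that("independent-analysis estimates are unbiased with t-based widths", {
  sc <- scenario_library()$scenario2
  est <- estimation_study(sc, "independent", n_sim = 400, seed = 8)
  expect_true(all(abs(est$bias) < 3 * sqrt(0.1 / 400)))
  # width of the 95% t interval at n = 10 averages 2 * qt(.975, 9) * E(s)/sqrt(10)
  c4 <- sqrt(2 / 9) * gamma(5) / gamma(4.5)   # E(s) for sigma = 1, n = 10
  expect_equal(mean(est$width), 2 * qt(0.975, 9) * c4 / sqrt(10),
               tolerance = 0.02)
  expect_true(all(est$mse >= est$bias^2 - 1e-12))
})

test_that("borrowing beats per-subgroup estimation where exchangeability holds", {
  sc <- scenario_library()
  mc <- sim_mcmc_settings()
  # homogeneous scenarios: two-subset borrowing cuts MSE below the
  # independent analysis's sigma^2/n in (almost) every subgroup
  for (nm in c("scenario1", "scenario2")) {
    ibis <- estimation_study(sc[[nm]], "ibis", n_sim = 60, seed = 21, mcmc = mc)
    ind <- estimation_study(sc[[nm]], "independent", n_sim = 60, seed = 21)
    expect_lt(mean(ibis$mse), mean(ind$mse))
  }
  # good nugget: full exchangeability drags the lone effective subgroup
  # toward the null pool much harder than the two-subset model does
  ibis3 <- estimation_study(sc$scenario3, "ibis", n_sim = 60, seed = 22, mcmc = mc)
  bhm3 <- estimation_study(sc$scenario3, "bhm", n_sim = 60, seed = 22, mcmc = mc)
  expect_gt(abs(bhm3$bias[3, 4]), abs(ibis3$bias[3, 4]))
  expect_gt(abs(bhm3$bias[3, 4]), 0.1)
})

test_that("threshold calibration honours the cap with monotone simulated FWER", {
  sc1 <- scenario_library()$scenario1
  grid_t <- seq(1, 4.5, by = 0.01)
  cal <- calibrate_threshold("independent", sc1, 0.1, grid_t,
                             n_sim = 1000, seed = 44)
  expect_lte(cal$fwer, 0.1)
  # analytic oracle: FWER = 1 - P(T9 <= t)^12 under independence
  t_exact <- qt(0.9^(1 / 12), df = 9)
  expect_equal(cal$threshold, t_exact, tolerance = 0.06)
  expect_true(all(diff(cal$table$fwer) <= 0))
  # any threshold passes a cap of ~1: the smallest grid value is returned
  cal_loose <- calibrate_threshold("independent", sc1, 0.999, grid_t,
                                   n_sim = 50, seed = 44)
  expect_equal(cal_loose$threshold, grid_t[1])
  expect_error(calibrate_threshold("independent", sc1, 0.0001, c(1, 1.1),
                                   n_sim = 200, seed = 44), "cap")
})

test_that("fixed-design operating characteristics behave at the extremes", {
  sc2 <- scenario_library()$scenario2
  # a rule that can never reject
  oc0 <- operating_characteristics(sc2, "independent",
                                   decision_config(t_threshold = 1e6),
                                   n_sim = 50, seed = 3)
  expect_equal(oc0$conjunctive_power, 0)
  expect_equal(oc0$disjunctive_power, 0)
  expect_true(is.na(oc0$fwer))        # no null subgroups in scenario 2
  expect_equal(oc0$en, 120)           # fixed design enrolls everyone
  sc1 <- scenario_library()$scenario1
  oc1 <- operating_characteristics(sc1, "independent",
                                   decision_config(t_threshold = -1e6),
                                   n_sim = 50, seed = 3)
  expect_equal(oc1$fwer, 1)           # always rejects some null
  expect_true(is.na(oc1$conjunctive_power))
  expect_equal(sum(oc1$null_reject_dist), 1, tolerance = 1e-12)
})

test_that("disjunctive power dominates conjunctive power", {
  sc <- scenario_library()$scenario7
  oc <- operating_characteristics(sc, "independent",
                                  decision_config(t_threshold = 2),
                                  n_sim = 300, seed = 5)
  expect_gte(oc$disjunctive_power, oc$conjunctive_power)
  expect_equal(oc$mc_se$fwer, sqrt(oc$fwer * (1 - oc$fwer) / 300))
})

test_that("replicate streams are common across methods and reproducible", {
  sc <- scenario_library()$scenario5
  cfg <- decision_config(t_threshold = 2.5)
  a <- operating_characteristics(sc, "independent", cfg, n_sim = 100, seed = 9)
  b <- operating_characteristics(sc, "independent", cfg, n_sim = 100, seed = 9)
  expect_identical(a$fwer, b$fwer)
  expect_identical(a$null_reject_dist, b$null_reject_dist)
})

test_that("the threshold heatmap reduces to a single OC run on a 1 x 1 grid", {
  sc <- scenario_library()$scenario8
  des <- enrichment_design(subgroup_grid(3, 4), accrual = 5,
                           bf_effective = 60, bf_promising = 8)
  mc <- sim_mcmc_settings(n_iterations = 500, n_burnin = 200)
  hm <- threshold_heatmap(sc, des, bf_e_grid = 60, bf_p_grid = 8,
                          mcmc = mc, n_sim = 8, seed = 77)
  expect_equal(nrow(hm), 1)
  expect_equal(hm$score,
               decision_score(hm$conjunctive_power, hm$fwer, hm$en, 120, 1, 0.5))
  expect_lte(hm$en, 120)
  # invalid pairs are skipped
  expect_error(threshold_heatmap(sc, des, bf_e_grid = 5, bf_p_grid = 10,
                                 mcmc = mc, n_sim = 2, seed = 1), "valid")
})

test_that("stricter futility thresholds never enroll more patients under CRN", {
  sc <- scenario_library()$scenario1
  des <- enrichment_design(subgroup_grid(3, 4), accrual = 5,
                           bf_effective = 200, bf_promising = 5)
  mc <- sim_mcmc_settings(n_iterations = 500, n_burnin = 200)
  hm <- threshold_heatmap(sc, des, bf_e_grid = 200, bf_p_grid = c(2, 10, 40),
                          mcmc = mc, n_sim = 15, seed = 13)
  ord <- order(hm$bf_promising)
  expect_true(all(diff(hm$en[ord]) <= 1e-9))
})
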