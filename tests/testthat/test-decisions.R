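test_that("Bayes factors are posterior-to-prior odds ratios with clipping", {
  draws_at <- function(p, M = 1000) c(rep(1, round(p * M)), rep(-1, M - round(p * M)))
  expect_equal(bayes_factor(draws_at(0.5), theta0 = 0), 1)
  expect_equal(bayes_factor(draws_at(0.9), theta0 = 0), 9)
  expect_equal(bayes_factor(draws_at(0.9), theta0 = 0, prior_odds = 3), 3)
  # clipping keeps the ratio finite at p = 0 and p = 1
  expect_equal(bayes_factor(rep(1, 1000)), 1000)
  expect_equal(bayes_factor(rep(-1, 1000)), 1 / 1000)
  # monotone in the exceedance fraction
  bfs <- vapply(seq(0.1, 0.9, by = 0.1), function(p) bayes_factor(draws_at(p)),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_error(bayes_factor(rnorm(10)), "at least 100")
  expect_error(bayes_factor(rnorm(500), prior_odds = 0), "prior_odds")
})

test_that("interim classification applies the three-way threshold rule", {
  cfg <- decision_config(bf_effective = 100, bf_promising = 5)
  g <- matrix(200, 3, 4)
  expect_true(all(classify_interim(g, cfg)$status == "effective"))
  # infinite efficacy threshold disables interim efficacy stopping
  cfg_inf <- decision_config(bf_effective = Inf, bf_promising = 5)
  out <- classify_interim(matrix(1e6, 3, 4), cfg_inf)
  expect_false(any(out$status == "effective"))
  bf <- matrix(50, 3, 4); bf[3, 4] <- 150; bf[1, 1] <- 1
  out <- classify_interim(bf, cfg, closure = FALSE)
  expect_equal(out$status[3, 4], "effective")
  expect_equal(out$status[1, 1], "ineffective")
  expect_equal(out$status[2, 2], "promising")
  expect_error(classify_interim(bf, decision_config(bf_effective = 100,
                                                    bf_promising = 5),
                                stage = 1)$status, NA)
})

test_that("monotone closure propagates decisions up the grid and is idempotent", {
  g <- subgroup_grid(3, 4)
  mk <- function(status) gridbhm:::new_decision_grid(g, status, matrix(0, 3, 4))
  s <- matrix("ineffective", 3, 4); s[1, 1] <- "effective"
  expect_true(all(monotone_closure(mk(s))$status == "effective"))
  s <- matrix("ineffective", 3, 4); s[2, 3] <- "promising"
  out <- monotone_closure(mk(s))$status
  expect_equal(out[2, 4], "promising")
  expect_equal(out[3, 3], "promising")
  expect_equal(out[1, 1], "ineffective")
  # a promising subgroup never upgrades anything at the binary final analysis
  out_final <- monotone_closure(mk(s), final = TRUE)$status
  expect_equal(out_final[2, 4], "ineffective")
  # idempotence and up-set structure on random grids
  set.seed(8)
  for (i in 1:25) {
    dg <- mk(random_status_grid(3, 4))
    once <- monotone_closure(dg)
    expect_identical(monotone_closure(once)$status, once$status)
    expect_true(is_up_set_mat(once$status == "effective") ||
                  !any(once$status == "effective"))
    fin <- monotone_closure(dg, final = TRUE)
    expect_identical(monotone_closure(fin, final = TRUE)$status, fin$status)
  }
})

test_that("independent analysis computes one-sample t statistics per subgroup", {
  g <- subgroup_grid(2, 2)
  d <- exact_moment_data(g, matrix(c(1, 0, 0, 0), 2, 2), matrix(1, 2, 2), 10)
  cfg <- decision_config(t_threshold = 2.9)
  out <- decide_independent(d, cfg, closure = FALSE)
  expect_equal(out$statistic[1, 1], sqrt(10), tolerance = 1e-10)
  expect_equal(out$statistic[2, 2], 0)          # ybar = theta0 gives t = 0
  expect_true(all(out$status == "effective" | out$statistic <= 2.9))
  expect_true(all(out$status[out$statistic <= 2.9] == "ineffective"))
  # closure: an effective lower-left subgroup drags its upper set along
  d2 <- exact_moment_data(g, matrix(c(2, 0, 0, 0), 2, 2), matrix(1, 2, 2), 10)
  out2 <- decide_independent(d2, cfg)
  expect_true(all(out2$status == "effective"))
  # n = 1 subgroups are rejected by the frequentist rules
  d1 <- trial_data(g, data.frame(k = c(1, 1, 2, 2, 2), j = c(1, 2, 1, 2, 2),
                                 y = rnorm(5)))
  expect_error(decide_independent(d1, cfg), "n >= 2")
  expect_error(decide_freq(d1, cfg), "n >= 2")
})

test_that("the pooled-subset rule picks the best subset and decides per subset", {
  g <- subgroup_grid(2, 2)
  truth <- scenario_spec(matrix(c(0, 0, 0, 3), 2, 2, byrow = TRUE), name = "c")
  d <- generate_trial_data(truth, 50, 1, seed = 31)
  out <- decide_freq(d, decision_config(t_threshold = 2.5))
  expect_equal(out$status[2, 2], "effective")
  expect_true(all(out$status[cbind(c(1, 1, 2), c(1, 2, 1))] == "ineffective"))
  # symmetric input: a single decision for everyone
  d_same <- exact_moment_data(g, matrix(2, 2, 2), matrix(1, 2, 2), 20)
  out_same <- decide_freq(d_same, decision_config(t_threshold = 2.5))
  expect_length(unique(as.vector(out_same$status)), 1)
  # subset-level inference contract: statuses are constant within each subset
  expect_length(unique(out$statistic[out$status == "effective"]), 1)
})

test_that("final subgroup identification respects the up-set structure", {
  sc <- scenario_library()$scenario2
  d <- generate_trial_data(sc, 10, 1, seed = 77)
  cfg <- decision_config(bf_effective = 50, bf_promising = 5)
  out <- decide_ibis_final(d, mcmc = mcmc_settings(1000, 400, seed = 3),
                           config = cfg)
  expect_true(is_up_set_mat(out$status == "effective") ||
                !any(out$status == "effective"))
  expect_true(all(dim(out$statistic) == c(3, 4)))
  expect_s3_class(attr(out, "selection"), "division_selection")
  # strong uniform effects: everything should clear a moderate threshold
  expect_true(all(out$status == "effective"))

  out_bhm <- decide_exchangeable(d, mcmc = mcmc_settings(1000, 400, seed = 3),
                                 config = cfg)
  expect_true(all(out_bhm$status == "effective"))
})
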