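test_that("with dominant likelihoods posterior means hit the sample means", {
  # one subgroup per subset on a 1 x 2 chain; hierarchy washes out at large n
  g <- subgroup_grid(1, 2)
  set.seed(1)
  obs <- rbind(data.frame(k = 1, j = 1, y = rnorm(1e5, 0, 1)),
               data.frame(k = 1, j = 2, y = rnorm(1e5, 2, 1)))
  d <- trial_data(g, obs)
  ss <- subgroup_summary(d)
  fit <- fit_two_subset_bhm(d, division(g, rbind(c(1, 2))),
                            mcmc = mcmc_settings(3000, 1000, seed = 4))
  ps <- posterior_summary(fit)
  expect_equal(ps$mean, as.vector(ss$mean), tolerance = 0.02)
  # conjugate-normal oracle: posterior concentrates at ybar with sd sigma/sqrt(n)
  expect_lt(abs(ps$mean[2] - ss$mean[1, 2]), 3 / sqrt(1e5) * 3)
})

test_that("the subset-mean ordering constraint holds in every retained draw", {
  sc <- scenario_library()$scenario5
  d <- generate_trial_data(sc, 10, 1, seed = 12)
  divs <- enumerate_divisions(sc$grid)
  # include adversarial divisions whose high set carries the weakest data
  for (dv in divs[c(1, 10, 20, 33)]) {
    fit <- fit_two_subset_bhm(d, dv, mcmc = mcmc_settings(1500, 500, seed = 2))
    expect_true(all(fit$theta_high > fit$theta_low))
    expect_true(all(fit$var_high > 0))
    expect_true(all(fit$var_low > 0))
  }
})

test_that("a near-degenerate shrinkage prior forces complete pooling", {
  sc <- scenario_library()$scenario2
  d <- generate_trial_data(sc, 10, 1, seed = 3)
  dv <- division(sc$grid, upper_set(sc$grid, 2, 1))  # rows 2-3 high
  pr <- bhm_priors(shrink_high = c(1e6, 1))          # IG mean ~ 1e-6
  fit <- fit_two_subset_bhm(d, dv, priors = pr,
                            mcmc = mcmc_settings(2000, 500, seed = 8))
  hi_cols <- which(as.vector(dv$high))
  spread <- apply(fit$theta_subgroup[, hi_cols], 1, function(x) diff(range(x)))
  expect_lt(stats::median(spread), 0.02)  # high-subset effects collapse together
})

test_that("subgroups without patients draw from the hierarchical conditional", {
  sc <- scenario_library()$scenario2
  n <- matrix(10, 3, 4); n[1, 1] <- 0
  d <- generate_trial_data(sc, n, 1, seed = 21)
  dv <- division(sc$grid, upper_set(sc$grid, 1, 2))  # (1,1) alone in the low set
  fit <- fit_two_subset_bhm(d, dv, mcmc = mcmc_settings(2000, 500, seed = 5))
  ps <- posterior_summary(fit)
  empty <- ps[ps$k == 1 & ps$j == 1, ]
  # no data: pulled to its (low) subset mean, with wide uncertainty
  expect_lt(abs(empty$mean - mean(fit$theta_low)), 0.5)
  expect_gt(empty$upper - empty$lower,
            max(ps$upper - ps$lower) * 0.5)
})

test_that("the two-subset model refuses the full-population division", {
  sc <- scenario_library()$scenario1
  d <- generate_trial_data(sc, 5, 1, seed = 1)
  full <- division(sc$grid, upper_set(sc$grid, 1, 1))
  expect_error(fit_two_subset_bhm(d, full), "exchangeable")
  expect_error(fit_two_subset_bhm(d, division(sc$grid, rbind(c(3, 4))), sigma = 0),
               "sigma")
})

test_that("the exchangeable model pools correctly and shrinks nuggets", {
  g <- subgroup_grid(2, 2)
  m <- matrix(1.7, 2, 2)
  d <- exact_moment_data(g, m, matrix(1, 2, 2), 4000)
  fit <- fit_exchangeable_bhm(d, mcmc = mcmc_settings(2000, 500, seed = 6))
  expect_equal(posterior_summary(fit)$mean, rep(1.7, 4), tolerance = 0.02)
  expect_true(all(fit$var_high > 0))

  # lone effective subgroup is biased toward the null pool
  sc3 <- scenario_library()$scenario3
  bias <- vapply(1:12, function(i) {
    d <- generate_trial_data(sc3, 10, 1, seed = 100 + i)
    f <- fit_exchangeable_bhm(d, mcmc = mcmc_settings(1200, 400, seed = i))
    mean(f$theta_subgroup[, 12]) - subgroup_summary(d)$mean[3, 4]
  }, numeric(1))
  expect_lt(mean(bias), -0.1)  # shrunk down toward the pooled mean
})

test_that("posterior summaries are empirical equal-tailed intervals", {
  g <- subgroup_grid(1, 1)
  const <- gridbhm:::new_posterior_draws(
    g, matrix(3, 500, 1), rep(3, 500), NULL, rep(1, 500), NULL, NULL, "exchangeable")
  ps <- posterior_summary(const)
  expect_equal(unlist(ps[, c("mean", "lower", "upper")]),
               c(mean = 3, lower = 3, upper = 3))
  set.seed(2)
  norm <- gridbhm:::new_posterior_draws(
    g, matrix(rnorm(1e6), ncol = 1), NULL, NULL, NULL, NULL, NULL, "exchangeable")
  ps <- posterior_summary(norm)
  expect_equal(ps$lower, -1.96, tolerance = 0.01)
  expect_equal(ps$upper, 1.96, tolerance = 0.01)
  expect_true(ps$lower <= ps$mean && ps$mean <= ps$upper)
  expect_error(posterior_summary(norm, level = 1.2), "level")
})

test_that("the Gibbs posterior matches an independent JAGS fit", {
  has_jags <- requireNamespace("rjags", quietly = TRUE) &&
    !inherits(try(rjags::jags.model(
      textConnection("model { x ~ dnorm(0, 1) }"), quiet = TRUE), silent = TRUE),
      "try-error")
  if (!has_jags) {
    # cross-check engine unavailable on this host: assert the long-run
    # self-consistency of two independent chains instead
    sc <- scenario_library()$scenario5
    d <- generate_trial_data(sc, 10, 1, seed = 17)
    dv <- division(sc$grid, upper_set(sc$grid, 2, 3))
    f1 <- fit_two_subset_bhm(d, dv, mcmc = mcmc_settings(6000, 1000, seed = 1))
    f2 <- fit_two_subset_bhm(d, dv, mcmc = mcmc_settings(6000, 1000, seed = 99))
    expect_equal(colMeans(f1$theta_subgroup), colMeans(f2$theta_subgroup),
                 tolerance = 0.05)
    succeed()
  } else {
    sc <- scenario_library()$scenario5
    d <- generate_trial_data(sc, 10, 1, seed = 17)
    ss <- subgroup_summary(d)
    dv <- division(sc$grid, upper_set(sc$grid, 2, 3))
    # same joint target: conjugate IG priors expressed as gamma precisions;
    # the truncated prior on theta_hi matches the ordering constraint up to a
    # normalising factor that is flat over the posterior range
    model <- "
      model {
        for (i in 1:M) {
          ybar[i] ~ dnorm(theta[i], n[i] / sigma2)
          theta[i] ~ dnorm(high[i] * theta_hi + (1 - high[i]) * theta_lo,
                           high[i] * tau_hi + (1 - high[i]) * tau_lo)
        }
        theta_lo ~ dnorm(0, 1e-3)
        theta_hi ~ dnorm(1, 1e-3) T(theta_lo, )
        tau_hi ~ dgamma(1e-3, 1e-3)
        tau_lo ~ dgamma(1e-3, 1e-3)
      }"
    jm <- rjags::jags.model(
      textConnection(model),
      data = list(M = 12, ybar = as.vector(ss$mean), n = as.vector(ss$n),
                  sigma2 = 1, high = as.integer(as.vector(dv$high))),
      n.chains = 1, quiet = TRUE,
      inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7))
    stats::update(jm, 2000, progress.bar = "none")
    sm <- rjags::coda.samples(jm, "theta", 20000, progress.bar = "none")[[1]]
    ours <- fit_two_subset_bhm(d, dv, mcmc = mcmc_settings(22000, 2000, seed = 3))
    expect_equal(unname(colMeans(ours$theta_subgroup)), unname(colMeans(sm)),
                 tolerance = 0.05)
  }
})
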