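# deterministic per-replicate sub-seed from a master seed (kept within the
# 32-bit integer range); replicate i always sees the same data stream no
# matter which method or threshold consumes it (common random numbers)
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * as.numeric(i)) %% 2147483629 + 1)
}

# per-replicate per-subgroup decision statistics for the fixed one-stage
# analyses; `closure` says whether monotone propagation applies to the
# resulting effective sets
simulate_stat_grids <- function(scenario, method, config, n_per_subgroup, sigma,
                                priors, mcmc, n_sim, seed) {
  K <- scenario$grid$K; J <- scenario$grid$J
  stats <- array(NA_real_, c(K, J, n_sim))
  for (r in seq_len(n_sim)) {
    set.seed(derive_seed(seed, r))
    data <- generate_trial_data(scenario, n_per_subgroup, sigma, seed = NULL)
    stats[, , r] <- switch(method,
      ibis = {
        sel <- select_optimal_division(data, priors, mcmc, sigma)
        bayes_factor_grid(sel$chosen_fit, config$theta0, config$prior_odds)
      },
      bhm = {
        fit <- fit_exchangeable_bhm(data, priors, mcmc, sigma)
        bayes_factor_grid(fit, config$theta0, config$prior_odds)
      },
      independent = {
        ss <- subgroup_summary(data)
        sqrt(ss$n) * (ss$mean - config$theta0) / ss$sd
      },
      freq = {
        res <- freq_subset_stats(data, config$theta0)
        stat <- matrix(res$t_low, K, J)
        stat[res$high] <- res$t_high
        stat
      },
      stop(sprintf("unknown method '%s'", method), call. = FALSE))
  }
  list(stats = stats, closure = method != "freq")
}

reject_matrix <- function(stat, threshold, closure) {
  eff <- stat > threshold
  if (closure && any(eff)) eff <- reach_from_below(eff)
  eff
}

oc_from_rejections <- function(rejections, scenario, en, n_sim) {
  alt <- scenario$alternative_mask
  null <- scenario$null_mask
  n_null_rej <- vapply(rejections, function(r) sum(r & null), integer(1))
  prob <- function(x) mean(x)
  se <- function(p) if (is.na(p)) NA_real_ else sqrt(p * (1 - p) / n_sim)
  fwer <- if (any(null)) prob(n_null_rej > 0) else NA_real_
  conj <- if (any(alt)) prob(vapply(rejections, function(r) all(r[alt]), logical(1))) else NA_real_
  disj <- if (any(alt)) prob(vapply(rejections, function(r) any(r[alt]), logical(1))) else NA_real_
  structure(list(fwer = fwer, conjunctive_power = conj, disjunctive_power = disj,
                 en = mean(en), n_sim = n_sim,
                 mc_se = list(fwer = se(fwer), conjunctive_power = se(conj),
                              disjunctive_power = se(disj),
                              en = stats::sd(en) / sqrt(n_sim)),
                 null_reject_dist = tabulate(n_null_rej + 1L, nbins = sum(null) + 1L) / n_sim,
                 scenario = scenario$name),
            class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("operating characteristics (scenario '%s', %d replicates)\n",
              x$scenario, x$n_sim))
  cat(sprintf("  FWER: %s   conjunctive power: %s   disjunctive power: %s\n",
              fmt_or_na(x$fwer), fmt_or_na(x$conjunctive_power),
              fmt_or_na(x$disjunctive_power)))
  cat(sprintf("  expected sample size: %.1f\n", x$en))
  invisible(x)
}

fmt_or_na <- function(p) if (is.na(p)) "--" else sprintf("%.4f", p)

#' Simulate design operating characteristics
#'
#' Estimates, over seeded replicates with common random numbers, the
#' family-wise error rate (probability of declaring effective at least one
#' truly null subgroup), conjunctive power (all truly alternative subgroups
#' declared effective), disjunctive power (at least one alternative declared
#' effective) and expected sample size.  Null/alternative labels come from
#' the scenario's `alternative_mask`.  Metrics that are undefined for a
#' scenario (power with no alternatives, FWER with no nulls) are `NA`.
#'
#' With `design = NULL` the fixed one-stage analysis is simulated with the
#' chosen method; supplying an [enrichment_design()] simulates the
#' multi-stage adaptive enrichment trial (method `"ibis"`).
#'
#' @param scenario a [scenario_spec()].
#' @param method one of `"ibis"`, `"independent"`, `"bhm"`, `"freq"`.
#' @param config a [decision_config()]; the effectiveness threshold used is
#'   `bf_effective` (Bayesian methods) or `t_threshold` (frequentist).
#' @param design optional [enrichment_design()] for the adaptive trial.
#' @param n_per_subgroup fixed-design per-subgroup sample size.
#' @param sigma known outcome standard deviation.
#' @param priors,mcmc model settings for the Bayesian methods.
#' @param n_sim number of replicates.
#' @param seed master seed; replicate `i` uses a sub-seed derived from it.
#' @return An `operating_characteristics` object; `null_reject_dist` gives
#'   the simulated distribution of the number of null subgroups declared
#'   effective (entry `m + 1` is the probability of exactly `m`).
#' @export
operating_characteristics <- function(scenario, method = c("ibis", "independent", "bhm", "freq"),
                                      config = decision_config(), design = NULL,
                                      n_per_subgroup = 10, sigma = 1,
                                      priors = bhm_priors(), mcmc = sim_mcmc_settings(),
                                      n_sim = 500, seed = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"))
  method <- match.arg(method)
  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  if (is.null(design)) {
    sg <- simulate_stat_grids(scenario, method, config, n_per_subgroup, sigma,
                              priors, mcmc, n_sim, seed)
    thr <- if (method %in% c("ibis", "bhm")) {
      stage_value(config$bf_effective, .Machine$integer.max)
    } else config$t_threshold
    rejections <- lapply(seq_len(n_sim), function(r) {
      reject_matrix(sg$stats[, , r], thr, sg$closure)
    })
    en_total <- sum(matrix(n_per_subgroup, scenario$grid$K, scenario$grid$J))
    oc_from_rejections(rejections, scenario, rep(en_total, n_sim), n_sim)
  } else {
    if (method != "ibis") {
      stop("the enrichment simulation is defined for method 'ibis'", call. = FALSE)
    }
    rejections <- vector("list", n_sim)
    en <- numeric(n_sim)
    for (r in seq_len(n_sim)) {
      res <- run_enrichment_trial(scenario, design, priors, mcmc, config, sigma,
                                  seed = derive_seed(seed, r))
      rejections[[r]] <- res$decisions$status == "effective"
      en[r] <- res$total_n
    }
    oc_from_rejections(rejections, scenario, en, n_sim)
  }
}

# chain sizes used inside the replicate-level simulation engine; shorter than
# the single-analysis default, sized so threshold calibration and operating
# characteristics are stable (see the vignette for the Monte-Carlo budget)
#' Default MCMC settings for the simulation engine
#'
#' Shorter chains than [mcmc_settings()] (2500 iterations, 500 burn-in, so
#' 2000 retained draws), sized for replicate-level simulation where
#' thousands of fits are needed and threshold calibration absorbs residual
#' Monte-Carlo error.
#' @param ... overrides passed to [mcmc_settings()].
#' @export
sim_mcmc_settings <- function(...) {
  args <- modifyList(list(n_iterations = 2500, n_burnin = 500), list(...))
  do.call(mcmc_settings, args)
}

#' Calibrate a decision threshold against a family-wise error cap
#'
#' Simulates the null scenario once per replicate (common random numbers
#' across all grid points: the per-subgroup decision statistics are computed
#' once and rethresholded), then returns the smallest threshold on the grid
#' whose simulated FWER does not exceed the cap.  Simulated FWER is
#' non-increasing in the threshold by construction.
#'
#' @param method one of `"ibis"`, `"independent"`, `"bhm"`, `"freq"`.
#' @param null_scenario the scenario supplying the null configuration
#'   (typically the global null).
#' @param fwer_cap target family-wise error cap in (0, 1).
#' @param threshold_grid ascending vector of candidate thresholds (Bayes
#'   factors or t statistics, per method).
#' @inheritParams operating_characteristics
#' @return List with `threshold` (the calibrated value), `fwer` (its
#'   simulated FWER), and `table` (a data.frame of FWER over the whole grid).
#' @export
calibrate_threshold <- function(method = c("ibis", "independent", "bhm", "freq"),
                                null_scenario, fwer_cap, threshold_grid,
                                config = decision_config(),
                                n_per_subgroup = 10, sigma = 1,
                                priors = bhm_priors(), mcmc = sim_mcmc_settings(),
                                n_sim = 500, seed = 1L) {
  method <- match.arg(method)
  if (fwer_cap <= 0 || fwer_cap >= 1) stop("fwer_cap must be in (0, 1)", call. = FALSE)
  threshold_grid <- sort(threshold_grid)
  sg <- simulate_stat_grids(null_scenario, method, config, n_per_subgroup, sigma,
                            priors, mcmc, n_sim, seed)
  null <- null_scenario$null_mask
  if (!any(null)) stop("null_scenario has no null subgroups", call. = FALSE)
  # cells whose effectiveness (after propagation if applicable) rejects a null
  relevant <- if (sg$closure) {
    ur <- matrix(FALSE, nrow(null), ncol(null))
    for (k in seq_len(nrow(null))) for (j in seq_len(ncol(null))) {
      us <- upper_set(null_scenario$grid, k, j)
      ur[k, j] <- any(null[us])
    }
    ur
  } else null
  crit <- vapply(seq_len(dim(sg$stats)[3]),
                 function(r) max(sg$stats[, , r][relevant]), numeric(1))
  fwer <- vapply(threshold_grid, function(thr) mean(crit > thr), numeric(1))
  ok <- which(fwer <= fwer_cap)
  if (!length(ok)) {
    stop("no threshold on the grid satisfies the FWER cap", call. = FALSE)
  }
  list(threshold = threshold_grid[ok[1L]], fwer = fwer[ok[1L]],
       table = data.frame(threshold = threshold_grid, fwer = fwer),
       method = method, fwer_cap = fwer_cap, n_sim = n_sim)
}

#' Estimation performance over simulated replicates
#'
#' Per-subgroup mean squared error, bias and average 95% interval width of
#' the treatment-effect estimates over seeded replicates: posterior means and
#' equal-tailed credible intervals for the Bayesian methods, sample means and
#' t-based confidence intervals for the independent analysis.
#'
#' @inheritParams operating_characteristics
#' @param method one of `"ibis"`, `"independent"`, `"bhm"`.
#' @param level interval level (default 0.95).
#' @return List of `K x J` matrices `mse`, `bias`, `width`, plus `n_sim`.
#' @export
estimation_study <- function(scenario, method = c("ibis", "independent", "bhm"),
                             n_per_subgroup = 10, sigma = 1,
                             priors = bhm_priors(), mcmc = sim_mcmc_settings(),
                             n_sim = 500, seed = 1L, level = 0.95) {
  method <- match.arg(method)
  if (n_sim < 1) stop("n_sim must be >= 1", call. = FALSE)
  K <- scenario$grid$K; J <- scenario$grid$J
  est <- array(NA_real_, c(K, J, n_sim))
  wid <- array(NA_real_, c(K, J, n_sim))
  alpha <- 1 - level
  for (r in seq_len(n_sim)) {
    set.seed(derive_seed(seed, r))
    data <- generate_trial_data(scenario, n_per_subgroup, sigma, seed = NULL)
    if (method == "independent") {
      ss <- subgroup_summary(data)
      est[, , r] <- ss$mean
      wid[, , r] <- 2 * stats::qt(1 - alpha / 2, ss$n - 1) * ss$sd / sqrt(ss$n)
    } else {
      fit <- if (method == "bhm") {
        fit_exchangeable_bhm(data, priors, mcmc, sigma)
      } else {
        select_optimal_division(data, priors, mcmc, sigma)$chosen_fit
      }
      ps <- posterior_summary(fit, level)
      est[, , r] <- matrix(ps$mean, K, J)
      wid[, , r] <- matrix(ps$upper - ps$lower, K, J)
    }
  }
  err <- sweep(est, c(1, 2), scenario$theta)
  list(mse = apply(err^2, c(1, 2), mean),
       bias = apply(err, c(1, 2), mean),
       width = apply(wid, c(1, 2), mean),
       n_sim = n_sim, method = method, scenario = scenario$name)
}

#' Decision score of a design configuration
#'
#' Linear trade-off between conjunctive power, family-wise error and
#' expected sample size:
#' `Score = Power - beta1 * FWER + beta2 * (1 - EN / N_max)`.
#' A one-unit FWER increase offsets `beta1` units of power; saving one
#' patient of expected sample size is worth `beta2 / N_max` units of power.
#'
#' @param power conjunctive power.
#' @param fwer family-wise error rate.
#' @param en expected sample size.
#' @param n_max maximum total sample size (> 0).
#' @param beta1,beta2 trade-off weights.
#' @return The score (real scalar).
#' @examples
#' decision_score(0.8, 0.1, 120, 120, 1, 0.5)  # 0.7
#' @export
decision_score <- function(power, fwer, en, n_max, beta1 = 1, beta2 = 0.5) {
  if (n_max <= 0) stop("n_max must be > 0", call. = FALSE)
  power - beta1 * fwer + beta2 * (1 - en / n_max)
}

#' Operating characteristics over a grid of interim thresholds
#'
#' Simulates the adaptive enrichment design at every valid pair of
#' thresholds `(BF_E, BF_P)` with common random numbers: each replicate's
#' patient outcomes are generated once and every threshold pair is evaluated
#' on them, with interim/final model fits shared between pairs that lead to
#' the same enrollment path.  Pairs with `BF_E <= BF_P` are skipped.
#'
#' @param scenario a [scenario_spec()].
#' @param design an [enrichment_design()] supplying stages and accrual; its
#'   thresholds are overridden by the grid values (`BF_E` is applied at
#'   every stage including the final, `BF_P` at the interims).
#' @param bf_e_grid,bf_p_grid candidate effectiveness / futility thresholds.
#' @param beta1,beta2 weights for [decision_score()].
#' @inheritParams operating_characteristics
#' @return A data.frame with one row per valid threshold pair: `bf_effective`,
#'   `bf_promising`, `fwer`, `conjunctive_power`, `disjunctive_power`, `en`
#'   and `score`.
#' @export
threshold_heatmap <- function(scenario, design, bf_e_grid, bf_p_grid,
                              beta1 = 1, beta2 = 0.5,
                              config = decision_config(),
                              sigma = 1, priors = bhm_priors(),
                              mcmc = sim_mcmc_settings(),
                              n_sim = 200, seed = 1L) {
  if (!length(bf_e_grid) || !length(bf_p_grid)) stop("threshold grids must be nonempty", call. = FALSE)
  pairs <- expand.grid(bf_effective = bf_e_grid, bf_promising = bf_p_grid)
  pairs <- pairs[pairs$bf_effective > pairs$bf_promising, , drop = FALSE]
  if (!nrow(pairs)) stop("no valid threshold pairs (need BF_E > BF_P)", call. = FALSE)
  designs <- lapply(seq_len(nrow(pairs)), function(i) {
    enrichment_design(design$grid, design$n_stages, design$accrual,
                      bf_effective = pairs$bf_effective[i],
                      bf_promising = pairs$bf_promising[i])
  })
  np <- nrow(pairs)
  rejections <- replicate(np, vector("list", n_sim), simplify = FALSE)
  en <- matrix(NA_real_, n_sim, np)
  for (r in seq_len(n_sim)) {
    rep_seed <- derive_seed(seed, r)
    stage_obs <- generate_stage_outcomes(scenario, design, sigma, rep_seed)
    cache <- new.env(parent = emptyenv())
    m <- mcmc; m$seed <- rep_seed
    for (i in seq_len(np)) {
      res <- run_enrichment_impl(stage_obs, designs[[i]], priors, m, config,
                                 sigma, bf_cache = cache)
      rejections[[i]][[r]] <- res$decisions$status == "effective"
      en[r, i] <- res$total_n
    }
  }
  out <- lapply(seq_len(np), function(i) {
    oc <- oc_from_rejections(rejections[[i]], scenario, en[, i], n_sim)
    data.frame(bf_effective = pairs$bf_effective[i],
               bf_promising = pairs$bf_promising[i],
               fwer = oc$fwer, conjunctive_power = oc$conjunctive_power,
               disjunctive_power = oc$disjunctive_power, en = oc$en,
               score = decision_score(oc$conjunctive_power,
                                      ifelse(is.na(oc$fwer), 0, oc$fwer),
                                      oc$en, design$n_max, beta1, beta2))
  })
  do.call(rbind, out)
}
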