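#' Decision configuration
#'
#' Thresholds and hypothesis settings shared by the decision rules.  The
#' hypotheses are one-sided per subgroup: H0 `theta_(k,j) <= theta0` against
#' H1 `theta_(k,j) > theta0`, with `theta0` the minimum acceptable treatment
#' effect (0 by default).  Under the packaged vague hierarchical priors the
#' two hypotheses carry equal prior probability, so `prior_odds = 1`.
#'
#' @param theta0 minimum acceptable treatment effect, analysis-scale units.
#' @param prior_odds prior odds Pr(H1)/Pr(H0) used in the Bayes factor.
#' @param bf_effective Bayes-factor threshold above which a subgroup is
#'   declared effective (`Inf` at an interim disables efficacy stopping).
#' @param bf_promising interim Bayes-factor threshold at or below which a
#'   subgroup is declared ineffective (futility); must be `< bf_effective`.
#' @param t_threshold t-statistic threshold for the frequentist comparator
#'   rules.
#' @return An object of class `decision_config`.
#' @export
decision_config <- function(theta0 = 0, prior_odds = 1,
                            bf_effective = 100, bf_promising = 10,
                            t_threshold = 2.9) {
  if (prior_odds <= 0) stop("prior_odds must be > 0", call. = FALSE)
  if (any(bf_promising < 0) || any(bf_effective <= bf_promising)) {
    stop("need bf_effective > bf_promising >= 0", call. = FALSE)
  }
  structure(list(theta0 = theta0, prior_odds = prior_odds,
                 bf_effective = bf_effective, bf_promising = bf_promising,
                 t_threshold = t_threshold),
            class = "decision_config")
}

#' Bayes factor for a one-sided subgroup hypothesis
#'
#' Estimates `p = Pr(theta > theta0 | data)` as the fraction of posterior
#' draws exceeding `theta0` and returns the ratio of posterior to prior odds
#' of the alternative, `(p / (1 - p)) / prior_odds`.  The exceedance fraction
#' is clipped to `[1/(M+1), M/(M+1)]` for `M` draws so the Bayes factor is
#' always finite; the clip tightens as the chain grows.
#'
#' @param draws numeric vector of at least 100 posterior draws of one
#'   subgroup effect.
#' @param theta0 minimum acceptable effect.
#' @param prior_odds prior odds Pr(H1)/Pr(H0).
#' @return The Bayes factor (positive scalar, monotone in the exceedance
#'   fraction).
#' @export
bayes_factor <- function(draws, theta0 = 0, prior_odds = 1) {
  if (length(draws) < 100) stop("need at least 100 draws", call. = FALSE)
  if (prior_odds <= 0) stop("prior_odds must be > 0", call. = FALSE)
  M <- length(draws)
  p <- mean(draws > theta0)
  p <- min(max(p, 1 / (M + 1)), M / (M + 1))
  (p / (1 - p)) / prior_odds
}

#' Per-subgroup Bayes factors from a model fit
#'
#' @param fit a `posterior_draws` object.
#' @inheritParams bayes_factor
#' @return A `K x J` matrix of Bayes factors.
#' @export
bayes_factor_grid <- function(fit, theta0 = 0, prior_odds = 1) {
  stopifnot(inherits(fit, "posterior_draws"))
  th <- fit$theta_subgroup
  M <- nrow(th)
  p <- colMeans(th > theta0)
  p <- pmin(pmax(p, 1 / (M + 1)), M / (M + 1))
  matrix((p / (1 - p)) / prior_odds, fit$grid$K, fit$grid$J)
}

new_decision_grid <- function(grid, status, statistic, pre_closure = status,
                              method = "ibis", thresholds = NULL) {
  structure(list(grid = grid, status = status, statistic = statistic,
                 pre_closure = pre_closure, method = method,
                 thresholds = thresholds),
            class = "decision_grid")
}

#' @export
print.decision_grid <- function(x, ...) {
  cat(sprintf("decision grid (%s): %d effective, %d promising, %d ineffective\n",
              x$method, sum(x$status == "effective"),
              sum(x$status == "promising"), sum(x$status == "ineffective")))
  s <- x$status
  dimnames(s) <- list(paste0("k", seq_len(nrow(s))), paste0("j", seq_len(ncol(s))))
  print(s, quote = FALSE)
  invisible(x)
}

#' Three-way interim classification from a Bayes-factor grid
#'
#' A subgroup is effective if its Bayes factor exceeds the stage's
#' `bf_effective`, ineffective if it does not exceed `bf_promising`, and
#' promising otherwise.  Monotone propagation ([monotone_closure()]) is then
#' applied.  Setting `bf_effective = Inf` disables interim efficacy stopping.
#'
#' @param bf_grid `K x J` matrix of Bayes factors.
#' @param config a [decision_config()]; `bf_effective`/`bf_promising` may be
#'   vectors indexed by `stage`.
#' @param stage 1-based analysis index selecting stage-specific thresholds.
#' @param closure apply monotone propagation (default `TRUE`).
#' @return A `decision_grid` with statuses in
#'   `{"effective", "promising", "ineffective"}`.
#' @export
classify_interim <- function(bf_grid, config, stage = 1L, closure = TRUE) {
  bf_grid <- as.matrix(bf_grid)
  be <- stage_value(config$bf_effective, stage)
  bp <- stage_value(config$bf_promising, stage)
  if (be <= bp) stop("need bf_effective > bf_promising", call. = FALSE)
  status <- matrix("promising", nrow(bf_grid), ncol(bf_grid))
  status[bf_grid > be] <- "effective"
  status[bf_grid <= bp] <- "ineffective"
  dg <- new_decision_grid(subgroup_grid(nrow(bf_grid), ncol(bf_grid)),
                          status, bf_grid, status, "ibis",
                          list(bf_effective = be, bf_promising = bp))
  if (closure) monotone_closure(dg) else dg
}

stage_value <- function(x, stage) if (length(x) >= stage) x[[stage]] else x[[length(x)]]

#' Monotone propagation of subgroup decisions
#'
#' Enforces marginal monotonicity on a decision grid: (i) an ineffective
#' subgroup lying in the upper set of any promising subgroup is upgraded to
#' promising; (ii) any non-effective subgroup lying in the upper set of an
#' effective subgroup is upgraded to effective.  At a final (binary)
#' analysis only rule (ii) applies.  The operation is idempotent and leaves
#' the effective region an up-set of the grid poset.
#'
#' @param decisions a `decision_grid`.
#' @param final apply only the effective-propagation rule (binary final
#'   analysis).
#' @return The closed `decision_grid` (with `pre_closure` preserved).
#' @export
monotone_closure <- function(decisions, final = FALSE) {
  stopifnot(inherits(decisions, "decision_grid"))
  s <- decisions$status
  if (!final) {
    prom_reach <- reach_from_below(s == "promising")
    s[s == "ineffective" & prom_reach] <- "promising"
  }
  eff_reach <- reach_from_below(decisions$status == "effective")
  s[eff_reach] <- "effective"
  decisions$status <- s
  decisions
}

# cells having at least one marked cell (weakly) below-left of them,
# i.e. the union of upper sets of the marked cells
reach_from_below <- function(marked) {
  K <- nrow(marked); J <- ncol(marked)
  r <- marked
  for (k in seq_len(K)) {
    for (j in seq_len(J)) {
      if (k > 1L) r[k, j] <- r[k, j] || r[k - 1L, j]
      if (j > 1L) r[k, j] <- r[k, j] || r[k, j - 1L]
    }
  }
  r
}

#' Independent per-subgroup t-test analysis
#'
#' The simplest comparator: each subgroup is analysed alone with the
#' one-sample t statistic `sqrt(n) * (Ybar - theta0) / s`, declared effective
#' when the statistic exceeds `t_threshold`, and (by default) monotone
#' propagation is applied as in the Bayesian rule.
#'
#' @param data a [trial_data()] with at least two patients per subgroup.
#' @param config a [decision_config()].
#' @param closure apply monotone propagation.
#' @return A binary `decision_grid` (statuses effective/ineffective) with the
#'   t statistics in `statistic`.
#' @export
decide_independent <- function(data, config = decision_config(), closure = TRUE) {
  stopifnot(inherits(data, "trial_data"))
  ss <- subgroup_summary(data)
  if (any(ss$n < 2)) stop("independent analysis needs n >= 2 in every subgroup", call. = FALSE)
  t_stat <- sqrt(ss$n) * (ss$mean - config$theta0) / ss$sd
  status <- matrix(ifelse(t_stat > config$t_threshold, "effective", "ineffective"),
                   nrow(t_stat), ncol(t_stat))
  dg <- new_decision_grid(data$grid, status, t_stat, status, "independent",
                          list(t_threshold = config$t_threshold))
  if (closure) monotone_closure(dg, final = TRUE) else dg
}

#' Frequentist partial-combination (subset-level) analysis
#'
#' For every candidate division, all member observations of the high-efficacy
#' subset are pooled and a one-sample t statistic against `theta0` is
#' computed; the division with the largest pooled statistic defines the
#' high-efficacy subset.  Pooled t tests are then performed on that subset
#' and on its complement with a common threshold, and each subset's decision
#' applies to all of its member subgroups.
#'
#' @inheritParams decide_independent
#' @return A binary `decision_grid`; `statistic` holds, for each subgroup,
#'   the pooled t statistic of the subset it belongs to.
#' @export
decide_freq <- function(data, config = decision_config()) {
  stopifnot(inherits(data, "trial_data"))
  ss <- subgroup_summary(data)
  if (any(ss$n < 2)) stop("pooled t analysis needs n >= 2 in every subgroup", call. = FALSE)
  res <- freq_subset_stats(data, config$theta0)
  status <- matrix("ineffective", data$grid$K, data$grid$J)
  stat <- matrix(res$t_low, data$grid$K, data$grid$J)
  stat[res$high] <- res$t_high
  if (res$t_high > config$t_threshold) status[res$high] <- "effective"
  if (res$t_low > config$t_threshold) status[!res$high] <- "effective"
  new_decision_grid(data$grid, status, stat, status, "freq",
                    list(t_threshold = config$t_threshold))
}

# pooled one-sample t over all observations in a cell set
pooled_t <- function(y, theta0) {
  n <- length(y)
  if (n < 2) return(-Inf)
  sqrt(n) * (mean(y) - theta0) / stats::sd(y)
}

freq_subset_stats <- function(data, theta0) {
  grid <- data$grid
  divs <- divisions_for(grid)
  cand <- divs[-length(divs)]
  obs <- data$observations
  cell <- (obs$j - 1L) * grid$K + obs$k
  t_g <- vapply(cand, function(d) {
    pooled_t(obs$y[d$high[cell]], theta0)
  }, numeric(1))
  best <- which.max(t_g)
  high <- cand[[best]]$high
  list(high = high, t_high = t_g[best],
       t_low = pooled_t(obs$y[!high[cell]], theta0), t_all = t_g)
}

#' Final-analysis subgroup identification with the two-subset model
#'
#' The full pipeline on accumulated data: select the optimal division by
#' posterior divergence, take per-subgroup posteriors under that division,
#' compute per-subgroup Bayes factors, declare a subgroup effective when its
#' Bayes factor exceeds `bf_effective` (final-stage value), and apply
#' monotone propagation.  No effectiveness claim is ever made at the subset
#' level: the division is a statistical device for information borrowing,
#' and inference stays per-subgroup.
#'
#' @inheritParams select_optimal_division
#' @param config a [decision_config()].
#' @return A binary `decision_grid` with the Bayes factors in `statistic`
#'   and the `division_selection` attached as attribute `"selection"`.
#' @export
decide_ibis_final <- function(data, priors = bhm_priors(),
                              mcmc = mcmc_settings(), config = decision_config(),
                              sigma = 1) {
  sel <- select_optimal_division(data, priors, mcmc, sigma)
  bf <- bayes_factor_grid(sel$chosen_fit, config$theta0, config$prior_odds)
  be <- stage_value(config$bf_effective, .Machine$integer.max)  # final value
  status <- matrix(ifelse(bf > be, "effective", "ineffective"),
                   data$grid$K, data$grid$J)
  dg <- new_decision_grid(data$grid, status, bf, status, "ibis",
                          list(bf_effective = be))
  dg <- monotone_closure(dg, final = TRUE)
  attr(dg, "selection") <- sel
  dg
}

#' Final-analysis decisions under the exchangeable comparator model
#'
#' Same Bayes-factor rule and monotone propagation as
#' [decide_ibis_final()], but with per-subgroup posteriors from the
#' exchangeable (all-subgroups) hierarchical model.
#'
#' @inheritParams decide_ibis_final
#' @return A binary `decision_grid`.
#' @export
decide_exchangeable <- function(data, priors = bhm_priors(),
                                mcmc = mcmc_settings(),
                                config = decision_config(), sigma = 1) {
  fit <- fit_exchangeable_bhm(data, priors, mcmc, sigma)
  bf <- bayes_factor_grid(fit, config$theta0, config$prior_odds)
  be <- stage_value(config$bf_effective, .Machine$integer.max)
  status <- matrix(ifelse(bf > be, "effective", "ineffective"),
                   data$grid$K, data$grid$J)
  dg <- new_decision_grid(data$grid, status, bf, status, "bhm",
                          list(bf_effective = be))
  monotone_closure(dg, final = TRUE)
}
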