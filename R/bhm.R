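#' Prior specification for the hierarchical models
#'
#' Vague defaults: the high-efficacy subset mean has a N(1, 1000) prior and
#' the low-efficacy subset mean a N(0, 1000) prior; both shrinkage variances
#' (the inter-subgroup variances that govern information borrowing within a
#' subset) carry IG(1e-3, 1e-3) priors.  The exchangeable (single-subset)
#' comparator pools all subgroups with a N(0, 1000) mean prior and the same
#' inverse-gamma shrinkage prior.
#'
#' @param mean_high,mean_low length-2 `c(location, variance)` of the normal
#'   priors on the subset-level mean effects.
#' @param shrink_high,shrink_low length-2 `c(shape, scale)` of the
#'   inverse-gamma priors on the subset shrinkage variances.
#' @param exchangeable_mean,exchangeable_shrink priors for the pooled
#'   exchangeable model.
#' @return An object of class `bhm_priors`.
#' @export
bhm_priors <- function(mean_high = c(1, 1000), mean_low = c(0, 1000),
                       shrink_high = c(1e-3, 1e-3), shrink_low = c(1e-3, 1e-3),
                       exchangeable_mean = c(0, 1000),
                       exchangeable_shrink = c(1e-3, 1e-3)) {
  chk <- function(x, nm, pos = 2L) {
    if (length(x) != 2L || any(!is.finite(x)) || any(x[pos] <= 0)) {
      stop(sprintf("'%s' must be length 2 with positive scale parameters", nm),
           call. = FALSE)
    }
  }
  chk(mean_high, "mean_high"); chk(mean_low, "mean_low")
  chk(shrink_high, "shrink_high", 1:2); chk(shrink_low, "shrink_low", 1:2)
  chk(exchangeable_mean, "exchangeable_mean")
  chk(exchangeable_shrink, "exchangeable_shrink", 1:2)
  structure(list(mean_high = mean_high, mean_low = mean_low,
                 shrink_high = shrink_high, shrink_low = shrink_low,
                 exchangeable_mean = exchangeable_mean,
                 exchangeable_shrink = exchangeable_shrink),
            class = "bhm_priors")
}

#' MCMC settings for the Gibbs samplers
#'
#' Defaults (5000 iterations, 2000 burn-in, one chain) are sized for a single
#' analysis; the simulation engine uses shorter chains (see the package
#' vignette for the Monte-Carlo error budget behind those sizes).
#'
#' @param n_iterations total Gibbs iterations per chain.
#' @param n_burnin burn-in iterations discarded (`< n_iterations`).
#' @param n_chains number of independent chains (concatenated after burn-in).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed applied at the start of a fit, or `NULL` to use
#'   the ambient RNG stream (the simulation engine's choice).
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iterations = 5000, n_burnin = 2000, n_chains = 1,
                          thin = 1, seed = NULL) {
  if (n_burnin < 0 || n_iterations <= n_burnin) {
    stop("need n_iterations > n_burnin >= 0", call. = FALSE)
  }
  if (n_chains < 1 || thin < 1) stop("n_chains and thin must be >= 1", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 n_chains = as.integer(n_chains),
                 thin = as.integer(thin), seed = seed),
            class = "mcmc_settings")
}

new_posterior_draws <- function(grid, theta, theta_high, theta_low,
                                var_high, var_low, division, model) {
  colnames(theta) <- paste0("theta_",
                            rep(seq_len(grid$K), times = grid$J), "_",
                            rep(seq_len(grid$J), each = grid$K))
  structure(list(grid = grid, theta_subgroup = theta,
                 theta_high = theta_high, theta_low = theta_low,
                 var_high = var_high, var_low = var_low,
                 division = division, model = model),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior draws (%s model): %d retained draws, %d subgroups\n",
              x$model, nrow(x$theta_subgroup), ncol(x$theta_subgroup)))
  invisible(x)
}

#' Fit the constrained two-subset Bayesian hierarchical model
#'
#' Given a division of the grid, subgroup effects are modelled as
#' exchangeable within the high-efficacy subset and, separately, within the
#' low-efficacy subset: `theta_(k,j) ~ N(theta_g, sigma_g^2)` for high
#' subgroups and `theta_(k,j) ~ N(theta_cg, sigma_cg^2)` for the complement,
#' with the likelihood `Ybar_(k,j) | theta_(k,j) ~ N(theta_(k,j),
#' sigma^2 / n_(k,j))` (known outcome variance).  The subset means are
#' ordered, `theta_g > theta_cg`, enforced by truncated-normal full
#' conditionals in an otherwise conjugate Gibbs sampler; this also removes
#' label switching.  Subgroups with no patients contribute no likelihood and
#' are drawn from their hierarchical conditional.
#'
#' @param data a [trial_data()].
#' @param division a [division()] with a nonempty low-efficacy set (use
#'   [fit_exchangeable_bhm()] for the full-population division).
#' @param priors a [bhm_priors()].
#' @param mcmc an [mcmc_settings()].
#' @param sigma known outcome standard deviation.
#' @return A `posterior_draws` object with per-subgroup effect draws
#'   (`theta_subgroup`, one column per subgroup in column-major `(k, j)`
#'   order), subset-level mean draws (`theta_high`, `theta_low`) and
#'   shrinkage-variance draws (`var_high`, `var_low`).
#' @export
fit_two_subset_bhm <- function(data, division, priors = bhm_priors(),
                               mcmc = mcmc_settings(), sigma = 1) {
  stopifnot(inherits(data, "trial_data"), inherits(division, "division"))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!all(dim(division$high) == c(data$grid$K, data$grid$J))) {
    stop("division grid does not match the data grid", call. = FALSE)
  }
  if (all(division$high)) {
    stop("two-subset model needs a nonempty low-efficacy set; ",
         "use fit_exchangeable_bhm() for the full-population division",
         call. = FALSE)
  }
  ss <- subgroup_summary(data)
  ybar <- as.vector(ss$mean); ybar[is.na(ybar)] <- 0
  n <- as.vector(ss$n)
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  chains <- lapply(seq_len(mcmc$n_chains), function(ch) {
    .gibbs_two_subset(ybar, n, as.vector(division$high), sigma^2,
                      priors$mean_high[1], priors$mean_high[2],
                      priors$mean_low[1], priors$mean_low[2],
                      priors$shrink_high[1], priors$shrink_high[2],
                      priors$shrink_low[1], priors$shrink_low[2],
                      mcmc$n_iterations, mcmc$n_burnin, mcmc$thin, TRUE)
  })
  new_posterior_draws(
    data$grid,
    do.call(rbind, lapply(chains, `[[`, "theta")),
    unlist(lapply(chains, `[[`, "theta_high")),
    unlist(lapply(chains, `[[`, "theta_low")),
    unlist(lapply(chains, `[[`, "var_high")),
    unlist(lapply(chains, `[[`, "var_low")),
    division, "two_subset")
}

#' Fit the exchangeable (single-subset) Bayesian hierarchical model
#'
#' The comparator model that borrows information across all subgroups at
#' once: `theta_(k,j) ~ N(theta_pool, sigma_pool^2)` with a vague normal
#' prior on the pooled mean and an inverse-gamma prior on the pooled
#' shrinkage variance.
#'
#' @inheritParams fit_two_subset_bhm
#' @return A `posterior_draws` object; the pooled mean and variance draws are
#'   stored in `theta_high`/`var_high` (with `theta_low`/`var_low` `NULL` and
#'   `division` `NULL`).
#' @export
fit_exchangeable_bhm <- function(data, priors = bhm_priors(),
                                 mcmc = mcmc_settings(), sigma = 1) {
  stopifnot(inherits(data, "trial_data"))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  ss <- subgroup_summary(data)
  ybar <- as.vector(ss$mean); ybar[is.na(ybar)] <- 0
  n <- as.vector(ss$n)
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  chains <- lapply(seq_len(mcmc$n_chains), function(ch) {
    .gibbs_exchangeable(ybar, n, sigma^2,
                        priors$exchangeable_mean[1], priors$exchangeable_mean[2],
                        priors$exchangeable_shrink[1], priors$exchangeable_shrink[2],
                        mcmc$n_iterations, mcmc$n_burnin, mcmc$thin)
  })
  new_posterior_draws(
    data$grid,
    do.call(rbind, lapply(chains, `[[`, "theta")),
    unlist(lapply(chains, `[[`, "theta_pool")), NULL,
    unlist(lapply(chains, `[[`, "var_pool")), NULL,
    NULL, "exchangeable")
}

#' @export
#' @describeIn fit_two_subset_bhm flatten posterior draws to a data.frame
#'   (one column per parameter), ready for `write.csv()`.
#' @param x a `posterior_draws` object.
#' @param ... unused.
as.data.frame.posterior_draws <- function(x, ...) {
  out <- as.data.frame(x$theta_subgroup)
  if (!is.null(x$theta_high)) out$theta_high <- x$theta_high
  if (!is.null(x$theta_low)) out$theta_low <- x$theta_low
  if (!is.null(x$var_high)) out$var_high <- x$var_high
  if (!is.null(x$var_low)) out$var_low <- x$var_low
  out
}

#' Per-subgroup posterior summaries
#'
#' Posterior mean and equal-tailed credible interval from the empirical
#' quantiles of the retained draws.
#'
#' @param draws a `posterior_draws` object.
#' @param level credibility level in (0, 1); default 0.95.
#' @return A data.frame with columns `k`, `j`, `mean`, `lower`, `upper`.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  th <- draws$theta_subgroup
  if (!nrow(th)) stop("no retained draws", call. = FALSE)
  q <- c((1 - level) / 2, 1 - (1 - level) / 2)
  K <- draws$grid$K; J <- draws$grid$J
  qs <- apply(th, 2, stats::quantile, probs = q, names = FALSE)
  data.frame(k = rep(seq_len(K), times = J), j = rep(seq_len(J), each = K),
             mean = colMeans(th), lower = qs[1, ], upper = qs[2, ],
             row.names = NULL)
}
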