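#' Multi-stage adaptive enrichment design
#'
#' Describes a design with `n_stages` analyses (`n_stages - 1` interims plus
#' one final): per-stage per-subgroup accrual, interim efficacy/futility
#' Bayes-factor thresholds, and the final effectiveness threshold.  The
#' packaged reference design on a 3 x 4 grid is two stages of 5 patients per
#' subgroup per stage, giving a maximum sample size of 120.
#'
#' @param grid a [subgroup_grid()].
#' @param n_stages total number of analyses `I >= 2`.
#' @param accrual per-stage per-subgroup accrual: a scalar, a `K x J` matrix
#'   (same every stage), or a `K x J x I` array.
#' @param bf_effective effectiveness thresholds, recycled to length
#'   `n_stages`; interim entries may be `Inf` to disable efficacy stopping.
#' @param bf_promising interim futility thresholds, recycled to length
#'   `n_stages - 1`; a subgroup with Bayes factor at or below this stops for
#'   futility.
#' @return An object of class `enrichment_design` (with derived `n_max`, the
#'   total sample size if every subgroup runs all stages).
#' @export
enrichment_design <- function(grid, n_stages = 2, accrual = 5,
                              bf_effective = 100, bf_promising = 10) {
  grid <- as_grid(grid)
  n_stages <- as.integer(n_stages)
  if (n_stages < 2) stop("n_stages must be >= 2", call. = FALSE)
  K <- grid$K; J <- grid$J
  acc <- array(NA_integer_, c(K, J, n_stages))
  if (length(accrual) == 1L) {
    acc[] <- as.integer(accrual)
  } else if (is.matrix(accrual)) {
    if (!all(dim(accrual) == c(K, J))) stop("accrual matrix must be K x J", call. = FALSE)
    for (i in seq_len(n_stages)) acc[, , i] <- as.integer(accrual)
  } else {
    if (!all(dim(accrual) == c(K, J, n_stages))) {
      stop("accrual array must be K x J x n_stages", call. = FALSE)
    }
    acc[] <- as.integer(accrual)
  }
  if (any(acc < 0)) stop("accrual must be >= 0", call. = FALSE)
  be <- rep_len(bf_effective, n_stages)
  bp <- rep_len(bf_promising, n_stages - 1L)
  if (any(bp < 0) || any(be[seq_len(n_stages - 1L)] <= bp)) {
    stop("need bf_effective > bf_promising >= 0 at every interim", call. = FALSE)
  }
  structure(list(grid = grid, n_stages = n_stages, accrual = acc,
                 bf_effective = be, bf_promising = bp, n_max = sum(acc)),
            class = "enrichment_design")
}

#' @export
print.enrichment_design <- function(x, ...) {
  cat(sprintf("%d-stage enrichment design on a %d x %d grid, N_max = %d\n",
              x$n_stages, x$grid$K, x$grid$J, x$n_max))
  cat("BF_E by stage:", paste(format(x$bf_effective), collapse = ", "), "\n")
  cat("BF_P (interims):", paste(format(x$bf_promising), collapse = ", "), "\n")
  invisible(x)
}

#' Run one adaptive enrichment trial
#'
#' Simulates a multi-stage trial under a scenario: at each stage, patients
#' accrue only to subgroups still open (promising); all accumulated data --
#' including data from subgroups already closed for efficacy or futility --
#' enter the interim analysis, which selects the optimal division, fits the
#' two-subset model, computes per-subgroup Bayes factors, and classifies the
#' open subgroups as effective / promising / ineffective with monotone
#' propagation.  Interim decisions are binding.  The whole trial stops early
#' when no subgroup is promising; otherwise the final analysis applies the
#' binary effectiveness rule to the subgroups still open.
#'
#' When `mcmc$seed` is set, the analysis at stage `i` seeds the sampler at
#' `mcmc$seed + i`, making the trial fully reproducible.
#'
#' @param scenario a [scenario_spec()] on the design's grid.
#' @param design an [enrichment_design()].
#' @param priors a [bhm_priors()].
#' @param mcmc an [mcmc_settings()].
#' @param config a [decision_config()] (supplies `theta0` and `prior_odds`;
#'   the stage thresholds come from the design).
#' @param sigma known outcome standard deviation.
#' @param seed integer seed for patient outcome generation.
#' @return An object of class `trial_result`: `decisions` (final binary
#'   [`decision_grid`][classify_interim]), `stages` (per-stage Bayes factors
#'   and status snapshots), `n_per_subgroup`, `total_n`, `stop_stage` (`NA`
#'   if the trial reached the final analysis) and `data` (the accumulated
#'   [trial_data()]).
#' @export
run_enrichment_trial <- function(scenario, design, priors = bhm_priors(),
                                 mcmc = mcmc_settings(), config = decision_config(),
                                 sigma = 1, seed = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(design, "enrichment_design"))
  if (!identical(unclass(scenario$grid), unclass(design$grid))) {
    stop("scenario and design grids differ", call. = FALSE)
  }
  stage_obs <- generate_stage_outcomes(scenario, design, sigma, seed)
  run_enrichment_impl(stage_obs, design, priors, mcmc, config, sigma)
}

generate_stage_outcomes <- function(scenario, design, sigma, seed) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(design$n_stages), function(i) {
    generate_trial_data(scenario, design$accrual[, , i], sigma,
                        seed = NULL, stage = i)$observations
  })
}

run_enrichment_impl <- function(stage_obs, design, priors, mcmc, config, sigma,
                                bf_cache = NULL) {
  grid <- design$grid
  K <- grid$K; J <- grid$J
  status <- matrix("promising", K, J)   # open until decided
  decided <- matrix(FALSE, K, J)
  data <- trial_data(grid)
  n_acc <- matrix(0L, K, J)
  stages <- vector("list", design$n_stages)
  stop_stage <- NA_integer_
  bf <- matrix(NA_real_, K, J)
  for (i in seq_len(design$n_stages)) {
    open <- !decided
    obs <- stage_obs[[i]]
    keep <- open[cbind(obs$k, obs$j)]
    if (any(keep)) data <- append_observations(data, obs[keep, , drop = FALSE])
    n_acc <- n_acc + design$accrual[, , i] * open
    bf <- enrichment_bf(data, priors, mcmc, config, sigma, stage = i,
                        open = open, bf_cache = bf_cache)
    if (i < design$n_stages) {
      be <- design$bf_effective[i]; bp <- design$bf_promising[i]
      status[open & bf > be] <- "effective"
      status[open & bf <= bp] <- "ineffective"
      status[open & bf <= be & bf > bp] <- "promising"
      dg <- new_decision_grid(grid, status, bf, method = "ibis")
      status <- monotone_closure(dg)$status
      decided <- status != "promising"
      stages[[i]] <- list(bf = bf, status = status, open = open)
      if (all(decided)) { stop_stage <- i; break }
    } else {
      be <- design$bf_effective[i]
      status[open] <- ifelse(bf[open] > be, "effective", "ineffective")
      dg <- new_decision_grid(grid, status, bf, method = "ibis")
      status <- monotone_closure(dg, final = TRUE)$status
      stages[[i]] <- list(bf = bf, status = status, open = open)
    }
  }
  final <- new_decision_grid(grid, status, bf, method = "ibis",
                             thresholds = list(bf_effective = design$bf_effective,
                                               bf_promising = design$bf_promising))
  structure(list(decisions = final, stages = stages,
                 n_per_subgroup = n_acc, total_n = sum(n_acc),
                 stop_stage = stop_stage, data = data),
            class = "trial_result")
}

# Bayes factors for one enrichment analysis, optionally memoised on the open
# set (analyses with identical accrual history see identical data under
# common random numbers, so threshold scans can share fits)
enrichment_bf <- function(data, priors, mcmc, config, sigma, stage, open,
                          bf_cache = NULL) {
  key <- paste0("s", stage, "|", paste(as.integer(open), collapse = ""))
  if (!is.null(bf_cache) && !is.null(bf_cache[[key]])) return(bf_cache[[key]])
  m <- mcmc
  if (!is.null(m$seed)) m$seed <- m$seed + stage
  sel <- select_optimal_division(data, priors, m, sigma)
  bf <- bayes_factor_grid(sel$chosen_fit, config$theta0, config$prior_odds)
  if (!is.null(bf_cache)) bf_cache[[key]] <- bf
  bf
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("enrichment trial: total n = %d%s\n", x$total_n,
              if (!is.na(x$stop_stage)) sprintf(", stopped early at stage %d", x$stop_stage) else ""))
  print(x$decisions)
  invisible(x)
}
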