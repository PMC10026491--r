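#' Endpoint transform to the exchangeable analysis scale
#'
#' Maps the natural parameter of a one-parameter exponential-family endpoint
#' onto the unbounded scale on which subgroup effects are modelled as
#' exchangeable normals: identity for a normal endpoint (e.g. log tumour-size
#' ratio), logit for a Bernoulli response rate, log for exponential survival
#' and Poisson count endpoints.
#'
#' Only the normal family is fitted by the hierarchical model in this
#' package; the other transforms are provided as utilities.
#'
#' @param family one of `"normal"`, `"bernoulli"`, `"exponential"`,
#'   `"poisson"`.
#' @param psi natural parameter value(s); must lie in the family's domain
#'   (`(0, 1)` for bernoulli, `> 0` for exponential/poisson).
#' @return The transformed effect(s) `h(psi)`.
#' @examples
#' endpoint_transform("bernoulli", 0.5)  # 0
#' endpoint_transform("normal", 1.3)     # 1.3
#' @export
endpoint_transform <- function(family = c("normal", "bernoulli", "exponential", "poisson"),
                               psi) {
  family <- match.arg(family)
  switch(family,
    normal = psi,
    bernoulli = {
      if (any(psi <= 0 | psi >= 1)) stop("bernoulli parameter must be in (0, 1)", call. = FALSE)
      log(psi / (1 - psi))
    },
    exponential = ,
    poisson = {
      if (any(psi <= 0)) stop(sprintf("%s parameter must be > 0", family), call. = FALSE)
      log(psi)
    })
}

#' Define a simulation scenario
#'
#' A scenario fixes the true per-subgroup treatment effects on the analysis
#' scale together with the set of subgroups counted as true alternatives
#' (clinically meaningful effect) when scoring error rates and power.
#'
#' @param theta numeric `K x J` matrix of true transformed effects.
#' @param alternative_mask logical `K x J` matrix marking the subgroups
#'   scored as alternatives in power metrics; defaults to `theta >= 1` (the
#'   packaged convention: a clinically meaningful effect equals 1).
#' @param null_mask logical `K x J` matrix marking the subgroups whose null
#'   hypothesis is true, scored in the family-wise error rate; defaults to
#'   `theta <= 0` (the minimum acceptable effect).  Subgroups in neither mask
#'   (effects between the minimum acceptable and the clinically meaningful
#'   level) enter neither metric.
#' @param name scenario label.
#' @return An object of class `scenario_spec` with elements `grid`, `theta`,
#'   `alternative_mask`, `null_mask` and `name`.
#' @export
scenario_spec <- function(theta, alternative_mask = theta >= 1,
                          null_mask = theta <= 0, name = "custom") {
  theta <- as.matrix(theta)
  grid <- subgroup_grid(nrow(theta), ncol(theta))
  alternative_mask <- as.matrix(alternative_mask)
  null_mask <- as.matrix(null_mask)
  if (!all(dim(alternative_mask) == dim(theta)) ||
      !all(dim(null_mask) == dim(theta))) {
    stop("alternative_mask and null_mask must have the same K x J shape as theta",
         call. = FALSE)
  }
  if (any(alternative_mask & null_mask)) {
    stop("a subgroup cannot be both null and alternative", call. = FALSE)
  }
  structure(list(grid = grid, theta = unname(theta),
                 alternative_mask = unname(alternative_mask != 0),
                 null_mask = unname(null_mask != 0), name = name),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario '%s' on a %d x %d grid\n", x$name, x$grid$K, x$grid$J))
  th <- x$theta
  dimnames(th) <- list(paste0("k", seq_len(nrow(th))), paste0("j", seq_len(ncol(th))))
  print(th)
  cat(sprintf("alternative subgroups: %d; null subgroups: %d (of %d)\n",
              sum(x$alternative_mask), sum(x$null_mask), length(x$theta)))
  invisible(x)
}

#' The packaged library of eight 3 x 4 simulation scenarios
#'
#' True effect matrices for twelve subgroups (three Biomarker1 levels by four
#' Biomarker2 levels) covering the canonical benchmark profiles: global null,
#' global alternative, a single "good nugget" high-efficacy subgroup, a single
#' "bad nugget" low-efficacy subgroup, mostly-null, mostly-alternative,
#' half-alternative staircase, and a linear effect gradient.  Effects are on
#' the analysis scale with the clinically meaningful effect equal to 1;
#' subgroups with effect >= 1 are flagged as alternatives and subgroups with
#' effect <= 0 as true nulls (cells in between enter neither power nor
#' error-rate metrics).
#'
#' @return Named list of eight [scenario_spec()] objects
#'   (`scenario1` ... `scenario8`).
#' @examples
#' scenario_library()$scenario3$theta
#' @export
scenario_library <- function() {
  by_row <- function(...) matrix(c(...), nrow = 3, ncol = 4, byrow = TRUE)
  th <- list(
    scenario1 = by_row(0, 0, 0, 0,
                       0, 0, 0, 0,
                       0, 0, 0, 0),
    scenario2 = by_row(1, 1, 1, 1,
                       1, 1, 1, 1,
                       1, 1, 1, 1),
    scenario3 = by_row(0, 0, 0, 0,
                       0, 0, 0, 0,
                       0, 0, 0, 1),
    scenario4 = by_row(0, 1, 1, 1,
                       1, 1, 1, 1,
                       1, 1, 1, 1),
    scenario5 = by_row(0, 0, 0, 0,
                       0, 0, 1, 1,
                       0, 0, 1, 1),
    scenario6 = by_row(0, 0, 1, 1,
                       0, 0, 1, 1,
                       1, 1, 1, 1),
    scenario7 = by_row(0, 0, 0, 1,
                       0, 0, 1, 1,
                       0, 1, 1, 1),
    scenario8 = by_row(0,    0.25, 0.5,  1,
                       0.25, 0.5,  1,    1.25,
                       0.5,  1,    1.25, 1.5))
  labels <- c("global null", "global alternative", "good nugget", "bad nugget",
              "mostly null", "mostly alternative", "half alternative", "linear")
  out <- mapply(function(m, nm) scenario_spec(m, name = nm), th, labels,
                SIMPLIFY = FALSE)
  names(out) <- names(th)
  out
}

#' Per-patient trial data on the analysis scale
#'
#' Holds one outcome row per patient with the subgroup indices `(k, j)`.
#' Outcomes are already on the transformed analysis scale (for the packaged
#' tumour-size endpoint, minus the log size ratio), modelled as normal with
#' per-subgroup mean and known variance.  Data from multiple trial stages
#' accumulate additively; an optional `stage` column records accrual stage.
#'
#' @param grid a [subgroup_grid()].
#' @param observations data.frame with numeric columns `k`, `j`, `y` (and
#'   optionally `stage`); may have zero rows.
#' @return An object of class `trial_data`.
#' @export
trial_data <- function(grid, observations = data.frame(k = integer(), j = integer(),
                                                       y = numeric())) {
  grid <- as_grid(grid)
  obs <- as.data.frame(observations)
  if (!all(c("k", "j", "y") %in% names(obs))) {
    stop("observations must have columns k, j, y", call. = FALSE)
  }
  if (nrow(obs) && (any(obs$k < 1 | obs$k > grid$K) || any(obs$j < 1 | obs$j > grid$J))) {
    stop("subgroup indices out of grid bounds", call. = FALSE)
  }
  if (is.null(obs$stage)) obs$stage <- rep(1L, nrow(obs))
  structure(list(grid = grid, observations = obs), class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("trial data: %d patients on a %d x %d grid\n",
              nrow(x$observations), x$grid$K, x$grid$J))
  print(subgroup_summary(x)$n)
  invisible(x)
}

#' Append observations to accumulated trial data
#' @param data a [trial_data()].
#' @param observations data.frame with columns `k`, `j`, `y` and optionally
#'   `stage`.
#' @return The updated `trial_data`.
#' @export
append_observations <- function(data, observations) {
  stopifnot(inherits(data, "trial_data"))
  add <- trial_data(data$grid, observations)$observations
  data$observations <- rbind(data$observations, add)
  data
}

#' Per-subgroup summary statistics
#'
#' @param data a [trial_data()].
#' @return List of `K x J` matrices: `n` (patient counts), `mean` (sample
#'   means, `NA` where `n = 0`), `sd` (sample standard deviations, `NA` where
#'   `n < 2`).
#' @export
subgroup_summary <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  K <- data$grid$K; J <- data$grid$J
  n <- matrix(0L, K, J); m <- matrix(NA_real_, K, J); s <- matrix(NA_real_, K, J)
  obs <- data$observations
  if (nrow(obs)) {
    idx <- (obs$j - 1L) * K + obs$k
    cnt <- tabulate(idx, nbins = K * J)
    n[] <- cnt
    sums <- vapply(seq_len(K * J), function(i) sum(obs$y[idx == i]), numeric(1))
    m[] <- ifelse(cnt > 0, sums / pmax(cnt, 1), NA_real_)
    for (i in which(cnt >= 2L)) s[i] <- stats::sd(obs$y[idx == i])
  }
  list(n = n, mean = m, sd = s)
}

#' Generate seeded synthetic trial data under a scenario
#'
#' Draws, for each subgroup, independent normal outcomes on the analysis
#' scale with mean equal to the scenario's true effect and common known
#' standard deviation `sigma`.
#'
#' @param scenario a [scenario_spec()].
#' @param n_per_subgroup integer scalar or `K x J` matrix of patient counts
#'   (>= 0).
#' @param sigma known outcome standard deviation (> 0).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param stage stage label stored with the observations.
#' @return A [trial_data()] object.
#' @examples
#' d <- generate_trial_data(scenario_library()$scenario2, 10, sigma = 1, seed = 7)
#' subgroup_summary(d)$n
#' @export
generate_trial_data <- function(scenario, n_per_subgroup = 10, sigma = 1,
                                seed = NULL, stage = 1L) {
  stopifnot(inherits(scenario, "scenario_spec"))
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  K <- scenario$grid$K; J <- scenario$grid$J
  n <- n_per_subgroup
  if (length(n) == 1L) n <- matrix(n, K, J)
  n <- matrix(as.integer(n), K, J)
  if (any(n < 0)) stop("n_per_subgroup must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", K * J)
  for (k in seq_len(K)) {
    for (j in seq_len(J)) {
      nn <- n[k, j]
      if (nn > 0L) {
        rows[[(j - 1L) * K + k]] <- data.frame(
          k = k, j = j, y = stats::rnorm(nn, scenario$theta[k, j], sigma),
          stage = stage)
      }
    }
  }
  trial_data(scenario$grid, do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Read / write per-patient trial data as CSV
#'
#' The on-disk format is one row per patient with columns `k`, `j`, `y`
#' (and optionally `stage`).
#'
#' @param path file path.
#' @param grid a [subgroup_grid()]; if `NULL` on read, the grid is inferred
#'   from the maximum observed levels.
#' @return `read_trial_data` returns a [trial_data()];
#'   `write_trial_data` returns `path` invisibly.
#' @export
read_trial_data <- function(path, grid = NULL) {
  obs <- utils::read.csv(path)
  if (is.null(grid)) grid <- subgroup_grid(max(obs$k), max(obs$j))
  trial_data(grid, obs)
}

#' @rdname read_trial_data
#' @param data a [trial_data()].
#' @export
write_trial_data <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  utils::write.csv(data$observations, path, row.names = FALSE)
  invisible(path)
}
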