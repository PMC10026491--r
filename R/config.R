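#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration describing a reproducible run:
#' grid/scenario, method, model and decision settings, simulation sizes and
#' the master seed.  Unknown keys and shape mismatches are rejected with the
#' offending key named; every stochastic verb requires an explicit `seed`.
#'
#' Recognised keys: `seed`, `grid` (`K`, `J`), `scenario` (a
#' [scenario_library()] name, or inline with `theta` and optional
#' `alternative_mask`/`null_mask`/`name`), `method`, `sigma`, `n_per_subgroup`, `n_sim`,
#' `theta0`, `prior_odds`, `bf_effective`, `bf_promising`, `t_threshold`,
#' `mcmc`, `priors`, `design` (`n_stages`, `accrual`, `bf_effective`,
#' `bf_promising`), `calibration` (`fwer_cap`, `threshold_grid`), `heatmap`
#' (`bf_e_grid`, `bf_p_grid`, `beta1`, `beta2`), `output`.
#'
#' @param path configuration file path.
#' @return An object of class `run_config` (a validated list with defaults
#'   applied).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("seed", "grid", "scenario", "method", "sigma", "n_per_subgroup",
             "n_sim", "theta0", "prior_odds", "bf_effective", "bf_promising",
             "t_threshold", "mcmc", "priors", "design", "calibration",
             "heatmap", "output")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  }
  cfg <- raw
  if (!is.null(cfg$grid)) {
    if (is.null(cfg$grid$K) || is.null(cfg$grid$J)) {
      stop("config key 'grid' needs K and J", call. = FALSE)
    }
    cfg$grid <- subgroup_grid(cfg$grid$K, cfg$grid$J)
  }
  if (!is.null(cfg$scenario)) {
    if (is.character(cfg$scenario)) {
      lib <- scenario_library()
      if (!cfg$scenario %in% names(lib)) {
        stop(sprintf("config key 'scenario': unknown scenario '%s'", cfg$scenario),
             call. = FALSE)
      }
      cfg$scenario <- lib[[cfg$scenario]]
    } else {
      if (is.null(cfg$scenario$theta)) {
        stop("config key 'scenario': inline scenario needs 'theta'", call. = FALSE)
      }
      theta <- do.call(rbind, cfg$scenario$theta)
      if (!is.null(cfg$grid) &&
          !all(dim(theta) == c(cfg$grid$K, cfg$grid$J))) {
        stop("config key 'scenario': theta matrix is not K x J", call. = FALSE)
      }
      mask <- if (!is.null(cfg$scenario$alternative_mask)) {
        do.call(rbind, cfg$scenario$alternative_mask)
      } else theta >= 1
      nmask <- if (!is.null(cfg$scenario$null_mask)) {
        do.call(rbind, cfg$scenario$null_mask)
      } else theta <= 0
      cfg$scenario <- scenario_spec(theta, mask, nmask,
                                    name = cfg$scenario$name %||% "inline")
    }
    if (is.null(cfg$grid)) cfg$grid <- cfg$scenario$grid
  }
  cfg$sigma <- cfg$sigma %||% 1
  cfg$n_per_subgroup <- cfg$n_per_subgroup %||% 10
  cfg$n_sim <- cfg$n_sim %||% 500
  cfg$method <- cfg$method %||% "ibis"
  cfg$priors <- do.call(bhm_priors, as_pairlists(cfg$priors))
  cfg$mcmc <- do.call(sim_mcmc_settings, cfg$mcmc %||% list())
  cfg$decision <- decision_config(
    theta0 = cfg$theta0 %||% 0, prior_odds = cfg$prior_odds %||% 1,
    bf_effective = cfg$bf_effective %||% 100,
    bf_promising = cfg$bf_promising %||% 10,
    t_threshold = cfg$t_threshold %||% 2.9)
  if (!is.null(cfg$design)) {
    if (is.null(cfg$grid)) stop("config key 'design' needs a grid or scenario", call. = FALSE)
    d <- cfg$design
    cfg$design <- enrichment_design(
      cfg$grid, n_stages = d$n_stages %||% 2, accrual = d$accrual %||% 5,
      bf_effective = unlist(d$bf_effective) %||% (cfg$bf_effective %||% 100),
      bf_promising = unlist(d$bf_promising) %||% (cfg$bf_promising %||% 10))
  }
  cfg$hash <- config_hash(raw)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_pairlists <- function(x) if (is.null(x)) list() else lapply(x, unlist)

# polynomial rolling hash of the deparsed raw config, for output provenance
# headers (stays in double-precision-exact integer range)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Execute a configured command
#'
#' Dispatches one of the package's run verbs on a loaded configuration and
#' (when `config$output` is set) writes the result atomically as JSON/CSV
#' with a provenance header (config hash and master seed).
#'
#' Verbs: `"enumerate"` (division enumeration), `"run-trial"` (one adaptive
#' enrichment trial), `"simulate-oc"` (operating characteristics),
#' `"calibrate"` (threshold calibration), `"heatmap"` (threshold-grid
#' operating characteristics), `"estimation"` (estimation metrics).
#'
#' @param verb one of the run verbs above.
#' @param config a [load_config()] result.
#' @return The computed result object, invisibly when written to disk.
#' @export
run_command <- function(verb = c("enumerate", "run-trial", "simulate-oc",
                                 "calibrate", "heatmap", "estimation"),
                        config) {
  verb <- match.arg(verb)
  stopifnot(inherits(config, "run_config"))
  if (verb != "enumerate" && is.null(config$seed)) {
    stop("stochastic commands require an explicit 'seed' in the config", call. = FALSE)
  }
  need <- function(key) {
    if (is.null(config[[key]])) {
      stop(sprintf("verb '%s' requires config key '%s'", verb, key), call. = FALSE)
    }
    config[[key]]
  }
  result <- switch(verb,
    "enumerate" = {
      divs <- enumerate_divisions(need("grid"))
      list(count = length(divs),
           divisions = lapply(divs, function(d) unname(apply(d$high, 1, as.integer, simplify = FALSE))))
    },
    "run-trial" = {
      res <- run_enrichment_trial(need("scenario"), need("design"),
                                  config$priors, config$mcmc, config$decision,
                                  config$sigma, seed = config$seed)
      list(status = res$decisions$status, bayes_factors = res$decisions$statistic,
           n_per_subgroup = res$n_per_subgroup, total_n = res$total_n,
           stop_stage = res$stop_stage)
    },
    "simulate-oc" = {
      oc <- operating_characteristics(need("scenario"), config$method,
                                      config$decision, design = config$design,
                                      n_per_subgroup = config$n_per_subgroup,
                                      sigma = config$sigma, priors = config$priors,
                                      mcmc = config$mcmc, n_sim = config$n_sim,
                                      seed = config$seed)
      unclass(oc)
    },
    "calibrate" = {
      cal <- need("calibration")
      calibrate_threshold(config$method, need("scenario"),
                          fwer_cap = cal$fwer_cap,
                          threshold_grid = unlist(cal$threshold_grid),
                          config = config$decision,
                          n_per_subgroup = config$n_per_subgroup,
                          sigma = config$sigma, priors = config$priors,
                          mcmc = config$mcmc, n_sim = config$n_sim,
                          seed = config$seed)
    },
    "heatmap" = {
      hm <- need("heatmap")
      threshold_heatmap(need("scenario"), need("design"),
                        bf_e_grid = unlist(hm$bf_e_grid),
                        bf_p_grid = unlist(hm$bf_p_grid),
                        beta1 = hm$beta1 %||% 1, beta2 = hm$beta2 %||% 0.5,
                        config = config$decision, sigma = config$sigma,
                        priors = config$priors, mcmc = config$mcmc,
                        n_sim = config$n_sim, seed = config$seed)
    },
    "estimation" = {
      estimation_study(need("scenario"), config$method,
                       n_per_subgroup = config$n_per_subgroup,
                       sigma = config$sigma, priors = config$priors,
                       mcmc = config$mcmc, n_sim = config$n_sim,
                       seed = config$seed)
    })
  if (!is.null(config$output)) {
    write_result_atomic(result, config, verb)
    return(invisible(result))
  }
  result
}

write_result_atomic <- function(result, config, verb) {
  payload <- list(verb = verb, config_hash = config$hash,
                  seed = config$seed, result = result)
  tmp <- tempfile(tmpdir = dirname(config$output))
  if (grepl("[.]csv$", config$output) && is.data.frame(result)) {
    hdr <- sprintf("# verb=%s config_hash=%s seed=%s", verb, config$hash,
                   config$seed %||% "none")
    writeLines(hdr, tmp)
    suppressWarnings(utils::write.table(result, tmp, append = TRUE, sep = ",",
                                        row.names = FALSE, quote = FALSE))
  } else {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  }
  file.rename(tmp, config$output)
  invisible(config$output)
}
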