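# Per-replicate (and per-sweep-cell) seeds are drawn once from the master
# seed, so runs are reproducible end to end and replicates stay independent
# however the work is scheduled.
replicate_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Run replicate cohorts through the estimators
#'
#' Simulates `n_replicates` independent cohorts under `config` (replicate
#' seeds derived from `config$seed`), fits the requested estimators to
#' each, and summarizes the hazard-ratio estimates by their median and
#' quartiles. Replicates whose estimate is non-finite or whose fit did not
#' converge are excluded from the summary and counted in `n_failed`; more
#' than 10% failures raises a warning.
#'
#' @param config A [scenario_config()]; its `seed` is the master seed.
#' @param n_replicates Number of replicate cohorts (the reference design
#'   uses 1000 replicates of 10,000 subjects).
#' @param estimators Subset of `c("poisson", "poisson_adjusted", "cox")`.
#' @param k_intervals Event-quantile intervals for `"poisson_adjusted"`.
#' @param return_estimates Attach the per-replicate estimate table as
#'   attribute `"estimates"` of the summary.
#' @return A data frame with one row per estimator: `estimator`,
#'   `median_rr`, `q1_rr`, `q3_rr`, `n_replicates`, `n_failed`,
#'   `realized_prevalence` (mean over replicates).
#' @examples
#' cfg <- scenario_preset("A", rr_t = 0.75, n_subjects = 2000, seed = 3)
#' run_replicates(cfg, n_replicates = 20)
#' @export
run_replicates <- function(config, n_replicates = 1000L,
                           estimators = "poisson", k_intervals = 10L,
                           return_estimates = FALSE) {
  stopifnot(inherits(config, "scenario_config"), n_replicates >= 1)
  estimators <- match.arg(estimators,
                          c("poisson", "poisson_adjusted", "cox"),
                          several.ok = TRUE)
  seeds <- replicate_seeds(config$seed, n_replicates)
  ests <- vector("list", n_replicates)
  prev <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seeds[r]
    cohort <- simulate_cohort(cfg)
    prev[r] <- exposure_prevalence(cohort)
    res <- fit_estimators(cohort, estimators = estimators,
                          k_intervals = k_intervals)
    res$replicate <- r
    ests[[r]] <- res
  }
  ests <- do.call(rbind, ests)
  summ <- lapply(split(ests, ests$estimator), function(d) {
    ok <- is.finite(d$rr) & d$converged
    q <- stats::quantile(d$rr[ok], probs = c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(estimator = d$estimator[1L],
               median_rr = q[2L], q1_rr = q[1L], q3_rr = q[3L],
               n_replicates = nrow(d), n_failed = sum(!ok),
               realized_prevalence = mean(prev))
  })
  out <- do.call(rbind, summ)
  out <- out[match(estimators, out$estimator), , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$n_failed > 0.1 * out$n_replicates))
    warning("more than 10% of replicates failed for at least one estimator")
  if (return_estimates) attr(out, "estimates") <- ests
  out
}

sweep_cell <- function(config, n_replicates, estimators, k_intervals) {
  run_replicates(config, n_replicates = n_replicates,
                 estimators = estimators, k_intervals = k_intervals)
}

#' Sweep the Weibull shape parameter
#'
#' Moves the baseline hazard from the constant-hazard scenario A toward
#' the decreasing-hazard scenario B (`lambda = 0.75`, shape in (0.1, 1))
#' or the increasing-hazard scenario C (`lambda = 0.1`, shape in (1, 3)),
#' holding the true effect fixed, and records the median estimated hazard
#' ratio at each grid point. With the unadjusted Poisson estimator this
#' traces how quickly a hazard trend biases the rate ratio.
#'
#' @param direction `"B"` (shape < 1) or `"C"` (shape > 1).
#' @param shape_grid Shape values; defaults cover the open interval in
#'   steps of 0.1 (toward B) or 0.2 (toward C) plus the reference points
#'   0.3/0.7 or 1.6/2.6.
#' @param rr_t True hazard ratio (default 0.75).
#' @param n_replicates,n_subjects Replicates per grid point and cohort
#'   size.
#' @param estimators,k_intervals Passed to [run_replicates()].
#' @param seed Master seed; per-cell seeds are derived from it.
#' @return A data frame with one row per (grid value, estimator):
#'   `parameter`, `value`, plus the [run_replicates()] summary columns.
#' @export
sweep_shape <- function(direction = c("B", "C"), shape_grid = NULL,
                        rr_t = 0.75, n_replicates = 1000L,
                        n_subjects = 10000L, estimators = "poisson",
                        k_intervals = 10L, seed = 1L) {
  direction <- match.arg(direction)
  lambda <- if (direction == "B") 0.75 else 0.1
  if (is.null(shape_grid)) {
    shape_grid <- if (direction == "B")
      sort(unique(c(seq(0.2, 0.9, by = 0.1), 0.3, 0.7)))
    else
      sort(unique(c(seq(1.2, 2.8, by = 0.2), 1.6, 2.6)))
  }
  lo <- if (direction == "B") 0.1 else 1
  hi <- if (direction == "B") 1 else 3
  if (any(shape_grid <= lo | shape_grid >= hi))
    stop(sprintf("'shape_grid' must lie strictly inside (%g, %g)", lo, hi))
  cell_seeds <- replicate_seeds(seed, length(shape_grid))
  rows <- lapply(seq_along(shape_grid), function(i) {
    cfg <- scenario_config(lambda = lambda, shape = shape_grid[i],
                           rr_t = rr_t, n_subjects = n_subjects,
                           seed = cell_seeds[i])
    cbind(parameter = "shape", value = shape_grid[i],
          sweep_cell(cfg, n_replicates, estimators, k_intervals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep the true exposure effect
#'
#' Varies the true hazard ratio over a grid (reference range 0.5 to 2)
#' within one of the named scenarios. Under scenario A the unadjusted
#' Poisson median traces the identity line; under B (C) it lies below
#' (above) the truth with a near-constant offset on the log scale.
#'
#' @param scenario `"A"`, `"B"` or `"C"` (see [scenario_preset()]).
#' @param rr_t_grid True hazard ratios to simulate.
#' @inheritParams sweep_shape
#' @return A data frame with one row per (grid value, estimator).
#' @export
sweep_effect <- function(scenario = c("A", "B", "C"),
                         rr_t_grid = c(0.5, 0.75, 1, 1.25, 1.5, 1.75, 2),
                         n_replicates = 1000L, n_subjects = 10000L,
                         estimators = "poisson", k_intervals = 10L,
                         seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(all(rr_t_grid > 0))
  cell_seeds <- replicate_seeds(seed, length(rr_t_grid))
  rows <- lapply(seq_along(rr_t_grid), function(i) {
    cfg <- scenario_preset(scenario, rr_t = rr_t_grid[i],
                           n_subjects = n_subjects, seed = cell_seeds[i])
    cbind(parameter = "rr_t", value = rr_t_grid[i],
          sweep_cell(cfg, n_replicates, estimators, k_intervals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep the prevalence of and time to exposure
#'
#' Switches the exposure process to the Bernoulli-eligibility plus
#' Gamma-switch-time scheme and sweeps the eligibility probability
#' (reference values 15%, 25%, 40%) against the Gamma shape (0 to 50 with
#' scale 0.1, i.e. mean time to exposure 0 to 5). The bias of the
#' unadjusted Poisson estimator grows with both.
#'
#' @param scenario `"B"` or `"C"` baseline hazard.
#' @param p_grid Eligibility probabilities.
#' @param gamma_shape_grid Gamma shape values (0 = exposed at baseline).
#' @param gamma_scale Gamma scale (default 0.1), so mean time to exposure
#'   is `gamma_shape * gamma_scale`.
#' @inheritParams sweep_shape
#' @return A data frame with one row per (p, shape, estimator), including
#'   `mean_exposure_time` and the realized prevalence.
#' @export
sweep_exposure <- function(scenario = c("B", "C"),
                           p_grid = c(0.15, 0.25, 0.40),
                           gamma_shape_grid = seq(0, 50, by = 10),
                           gamma_scale = 0.1, rr_t = 0.75,
                           n_replicates = 1000L, n_subjects = 10000L,
                           estimators = "poisson", k_intervals = 10L,
                           seed = 1L) {
  scenario <- match.arg(scenario)
  grid <- expand.grid(p_exposed = p_grid, gamma_shape = gamma_shape_grid)
  cell_seeds <- replicate_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- scenario_preset(scenario, rr_t = rr_t, n_subjects = n_subjects,
                           exposure_scheme = "binomial_gamma",
                           p_exposed = grid$p_exposed[i],
                           gamma_shape = grid$gamma_shape[i],
                           gamma_scale = gamma_scale,
                           seed = cell_seeds[i])
    cbind(parameter = "exposure", p_exposed = grid$p_exposed[i],
          gamma_shape = grid$gamma_shape[i],
          mean_exposure_time = grid$gamma_shape[i] * gamma_scale,
          sweep_cell(cfg, n_replicates, estimators, k_intervals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
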