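#' Scenario configuration
#'
#' Bundles everything needed to simulate one cohort: the Weibull baseline
#' hazard, the true exposure effect, the administrative censoring horizon,
#' the cohort size, the exposure-generation scheme, and the master seed.
#'
#' Two exposure schemes are supported:
#' \describe{
#'   \item{`"uniform"`}{every subject receives a potential exposure-switch
#'     time drawn Uniform(0, `uniform_hi`); the switch is observed only if
#'     it precedes the end of follow-up.}
#'   \item{`"binomial_gamma"`}{a Bernoulli(`p_exposed`) draw decides whether
#'     the subject is ever eligible for exposure; eligible subjects receive
#'     a Gamma(`gamma_shape`, scale = `gamma_scale`) switch time (mean
#'     `gamma_shape * gamma_scale`). `gamma_shape = 0` is the degenerate
#'     exposed-from-baseline point (switch time exactly 0). Realized
#'     prevalence is at most `p_exposed` because late switch times are
#'     truncated by events and censoring.}
#' }
#'
#' @param lambda,shape Weibull baseline-hazard parameters, see
#'   [weibull_hazard()].
#' @param rr_t Positive scalar, the true hazard ratio of exposure (constant
#'   over time).
#' @param censor_time Administrative censoring horizon (default 5 time
#'   units).
#' @param n_subjects Cohort size (default 10000).
#' @param exposure_scheme `"uniform"` or `"binomial_gamma"`.
#' @param uniform_hi Upper bound of the uniform exposure-time distribution
#'   (default 10).
#' @param p_exposed Eligibility probability, `binomial_gamma` scheme only.
#' @param gamma_shape,gamma_scale Gamma parameters of the exposure time,
#'   `binomial_gamma` scheme only (scale defaults to 0.1).
#' @param seed Integer master seed for [simulate_cohort()].
#'
#' @return An object of class `"scenario_config"`.
#' @seealso [scenario_preset()] for the three named baseline-hazard
#'   scenarios, [simulate_cohort()].
#' @export
scenario_config <- function(lambda, shape, rr_t = 0.75, censor_time = 5,
                            n_subjects = 10000L,
                            exposure_scheme = c("uniform", "binomial_gamma"),
                            uniform_hi = 10, p_exposed = NULL,
                            gamma_shape = NULL, gamma_scale = 0.1,
                            seed = 1L) {
  exposure_scheme <- match.arg(exposure_scheme)
  hz <- weibull_hazard(lambda, shape)   # validates lambda, shape
  rr_t <- check_rr(rr_t)
  stopifnot(is.numeric(censor_time), length(censor_time) == 1L, censor_time > 0,
            is.numeric(n_subjects), length(n_subjects) == 1L, n_subjects >= 1,
            is.numeric(seed), length(seed) == 1L)
  if (exposure_scheme == "uniform") {
    stopifnot(is.numeric(uniform_hi), length(uniform_hi) == 1L, uniform_hi > 0)
  } else {
    if (is.null(p_exposed) || is.null(gamma_shape))
      stop("scheme 'binomial_gamma' requires 'p_exposed' and 'gamma_shape'")
    stopifnot(is.numeric(p_exposed), length(p_exposed) == 1L,
              p_exposed >= 0, p_exposed <= 1,
              is.numeric(gamma_shape), length(gamma_shape) == 1L,
              gamma_shape >= 0,
              is.numeric(gamma_scale), length(gamma_scale) == 1L,
              gamma_scale > 0)
  }
  structure(list(lambda = hz$lambda, shape = hz$shape, rr_t = rr_t,
                 censor_time = as.numeric(censor_time),
                 n_subjects = as.integer(n_subjects),
                 exposure_scheme = exposure_scheme,
                 uniform_hi = as.numeric(uniform_hi),
                 p_exposed = if (is.null(p_exposed)) NA_real_ else as.numeric(p_exposed),
                 gamma_shape = if (is.null(gamma_shape)) NA_real_ else as.numeric(gamma_shape),
                 gamma_scale = as.numeric(gamma_scale),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: lambda = %g, shape = %g, rr_t = %g, censored at %g\n",
              x$lambda, x$shape, x$rr_t, x$censor_time))
  if (x$exposure_scheme == "uniform") {
    cat(sprintf("  exposure: Uniform(0, %g)\n", x$uniform_hi))
  } else {
    cat(sprintf("  exposure: Bernoulli(%g) x Gamma(shape = %g, scale = %g)\n",
                x$p_exposed, x$gamma_shape, x$gamma_scale))
  }
  cat(sprintf("  n_subjects = %d, seed = %d\n", x$n_subjects, x$seed))
  invisible(x)
}

# Baseline-hazard (lambda, shape) pairs of the three named scenarios:
# constant (A), decreasing (B) and increasing (C) hazard.
scenario_params <- list(
  A = c(lambda = 0.1,   shape = 1),
  B = c(lambda = 0.75,  shape = 0.33),
  C = c(lambda = 1e-05, shape = 7)
)

#' Named scenario presets
#'
#' The three reference baseline hazards, all censored at 5 time units with
#' uniform(0, 10) exposure times unless overridden:
#' \describe{
#'   \item{A}{constant hazard: `lambda = 0.1, shape = 1` (exponential).}
#'   \item{B}{decreasing hazard: `lambda = 0.75, shape = 0.33`.}
#'   \item{C}{increasing hazard: `lambda = 1e-05, shape = 7`.}
#' }
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @param ... Overrides passed to [scenario_config()] (e.g. `rr_t`,
#'   `n_subjects`, `seed`, or an alternative exposure scheme).
#' @return A [scenario_config()].
#' @examples
#' scenario_preset("B", rr_t = 0.75, n_subjects = 1000, seed = 42)
#' @export
scenario_preset <- function(scenario = c("A", "B", "C"), ...) {
  scenario <- match.arg(scenario)
  p <- scenario_params[[scenario]]
  scenario_config(lambda = p[["lambda"]], shape = p[["shape"]], ...)
}

#' Read a scenario configuration from a YAML or JSON file
#'
#' The file may either give a `preset` key (`"A"`, `"B"`, `"C"`) plus
#' overrides, or spell out `lambda` and `shape` directly; all other keys
#' are passed to [scenario_config()].
#'
#' @param path Path to a YAML (or JSON) file.
#' @param ... Further overrides applied on top of the file's values.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading config files requires the 'yaml' package")
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  if (!is.null(vals$preset)) {
    preset <- vals$preset
    vals$preset <- NULL
    do.call(scenario_preset, c(list(scenario = preset), vals))
  } else {
    do.call(scenario_config, vals)
  }
}
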