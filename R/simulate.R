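#' Draw exposure-switch times
#'
#' Draws the potential exposure-switch time of each subject under the
#' config's exposure scheme. Under `"uniform"` every subject gets a draw on
#' (0, `uniform_hi`). Under `"binomial_gamma"` a subject is eligible with
#' probability `p_exposed` and, if eligible, switches at a
#' Gamma(`gamma_shape`, scale = `gamma_scale`) time (`gamma_shape = 0`
#' degenerates to a switch at time 0); ineligible subjects get `NA`.
#'
#' Both schemes consume exactly two uniform variates per subject (the
#' eligibility draw is unused under `"uniform"`), so the draw for subject
#' `j` never depends on the total number of subjects.
#'
#' @param config A [scenario_config()].
#' @param n Number of subjects.
#' @param u_eligible,u_time Optional uniform(0,1) variates of length `n`;
#'   drawn from the current RNG state when omitted. Supplying them makes
#'   the function a pure inverse-transform map.
#' @return Numeric vector of length `n`; `NA` marks subjects never eligible
#'   for exposure.
#' @export
draw_exposure_times <- function(config, n = config$n_subjects,
                                u_eligible = NULL, u_time = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (is.null(u_eligible)) u_eligible <- stats::runif(n)
  if (is.null(u_time)) u_time <- stats::runif(n)
  stopifnot(length(u_eligible) == n, length(u_time) == n)
  if (config$exposure_scheme == "uniform") {
    config$uniform_hi * u_time
  } else {
    e <- rep(NA_real_, n)
    eligible <- u_eligible < config$p_exposed
    e[eligible] <- if (config$gamma_shape == 0) 0 else
      stats::qgamma(u_time[eligible], shape = config$gamma_shape,
                    scale = config$gamma_scale)
    e
  }
}

#' Simulate one subject
#'
#' The core per-subject algorithm: (1) draw a baseline event time by
#' inverse transform; (2) if the potential exposure time precedes it, the
#' subject switches to exposed and the event time is re-drawn from the
#' conditional distribution with hazard multiplied by `rr_t` after the
#' switch; (3) follow-up ends at the event or the censoring horizon,
#' whichever comes first; (4) the exposure time is recorded only when the
#' switch falls inside observed follow-up.
#'
#' @param hz A [weibull_hazard()].
#' @param rr_t True hazard ratio of exposure.
#' @param exposure_time Potential switch time, or `NA` if never eligible.
#' @param censor_time Administrative censoring horizon.
#' @param u_event,u_cond Uniform(0,1) variates driving the baseline and
#'   conditional event-time draws; drawn from the current RNG state when
#'   omitted.
#' @return A one-row data frame with columns `exposure_time` (`NA` when the
#'   switch was not observed), `end_time`, and `event` (logical).
#' @export
simulate_subject <- function(hz, rr_t, exposure_time, censor_time,
                             u_event = stats::runif(1), u_cond = stats::runif(1)) {
  stopifnot(inherits(hz, "weibull_hazard"), censor_time > 0)
  t_event <- sample_event_time(hz, u_event)
  if (!is.na(exposure_time) && exposure_time < t_event) {
    t_event <- sample_conditional_event_time(hz, rr_t, exposure_time, u_cond)
  }
  end_time <- min(t_event, censor_time)
  data.frame(
    exposure_time = if (!is.na(exposure_time) && exposure_time < end_time)
      exposure_time else NA_real_,
    end_time = end_time,
    event = t_event <= censor_time
  )
}

#' Simulate a cohort
#'
#' Generates `config$n_subjects` independent subjects under the config's
#' baseline hazard, exposure scheme, true effect and censoring horizon.
#' Deterministic given `config$seed`: each subject consumes a fixed block
#' of four uniform variates (eligibility, exposure time, baseline event
#' time, conditional event time), so enlarging the cohort appends subjects
#' without reshuffling existing ones.
#'
#' @param config A [scenario_config()].
#' @return A data frame of class `"itb_cohort"` with columns `id`,
#'   `exposure_time` (`NA` when no switch occurred during follow-up),
#'   `end_time`, `event`; the config is attached as attribute `"config"`.
#' @examples
#' coh <- simulate_cohort(scenario_preset("A", n_subjects = 500, seed = 7))
#' mean(coh$event)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_subjects
  hz <- weibull_hazard(config$lambda, config$shape)
  set.seed(config$seed)
  u <- matrix(stats::runif(4L * n), nrow = 4L)   # column j = subject j
  e <- draw_exposure_times(config, n, u_eligible = u[1L, ], u_time = u[2L, ])
  t_event <- sample_event_time(hz, u[3L, ])
  switched <- !is.na(e) & e < t_event
  t_event[switched] <- sample_conditional_event_time(
    hz, config$rr_t, e[switched], u[4L, switched])
  end_time <- pmin(t_event, config$censor_time)
  event <- t_event <= config$censor_time
  e[!(!is.na(e) & e < end_time)] <- NA_real_
  out <- data.frame(id = seq_len(n), exposure_time = e,
                    end_time = end_time, event = event)
  attr(out, "config") <- config
  class(out) <- c("itb_cohort", "data.frame")
  out
}

#' Realized exposure prevalence
#'
#' Fraction of subjects whose switch to exposure occurred during observed
#' follow-up. Under the `binomial_gamma` scheme this is at most
#' `p_exposed`, because switch times after the event or the censoring
#' horizon are never observed.
#'
#' @param cohort A cohort from [simulate_cohort()].
#' @return A scalar in `[0, 1]`.
#' @export
exposure_prevalence <- function(cohort) {
  mean(!is.na(cohort$exposure_time))
}

#' Write / read a cohort as tab-delimited text
#'
#' Columns `id`, `exposure_time` (empty when no switch was observed),
#' `end_time`, `event` (0/1).
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns the cohort data frame;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$event <- as.integer(out$event)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  d <- utils::read.delim(path, na.strings = "")
  stopifnot(all(c("id", "exposure_time", "end_time", "event") %in% names(d)))
  d$event <- as.logical(d$event)
  class(d) <- c("itb_cohort", "data.frame")
  d
}
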