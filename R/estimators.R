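# All estimators return the same one-row result layout so replicate runs
# can rbind them. CIs are Wald on the log scale.
estimate_result <- function(estimator, rr, log_se, n_events,
                            converged = TRUE, n_iterations = NA_integer_) {
  z <- stats::qnorm(0.975)
  data.frame(
    estimator = estimator,
    rr = rr,
    log_se = log_se,
    ci_low = exp(log(rr) - z * log_se),
    ci_high = exp(log(rr) + z * log_se),
    converged = converged,
    n_events = as.integer(n_events),
    n_iterations = as.integer(n_iterations)
  )
}

#' Closed-form Poisson rate ratio
#'
#' The crude incidence-rate ratio from a two-cell rate table,
#' \deqn{\widehat{RR} = \frac{d_1 / PT_1}{d_0 / PT_0}, \qquad
#'       \mathrm{SE}(\log \widehat{RR}) = \sqrt{1/d_1 + 1/d_0},}
#' with \eqn{d_x} events and \eqn{PT_x} person-time in exposure state
#' \eqn{x}. This is exactly the maximum-likelihood estimate of the
#' two-parameter Poisson log-linear model with a log person-time offset,
#' and serves as the oracle for [poisson_glm()].
#'
#' Zero events in either cell yield `rr` of 0 or `Inf` with a non-finite
#' `log_se` and `converged = FALSE` rather than an error; the replicate
#' engine counts and excludes such fits.
#'
#' @param rate_table A [aggregate_rate_table()] result without an interval
#'   dimension; both exposure cells must carry positive person-time.
#' @return A one-row data frame: `estimator`, `rr`, `log_se`, `ci_low`,
#'   `ci_high`, `converged`, `n_events`, `n_iterations`.
#' @export
poisson_rr_closed_form <- function(rate_table) {
  stopifnot(all(c("exposed", "events", "person_time") %in% names(rate_table)))
  if ("interval" %in% names(rate_table) && any(!is.na(rate_table$interval)))
    stop("rate table has an interval dimension; use poisson_glm(adjust_intervals = TRUE)")
  d1 <- sum(rate_table$events[rate_table$exposed])
  d0 <- sum(rate_table$events[!rate_table$exposed])
  pt1 <- sum(rate_table$person_time[rate_table$exposed])
  pt0 <- sum(rate_table$person_time[!rate_table$exposed])
  if (pt1 <= 0 || pt0 <= 0)
    stop("both exposure states need positive person-time")
  rr <- (d1 / pt1) / (d0 / pt0)
  log_se <- sqrt(1 / d1 + 1 / d0)   # Inf when either cell has no events
  estimate_result("poisson", rr, log_se, d1 + d0,
                  converged = d1 > 0 && d0 > 0, n_iterations = 0L)
}

#' Poisson rate model with person-time offset
#'
#' Fits the Poisson log-linear model
#' \eqn{\log E[d] = \log PT + \beta_0 + \beta_E \cdot \mathrm{exposed}
#' \; [+ \gamma_k]} by iteratively reweighted least squares
#' ([stats::glm()]), where the optional \eqn{\gamma_k} are follow-up
#' interval indicators. Without interval adjustment this reproduces
#' [poisson_rr_closed_form()]; with it, the model is the
#' piecewise-exponential remedy: each follow-up interval receives its own
#' baseline rate, absorbing the hazard trend that otherwise confounds the
#' exposure contrast.
#'
#' Intervals in which no events occurred cannot identify their own rate
#' (the indicator coefficient diverges); such intervals are dropped with a
#' warning before fitting.
#'
#' @param episodes Counting-process episodes ([to_episodes()]), split by
#'   [split_by_cutpoints()] when `adjust_intervals = TRUE`.
#' @param adjust_intervals Add per-interval baseline-rate indicators.
#' @return A one-row result data frame (see [poisson_rr_closed_form()]),
#'   with `estimator` `"poisson"` or `"poisson_adjusted"`.
#' @export
poisson_glm <- function(episodes, adjust_intervals = FALSE) {
  rt <- aggregate_rate_table(episodes)
  if (adjust_intervals) {
    if (!"interval" %in% names(episodes))
      stop("adjust_intervals = TRUE requires episodes split by cutpoints")
    keep_iv <- unique(rt$interval[rt$events > 0])
    if (length(keep_iv) < length(unique(rt$interval))) {
      warning("dropping follow-up interval(s) with zero events")
      rt <- rt[rt$interval %in% keep_iv, , drop = FALSE]
    }
    form <- if (length(keep_iv) > 1L)
      events ~ exposed + factor(interval) + offset(log(person_time))
    else
      events ~ exposed + offset(log(person_time))
    fit <- stats::glm(form, family = stats::poisson(), data = rt,
                      control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  } else {
    rt$interval <- NULL
    fit <- stats::glm(events ~ exposed + offset(log(person_time)),
                      family = stats::poisson(), data = rt,
                      control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  }
  co <- summary(fit)$coefficients
  estimate_result(
    if (adjust_intervals) "poisson_adjusted" else "poisson",
    rr = exp(co["exposedTRUE", "Estimate"]),
    log_se = co["exposedTRUE", "Std. Error"],
    n_events = sum(rt$events),
    converged = fit$converged,
    n_iterations = fit$iter)
}

#' Cox model with a time-varying exposure covariate
#'
#' Maximizes the partial likelihood for a single binary time-varying
#' covariate on counting-process episodes (risk set at an event time t:
#' episodes with start < t <= stop), with Breslow tie handling, via
#' [survival::coxph()]. The baseline hazard is left unspecified, so the
#' estimate is consistent for the exposure hazard ratio whatever the
#' hazard trend — the model-free comparator to the Poisson fits.
#'
#' When every event occurs in a single exposure state the partial
#' likelihood is monotone; the result is flagged `converged = FALSE` with
#' `rr` 0 or `Inf`.
#'
#' @param episodes Counting-process episodes ([to_episodes()]).
#' @return A one-row result data frame with `estimator = "cox"`.
#' @export
cox_tvc <- function(episodes) {
  stopifnot(all(c("start", "stop", "exposed", "event") %in% names(episodes)))
  n_events <- sum(episodes$event)
  if (n_events < 1) stop("at least one event is required")
  d1 <- sum(episodes$event & episodes$exposed)
  if (d1 == 0L || d1 == n_events) {
    return(estimate_result("cox", rr = if (d1 == 0L) 0 else Inf,
                           log_se = Inf, n_events = n_events,
                           converged = FALSE))
  }
  # a monotone partial likelihood surfaces as coxph's "beta may be
  # infinite" warning; record it in the converged flag instead of warning
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(start, stop, event) ~ exposed,
      data = episodes, ties = "breslow",
      control = survival::coxph.control(eps = 1e-10, iter.max = 50,
                                        timefix = FALSE)),
    warning = function(w) {
      if (grepl("beta may be infinite", conditionMessage(w))) {
        monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  estimate_result("cox", rr = exp(beta), log_se = se, n_events = n_events,
                  converged = is.finite(beta) && abs(beta) < 15 && !monotone,
                  n_iterations = fit$iter)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of marginal survival; censored subjects leave
#' the risk set at their end of follow-up.
#'
#' @param cohort A cohort data frame with `end_time` and `event`.
#' @return A data frame of class `"km_curve"` with columns `time`
#'   (increasing), `survival` (non-increasing) and `at_risk`.
#' @export
kaplan_meier <- function(cohort) {
  stopifnot(nrow(cohort) >= 1)
  fit <- survival::survfit(
    survival::Surv(end_time, event) ~ 1,
    data = data.frame(end_time = cohort$end_time,
                      event = as.integer(cohort$event)))
  out <- data.frame(time = fit$time, survival = fit$surv, at_risk = fit$n.risk)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Step-function evaluation (right-continuous): the survival just after the
#' last event time at or before `t`.
#'
#' @param km A [kaplan_meier()] curve.
#' @param t Times at which to evaluate.
#' @return Survival probabilities, same length as `t`.
#' @export
km_survival_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$survival)[idx + 1L]
}

#' Fit a set of estimators to one cohort
#'
#' Convenience wrapper running any subset of the unadjusted Poisson rate
#' ratio (closed form), the interval-adjusted piecewise Poisson (with
#' `k_intervals` event-quantile follow-up intervals) and the Cox
#' time-varying-covariate model on the same cohort.
#'
#' @param cohort A cohort data frame.
#' @param estimators Subset of `c("poisson", "poisson_adjusted", "cox")`.
#' @param k_intervals Number of event-quantile follow-up intervals for the
#'   piecewise Poisson model.
#' @return A data frame with one row per estimator.
#' @export
fit_estimators <- function(cohort,
                           estimators = c("poisson", "poisson_adjusted", "cox"),
                           k_intervals = 10L) {
  estimators <- match.arg(estimators, several.ok = TRUE)
  ep <- to_episodes(cohort)
  out <- list()
  if ("poisson" %in% estimators)
    out$poisson <- poisson_rr_closed_form(aggregate_rate_table(ep))
  if ("poisson_adjusted" %in% estimators) {
    cuts <- event_quantile_cutpoints(cohort, k = k_intervals)
    out$poisson_adjusted <- poisson_glm(split_by_cutpoints(ep, cuts),
                                        adjust_intervals = TRUE)
  }
  if ("cox" %in% estimators)
    out$cox <- cox_tvc(ep)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
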