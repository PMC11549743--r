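#' Weibull baseline hazard
#'
#' Constructs a Weibull baseline hazard in the rate-scale parameterization
#' \deqn{h(t) = \lambda \upsilon t^{\upsilon - 1}, \qquad
#'       S(t) = \exp(-\lambda t^{\upsilon}),}
#' where `lambda` (\eqn{\lambda > 0}, units time^-shape) sets the overall
#' event rate and `shape` (\eqn{\upsilon > 0}, dimensionless) sets the trend:
#' the hazard decreases over follow-up when `shape < 1`, is constant
#' (exponential survival with rate `lambda`) when `shape == 1`, and increases
#' when `shape > 1`.
#'
#' @param lambda Positive scalar, the rate-scale parameter \eqn{\lambda}.
#' @param shape Positive scalar, the shape parameter \eqn{\upsilon}.
#'
#' @return An object of class `"weibull_hazard"`.
#' @seealso [hazard_at()], [survival_at()], [sample_event_time()],
#'   [sample_conditional_event_time()]
#' @examples
#' hz <- weibull_hazard(lambda = 0.1, shape = 1)
#' survival_at(hz, 5)      # exp(-0.5)
#' @export
weibull_hazard <- function(lambda, shape) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (lambda <= 0) stop("'lambda' must be positive")
  if (shape <= 0) stop("'shape' must be positive")
  structure(list(lambda = as.numeric(lambda), shape = as.numeric(shape)),
            class = "weibull_hazard")
}

#' @export
print.weibull_hazard <- function(x, ...) {
  trend <- if (x$shape < 1) "decreasing" else if (x$shape > 1) "increasing" else "constant"
  cat(sprintf("Weibull hazard: lambda = %g, shape = %g (%s hazard)\n",
              x$lambda, x$shape, trend))
  invisible(x)
}

# t^s computed in log space; defined as 0 at t = 0 for every s > 0 so that
# survival_at(., 0) == 1 even for shape < 1.
pow_ts <- function(t, s) {
  out <- exp(s * log(t))
  out[t == 0] <- 0
  out
}

check_time <- function(t) {
  if (!is.numeric(t) || anyNA(t)) stop("'t' must be numeric and non-missing")
  if (any(t < 0)) stop("negative time is outside the domain")
  as.numeric(t)
}

check_unit <- function(u) {
  if (!is.numeric(u) || anyNA(u)) stop("'u' must be numeric and non-missing")
  if (any(u <= 0) || any(u >= 1)) stop("'u' must lie strictly in (0, 1)")
  as.numeric(u)
}

check_rr <- function(rr_t) {
  stopifnot(is.numeric(rr_t), length(rr_t) == 1L, is.finite(rr_t))
  if (rr_t <= 0) stop("'rr_t' must be a positive hazard ratio")
  as.numeric(rr_t)
}

#' Instantaneous hazard
#'
#' Evaluates \eqn{h(t) = \lambda \upsilon t^{\upsilon - 1}}. For `shape < 1`
#' the hazard diverges as `t` approaches 0 and `Inf` is returned at `t = 0`.
#'
#' @param hz A [weibull_hazard()].
#' @param t Non-negative times (vectorized).
#' @return Hazard values, same length as `t`.
#' @export
hazard_at <- function(hz, t) {
  stopifnot(inherits(hz, "weibull_hazard"))
  t <- check_time(t)
  hz$lambda * hz$shape * t^(hz$shape - 1)
}

#' Survival function
#'
#' Evaluates \eqn{S(t) = \exp(-\lambda t^{\upsilon})}, the probability of
#' remaining event-free to time `t`; consistent with [hazard_at()] through
#' \eqn{S(t) = \exp(-\int_0^t h(u)\,du)}.
#'
#' @inheritParams hazard_at
#' @return Survival probabilities in `[0, 1]`, same length as `t`.
#' @export
survival_at <- function(hz, t) {
  stopifnot(inherits(hz, "weibull_hazard"))
  t <- check_time(t)
  exp(-hz$lambda * pow_ts(t, hz$shape))
}

#' Inverse-CDF event-time sampling
#'
#' Maps uniform variates to Weibull event times by inverting the survival
#' function: \eqn{T = (-\log u / \lambda)^{1/\upsilon}}, so that
#' `survival_at(hz, sample_event_time(hz, u)) == u`.
#'
#' @inheritParams hazard_at
#' @param u Uniform variates strictly in (0, 1) (vectorized).
#' @return Positive event times, same length as `u`.
#' @export
sample_event_time <- function(hz, u) {
  stopifnot(inherits(hz, "weibull_hazard"))
  u <- check_unit(u)
  pow_ts(-log(u) / hz$lambda, 1 / hz$shape)
}

#' Conditional event-time sampling after an exposure switch
#'
#' Draws the event time of a subject who is event-free at the exposure
#' switch time `e` and whose hazard is multiplied by `rr_t` from `e`
#' onward (proportional hazards on the residual time; the time scale is
#' not reset). Inverting the conditional survival
#' \eqn{S(t \mid T > e) = \exp\{-\rho\lambda(t^{\upsilon} - e^{\upsilon})\}}
#' gives \eqn{T = (e^{\upsilon} - \log u / (\rho\lambda))^{1/\upsilon}},
#' with \eqn{\rho} the true hazard ratio.
#'
#' At `e = 0` and `rr_t = 1` this reduces to [sample_event_time()].
#'
#' @inheritParams sample_event_time
#' @param rr_t Positive scalar, the true hazard ratio of exposure.
#' @param e Non-negative exposure-switch times (vectorized with `u`).
#' @return Event times strictly greater than `e`.
#' @export
sample_conditional_event_time <- function(hz, rr_t, e, u) {
  stopifnot(inherits(hz, "weibull_hazard"))
  rr_t <- check_rr(rr_t)
  e <- check_time(e)
  u <- check_unit(u)
  pow_ts(pow_ts(e, hz$shape) - log(u) / (rr_t * hz$lambda), 1 / hz$shape)
}
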