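# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: survival by numerical integration of the hazard,
# and the Cox coefficient by direct 1-D maximization of the Breslow log
# partial likelihood.

# exp(-integral of the hazard), by adaptive quadrature
survival_by_integration <- function(hz, t) {
  if (t == 0) return(1)
  integrand <- function(u) hazard_at(hz, u)
  # the hazard diverges at 0 for shape < 1; integrate() handles the
  # integrable singularity
  exp(-stats::integrate(integrand, 0, t, rel.tol = 1e-10)$value)
}

# Breslow log partial likelihood for one binary time-varying covariate on
# counting-process episodes; risk set at event time t: start < t <= stop.
breslow_logpl <- function(beta, episodes) {
  evt <- which(episodes$event)
  ll <- 0
  for (i in evt) {
    t <- episodes$stop[i]
    at_risk <- episodes$start < t & episodes$stop >= t
    ll <- ll + beta * episodes$exposed[i] -
      log(sum(exp(beta * episodes$exposed[at_risk])))
  }
  ll
}

# grid search bracketing the maximizer, refined by optimize()
cox_grid_oracle <- function(episodes, lo = -4, hi = 4) {
  grid <- seq(lo, hi, by = 0.05)
  vals <- vapply(grid, breslow_logpl, numeric(1), episodes = episodes)
  b0 <- grid[which.max(vals)]
  stats::optimize(breslow_logpl, interval = c(b0 - 0.1, b0 + 0.1),
                  episodes = episodes, maximum = TRUE,
                  tol = 1e-12)$maximum
}

# random two-cell rate tables for the GLM-vs-closed-form equivalence check
random_rate_table <- function() {
  rt <- data.frame(
    exposed = c(FALSE, TRUE),
    events = c(sample(1:500, 1), sample(1:500, 1)),
    person_time = stats::runif(2, 10, 5000)
  )
  class(rt) <- c("rate_table", "data.frame")
  rt
}

# expand a two-cell rate table into episodes whose aggregation recovers it
# exactly (one episode per event, sharing the cell's person-time equally)
rate_table_as_episodes <- function(rt) {
  rows <- lapply(seq_len(nrow(rt)), function(i) {
    d <- rt$events[i]
    k <- max(d, 1L)
    data.frame(start = 0, stop = rep(rt$person_time[i] / k, k),
               exposed = rt$exposed[i], event = rep(d > 0, k))
  })
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  out
}

# small cohorts for the Cox oracle comparison
small_cohort <- function(seed, n = 15L, rr_t = 1.3) {
  simulate_cohort(scenario_config(lambda = 0.3, shape = 1, rr_t = rr_t,
                                  n_subjects = n, seed = seed))
}
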