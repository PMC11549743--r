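#' Convert subjects to counting-process episodes
#'
#' Expands each subject into (start, stop] episodes of constant exposure:
#' a never-exposed subject contributes one unexposed episode covering all
#' of follow-up; an exposed subject contributes an unexposed episode
#' (0, E] and an exposed episode (E, end_time], with the event flag on the
#' final episode only. A switch at exactly time 0 yields a single exposed
#' episode (zero-length episodes are never emitted). This is the
#' bookkeeping that classifies the pre-switch (otherwise "immortal")
#' person-time as unexposed.
#'
#' @param cohort A cohort data frame from [simulate_cohort()] or
#'   [read_cohort()] (a single-subject data frame works too).
#' @return A data frame with columns `id`, `start`, `stop`, `exposed`
#'   (logical), `event` (logical), sorted by `id` then `start`. Episodes of
#'   one subject tile `[0, end_time]` without gaps or overlaps.
#' @export
to_episodes <- function(cohort) {
  stopifnot(all(c("id", "exposure_time", "end_time", "event") %in% names(cohort)))
  if (any(cohort$end_time <= 0)) stop("end_time must be positive")
  e <- cohort$exposure_time
  bad <- !is.na(e) & e >= cohort$end_time
  if (any(bad))
    stop("exposure_time at or after end_time violates the subject record invariant")
  exp_obs <- !is.na(e)
  pre <- exp_obs & e > 0          # unexposed lead-in episode exists
  ep <- data.frame(
    id = c(cohort$id[!exp_obs], cohort$id[pre], cohort$id[exp_obs]),
    start = c(rep(0, sum(!exp_obs)), rep(0, sum(pre)), e[exp_obs]),
    stop = c(cohort$end_time[!exp_obs], e[pre], cohort$end_time[exp_obs]),
    exposed = rep(c(FALSE, FALSE, TRUE), c(sum(!exp_obs), sum(pre), sum(exp_obs))),
    event = c(cohort$event[!exp_obs], rep(FALSE, sum(pre)), cohort$event[exp_obs])
  )
  ep[order(ep$id, ep$start), , drop = FALSE]
}

#' Split episodes at follow-up cutpoints
#'
#' Partitions each episode at the cutpoints falling strictly inside it and
#' labels every fragment with the follow-up interval containing its start,
#' using the half-open convention `[c_k, c_{k+1})` with `c_0 = 0` (interval
#' 1 is `[0, c_1)`). The event flag is carried only by the fragment that
#' ends at the original episode's stop, so an event at exactly a cutpoint
#' stays in the earlier interval. Person-time is conserved exactly: the
#' fragment boundaries are the original start/stop values and the cutpoints
#' themselves, so durations telescope.
#'
#' @param episodes Episode data frame from [to_episodes()].
#' @param cutpoints Strictly increasing positive cutpoints; an empty vector
#'   returns the episodes with all fragments in interval 1.
#' @return The episode data frame with an added integer `interval` column.
#' @export
split_by_cutpoints <- function(episodes, cutpoints) {
  stopifnot(all(c("id", "start", "stop", "exposed", "event") %in% names(episodes)))
  cutpoints <- as.numeric(cutpoints)
  if (anyNA(cutpoints) || is.unsorted(cutpoints, strictly = TRUE) ||
      any(cutpoints <= 0))
    stop("'cutpoints' must be strictly increasing and positive")
  n <- nrow(episodes)
  if (length(cutpoints) == 0L || n == 0L) {
    episodes$interval <- rep(1L, n)
    return(episodes)
  }
  # interior cutpoints: start < c < stop
  inside <- outer(episodes$start, cutpoints, "<") &
    outer(episodes$stop, cutpoints, ">")
  hits <- which(inside, arr.ind = TRUE)
  row_of <- c(seq_len(n), hits[, 1L])
  frag_start <- c(episodes$start, cutpoints[hits[, 2L]])
  ord <- order(row_of, frag_start)
  row_of <- row_of[ord]
  frag_start <- frag_start[ord]
  last <- row_of != c(row_of[-1L], 0L)
  frag_stop <- c(frag_start[-1L], 0)
  frag_stop[last] <- episodes$stop[row_of[last]]
  ev <- rep(FALSE, length(row_of))
  ev[last] <- episodes$event[row_of[last]]
  out <- data.frame(
    id = episodes$id[row_of],
    start = frag_start,
    stop = frag_stop,
    exposed = episodes$exposed[row_of],
    event = ev,
    interval = findInterval(frag_start, cutpoints) + 1L
  )
  rownames(out) <- NULL
  out
}

#' Event-quantile cutpoints
#'
#' Cutpoints at the empirical quantiles of the observed event times,
#' yielding `k` follow-up intervals with roughly equal numbers of events —
#' the default interval choice for the piecewise-exponential remedy, which
#' equalizes the information available to each interval's rate.
#'
#' @param cohort A cohort data frame (only subjects with `event == TRUE`
#'   contribute).
#' @param k Number of intervals (so `k - 1` cutpoints before
#'   deduplication).
#' @return Numeric vector of strictly increasing cutpoints.
#' @export
event_quantile_cutpoints <- function(cohort, k = 5L) {
  stopifnot(k >= 1)
  times <- cohort$end_time[cohort$event]
  if (length(times) == 0L) stop("no events: cannot place event-quantile cutpoints")
  if (k == 1L) return(numeric(0))
  cuts <- unique(unname(stats::quantile(times, probs = seq_len(k - 1L) / k)))
  cuts[cuts > 0 & cuts < max(times)]
}

#' Aggregate episodes into a person-time rate table
#'
#' Sums events and person-time by exposure state, and additionally by
#' follow-up interval when the episodes carry an `interval` column. These
#' are the sufficient statistics of the (piecewise) Poisson rate model.
#'
#' @param episodes Episode data frame, optionally split by
#'   [split_by_cutpoints()].
#' @return A data frame of class `"rate_table"` with columns `exposed`,
#'   `interval` (`NA` when episodes were not split), `events`,
#'   `person_time`; cells with zero person-time are omitted.
#' @export
aggregate_rate_table <- function(episodes) {
  stopifnot(all(c("start", "stop", "exposed", "event") %in% names(episodes)))
  dur <- episodes$stop - episodes$start
  if (any(dur <= 0)) stop("zero- or negative-length episode")
  has_iv <- "interval" %in% names(episodes)
  iv <- if (has_iv) episodes$interval else rep(NA_integer_, nrow(episodes))
  key <- paste(episodes$exposed, iv, sep = "\r")
  ev <- rowsum(as.numeric(episodes$event), key)
  pt <- rowsum(dur, key)
  parts <- strsplit(rownames(ev), "\r", fixed = TRUE)
  out <- data.frame(
    exposed = vapply(parts, function(p) as.logical(p[1L]), logical(1)),
    interval = vapply(parts, function(p) suppressWarnings(as.integer(p[2L])),
                      integer(1)),
    events = as.integer(ev[, 1L]),
    person_time = pt[, 1L]
  )
  out <- out[out$person_time > 0, , drop = FALSE]
  out <- out[order(out$interval, out$exposed), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Write / read counting-process episode tables
#'
#' Tab-delimited text with columns `id`, `start`, `stop`, `exposed` (0/1),
#' `event` (0/1) and, if present, `interval` — the standard (start, stop]
#' layout consumed by time-varying-covariate survival models, so episode
#' tables built from real cohorts can be fed straight to the estimators.
#'
#' @param episodes Episode data frame.
#' @param path File path.
#' @return `read_episodes()` returns the episode data frame;
#'   `write_episodes()` returns `path` invisibly.
#' @export
write_episodes <- function(episodes, path) {
  out <- episodes
  out$exposed <- as.integer(out$exposed)
  out$event <- as.integer(out$event)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_episodes
#' @export
read_episodes <- function(path) {
  d <- utils::read.delim(path, na.strings = "")
  stopifnot(all(c("id", "start", "stop", "exposed", "event") %in% names(d)))
  d$exposed <- as.logical(d$exposed)
  d$event <- as.logical(d$event)
  d
}
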