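toy_cohort <- function() {
  data.frame(
    id = 1:3,
    exposure_time = c(1.5, NA, 4.99),
    end_time = c(3.2, 5, 5),
    event = c(TRUE, FALSE, FALSE)
  )
}

test_that("subjects expand to tiling counting-process episodes", {
  ep <- to_episodes(toy_cohort())
  e1 <- ep[ep$id == 1, ]
  expect_equal(e1$start, c(0, 1.5))
  expect_equal(e1$stop, c(1.5, 3.2))
  expect_equal(e1$exposed, c(FALSE, TRUE))
  expect_equal(e1$event, c(FALSE, TRUE))     # event only on the last episode
  e2 <- ep[ep$id == 2, ]
  expect_equal(nrow(e2), 1L)
  expect_false(e2$exposed)
  e3 <- ep[ep$id == 3, ]
  expect_equal(e3$stop - e3$start, c(4.99, 0.01))
})

test_that("an exposure switch at time zero yields a single exposed episode", {
  ep <- to_episodes(data.frame(id = 1L, exposure_time = 0,
                               end_time = 2.5, event = TRUE))
  expect_equal(nrow(ep), 1L)
  expect_true(ep$exposed)
  expect_equal(c(ep$start, ep$stop), c(0, 2.5))
})

test_that("an exposure time at or after end of follow-up is rejected", {
  bad <- data.frame(id = 1L, exposure_time = 5, end_time = 5, event = FALSE)
  expect_error(to_episodes(bad), "invariant")
})

test_that("episode invariants hold on simulated cohorts", {
  coh <- simulate_cohort(scenario_preset("B", rr_t = 0.75,
                                         n_subjects = 3000, seed = 61))
  ep <- to_episodes(coh)
  expect_true(all(ep$stop > ep$start))
  # per-subject tiling: stop_k == start_{k+1}, first start 0, last stop end
  by_id <- split(ep, ep$id)
  expect_true(all(vapply(by_id, function(d) {
    d <- d[order(d$start), ]
    d$start[1] == 0 &&
      all(abs(d$stop[-nrow(d)] - d$start[-1]) == 0) &&
      !is.unsorted(d$exposed)                 # at most one FALSE -> TRUE
  }, logical(1))))
  # conservation and event uniqueness
  expect_equal(sum(ep$stop - ep$start), sum(coh$end_time))
  expect_equal(sum(ep$event), sum(coh$event))
})

test_that("splitting partitions episodes at interior cutpoints", {
  ep <- data.frame(id = 1L, start = 0, stop = 3.2,
                   exposed = FALSE, event = TRUE)
  sp <- split_by_cutpoints(ep, c(1, 2))
  expect_equal(sp$start, c(0, 1, 2))
  expect_equal(sp$stop, c(1, 2, 3.2))
  expect_equal(sp$interval, 1:3)
  expect_equal(sp$event, c(FALSE, FALSE, TRUE))

  # empty cutpoints: identity up to the interval column
  sp0 <- split_by_cutpoints(ep, numeric(0))
  expect_equal(sp0$interval, 1L)
  expect_equal(sp0[names(ep)], ep)

  expect_error(split_by_cutpoints(ep, c(2, 1)), "increasing")
  expect_error(split_by_cutpoints(ep, c(1, 1)), "increasing")
})

test_that("an event at exactly a cutpoint stays in the earlier interval", {
  ep <- data.frame(id = 1L, start = 0, stop = 2,
                   exposed = TRUE, event = TRUE)
  sp <- split_by_cutpoints(ep, c(1, 2))
  expect_equal(nrow(sp), 2L)                  # no zero-length third fragment
  expect_equal(sp$interval[sp$event], 2L)
})

test_that("person-time is conserved exactly under random splitting", {
  set.seed(62)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    start <- runif(n, 0, 4)
    ep <- data.frame(id = seq_len(n), start = start,
                     stop = start + runif(n, 0.01, 3),
                     exposed = runif(n) < 0.5, event = runif(n) < 0.3)
    cuts <- sort(unique(runif(sample(1:8, 1), 0.1, 6)))
    sp <- split_by_cutpoints(ep, cuts)
    expect_equal(sum(sp$stop - sp$start), sum(ep$stop - ep$start),
                 tolerance = 1e-12)
    expect_equal(sum(sp$event), sum(ep$event))
    # fragments of one episode are contiguous
    expect_true(all(vapply(split(sp, sp$id), function(d) {
      all(d$stop[-nrow(d)] == d$start[-1])
    }, logical(1))))
    # interval labels follow the half-open convention on fragment starts
    expect_equal(sp$interval, findInterval(sp$start, cuts) + 1L)
  }
})

test_that("rate tables sum events and person-time by cell", {
  rt <- aggregate_rate_table(to_episodes(toy_cohort()))
  expect_equal(rt$person_time[!rt$exposed], 1.5 + 5 + 4.99)
  expect_equal(rt$person_time[rt$exposed], (3.2 - 1.5) + 0.01)
  expect_equal(rt$events[rt$exposed], 1L)
  expect_equal(rt$events[!rt$exposed], 0L)
})

test_that("marginalizing a split rate table recovers the unsplit table", {
  coh <- simulate_cohort(scenario_preset("C", rr_t = 0.75,
                                         n_subjects = 2000, seed = 63))
  ep <- to_episodes(coh)
  rt <- aggregate_rate_table(ep)
  sp <- split_by_cutpoints(ep, event_quantile_cutpoints(coh, k = 6))
  rts <- aggregate_rate_table(sp)
  marg <- rowsum(rts[c("events", "person_time")], rts$exposed)
  expect_equal(marg$events, rt$events)
  expect_equal(marg$person_time, rt$person_time, tolerance = 1e-12)
  # split table still conserves totals
  expect_equal(sum(rts$person_time), sum(coh$end_time), tolerance = 1e-12)
  expect_equal(sum(rts$events), sum(coh$event))
})

test_that("event-quantile cutpoints are interior and ordered", {
  coh <- simulate_cohort(scenario_preset("B", rr_t = 0.75,
                                         n_subjects = 2000, seed = 64))
  cuts <- event_quantile_cutpoints(coh, k = 10)
  expect_false(is.unsorted(cuts, strictly = TRUE))
  expect_true(all(cuts > 0 & cuts < 5))
  expect_identical(event_quantile_cutpoints(coh, k = 1), numeric(0))
  no_events <- data.frame(id = 1L, exposure_time = NA_real_,
                          end_time = 5, event = FALSE)
  expect_error(event_quantile_cutpoints(no_events, k = 5), "no events")
})

test_that("episode tables round-trip through delimited text", {
  coh <- simulate_cohort(scenario_preset("B", n_subjects = 40, seed = 65))
  ep <- split_by_cutpoints(to_episodes(coh), c(0.5, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_episodes(ep, path)
  back <- read_episodes(path)
  expect_equal(back$start, ep$start)
  expect_equal(back$stop, ep$stop)
  expect_identical(back$exposed, ep$exposed)
  expect_identical(back$event, ep$event)
  expect_equal(back$interval, ep$interval)
})
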