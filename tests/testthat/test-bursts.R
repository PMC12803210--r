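test_that("population activity counts cells per bin correctly", {
  # 10 cells at 1 Hz, 10 s; events placed by hand
  v <- matrix(0, nrow = 10, ncol = 10)
  v[4, 1:4] <- 0.5           # 4 cells peak in frame 4 (bin 4)
  v[3, 1:4] <- 0             # ensure local maxima
  dff <- make_dff_trace(v, frame_rate_hz = 1)
  ev <- detect_events(dff)
  pop <- build_population_activity(ev, dff, bin_s = 1)
  expect_equal(nrow(pop), 10)
  expect_equal(pop$active_fraction[4], 0.4)
  expect_equal(pop$active_fraction[-4], rep(0, 9))
  expect_true(all(pop$active_fraction >= 0 & pop$active_fraction <= 1))

  # all cells in the same bin reach the upper bound
  v2 <- matrix(0, nrow = 10, ncol = 10)
  v2[6, ] <- 0.9
  dff2 <- make_dff_trace(v2, frame_rate_hz = 1)
  pop2 <- build_population_activity(detect_events(dff2), dff2, bin_s = 1)
  expect_equal(max(pop2$active_fraction), 1.0)

  # no events anywhere
  dff3 <- make_dff_trace(matrix(0, nrow = 10, ncol = 10), frame_rate_hz = 1)
  pop3 <- build_population_activity(detect_events(dff3), dff3)
  expect_true(all(pop3$active_fraction == 0))
})

test_that("suprathreshold mode counts frame-coincident suprathreshold cells", {
  v <- matrix(0, nrow = 6, ncol = 4)
  v[2, 1:3] <- 0.4
  v[5, 1] <- 0.25
  dff <- make_dff_trace(v, frame_rate_hz = 2)
  pop <- build_population_activity(detect_events(dff), dff,
                                   activity_mode = "suprathreshold")
  expect_equal(nrow(pop), 6)  # one bin per frame
  expect_equal(pop$active_fraction[2], 0.75)
  expect_equal(pop$active_fraction[5], 0.25)
  expect_equal(pop$mean_dff, rowMeans(v))
})

test_that("mismatched roi ids are a data error", {
  v <- matrix(0.0, nrow = 5, ncol = 2)
  dff <- make_dff_trace(v, frame_rate_hz = 1)
  ev <- detect_events(dff)
  dff2 <- trace_set(v, 1, roi_ids = c("a", "b"), kind = "dff")
  expect_error(build_population_activity(ev, dff2), "roi_id")
})

test_that("detected bursts are exactly the maximal strict-suprathreshold runs", {
  # worked example
  pop <- make_pop(c(0, 0.4, 0.4, 0.4, 0))
  bb <- detect_bursts(pop, sync_fraction = 0.3)
  expect_equal(nrow(bb), 1)
  expect_equal(bb$start_s, 1)
  expect_equal(bb$end_s, 3)
  expect_equal(bb$duration_s, 3)
  expect_false(bb$truncated)

  # sub-threshold throughout, and the strictness convention at 0.30
  expect_equal(nrow(detect_bursts(make_pop(c(0, 0.2, 0.2, 0)), 0.3)), 0)
  expect_equal(nrow(detect_bursts(make_pop(c(0, 0.30, 0)), 0.3)), 0)
  expect_equal(nrow(detect_bursts(make_pop(rep(0, 8)), 0.3)), 0)

  # randomized run-enumeration oracle
  set.seed(55)
  for (i in 1:200) {
    frac <- sample(c(0, 0.1, 0.29, 0.3, 0.31, 0.5, 1), sample(3:60, 1),
                   replace = TRUE)
    pop <- make_pop(frac)
    bb <- detect_bursts(pop, sync_fraction = 0.3)
    oracle <- brute_runs(frac, 0.3)
    expect_equal(nrow(bb), nrow(oracle))
    if (nrow(oracle) > 0) {
      expect_equal(bb$start_s, pop$bin_start_s[oracle$start])
      expect_equal(bb$end_s, pop$bin_start_s[oracle$end])
      # every bin inside a burst is above threshold, and bursts are maximal
      for (j in seq_len(nrow(oracle))) {
        expect_true(all(frac[oracle$start[j]:oracle$end[j]] > 0.3))
        if (oracle$start[j] > 1) expect_lte(frac[oracle$start[j] - 1], 0.3)
        if (oracle$end[j] < length(frac)) expect_lte(frac[oracle$end[j] + 1], 0.3)
      }
    }
  }
})

test_that("bursts are disjoint, sorted, bounded by the recording, and monotone in threshold", {
  set.seed(91)
  # burst-like activity: unimodal peaks on a quiet background, so raising the
  # synchronization threshold can shrink or remove bursts but never split one
  make_bursty <- function() {
    frac <- rep(0, 120)
    for (ctr in sample(seq(10, 110, by = 15), sample(3:7, 1))) {
      h <- runif(1, 0.2, 1)
      w <- sample(1:4, 1)
      idx <- pmax(1, pmin(120, (ctr - w):(ctr + w)))
      frac[idx] <- pmax(frac[idx], h * (1 - abs(seq(-w, w)) / (w + 1)))
    }
    frac
  }
  for (i in 1:30) {
    frac <- make_bursty()
    pop <- make_pop(frac)
    bb <- detect_bursts(pop, sync_fraction = 0.4)
    if (nrow(bb) > 1) {
      expect_true(all(diff(bb$start_s) > 0))
      expect_true(all(bb$start_s[-1] > bb$end_s[-nrow(bb)]))
    }
    expect_lte(sum(bb$duration_s), attr(pop, "duration_s"))
    n_by_thr <- vapply(c(0.15, 0.3, 0.45, 0.6, 0.75), function(sf)
      nrow(detect_bursts(pop, sync_fraction = sf)), numeric(1))
    expect_true(all(diff(n_by_thr) <= 0))
    # total burst time is always non-increasing in the threshold
    t_low <- sum(detect_bursts(pop, sync_fraction = 0.3)$duration_s)
    t_high <- sum(detect_bursts(pop, sync_fraction = 0.6)$duration_s)
    expect_lte(t_high, t_low)
  }
})

test_that("gap merging bridges short sub-threshold dips; edge bursts are flagged truncated", {
  frac <- c(0.5, 0, 0.5, 0.5, 0, 0, 0.5)
  bb0 <- detect_bursts(make_pop(frac), 0.3, min_gap_bins = 0)
  expect_equal(nrow(bb0), 3)
  bb1 <- detect_bursts(make_pop(frac), 0.3, min_gap_bins = 1)
  expect_equal(nrow(bb1), 2)
  expect_equal(bb1$start_s[1], 0)
  expect_equal(bb1$end_s[1], 3)
  bb2 <- detect_bursts(make_pop(frac), 0.3, min_gap_bins = 2)
  expect_equal(nrow(bb2), 1)
  expect_true(all(bb2$truncated))
  expect_equal(bb0$truncated, c(TRUE, FALSE, TRUE))
})

test_that("burst summaries and relative change follow their definitions", {
  # 30 bursts in 600 s -> 3 bursts/min
  frac <- rep(c(0.5, rep(0, 19)), 30)
  frac[1] <- 0  # avoid edge truncation of the first burst
  pop <- make_pop(frac)
  bb <- detect_bursts(pop, 0.3)
  s <- summarize_bursts(bb, duration_s = 600)
  expect_equal(s$n_bursts, 29)  # one burst lost by shifting off the grid start
  expect_equal(s$burst_frequency, 29 / 10)

  # arithmetic on durations and amplitudes
  pop2 <- make_pop(c(0, 0.6, 0, 0.8, 0.8, 0.8, 0), mean_dff = c(0, 0.2, 0, 0.4, 0.6, 0.5, 0))
  bb2 <- detect_bursts(pop2, 0.3)
  s2 <- summarize_bursts(bb2, duration_s = 7)
  expect_equal(s2$mean_duration_s, mean(c(1, 3)))
  expect_equal(s2$mean_amplitude, mean(c(0.2, 0.6)))

  # empty case: frequency 0, means undefined
  s0 <- summarize_bursts(detect_bursts(make_pop(rep(0, 10)), 0.3), duration_s = 10)
  expect_equal(s0$burst_frequency, 0)
  expect_true(is.na(s0$mean_amplitude))
  expect_false(s0$has_bursts)

  # relative change
  expect_equal(relative_change(s2, s2)$frequency_ratio, 1)
  half <- s2; half$burst_frequency <- s2$burst_frequency / 2
  expect_equal(relative_change(s2, half)$frequency_ratio, 0.5)
  rc0 <- relative_change(s0, s2)
  expect_true(is.na(rc0$frequency_ratio))
})

test_that("truncated bursts count toward frequency but not mean duration by default", {
  frac <- c(0.5, 0.5, 0, 0.4, 0.4, 0.4, 0, 0.5)
  bb <- detect_bursts(make_pop(frac), 0.3)
  expect_equal(bb$truncated, c(TRUE, FALSE, TRUE))
  s <- summarize_bursts(bb, duration_s = 8)
  expect_equal(s$n_bursts, 3)
  expect_equal(s$mean_duration_s, 3)  # only the interior burst
  s_all <- summarize_bursts(bb, duration_s = 8, exclude_truncated_duration = FALSE)
  expect_equal(s_all$mean_duration_s, mean(c(2, 3, 1)))
})

test_that("circularly shifting event trains preserves per-neuron counts", {
  p <- sim_params(n_cells = 10, duration_s = 120, seed = 14)
  dff <- compute_dff(render_fluorescence(simulate_spike_raster(p), p))
  ev <- detect_events(dff)
  sh <- shuffle_events(ev, seed = 2)
  expect_equal(table(sh$roi_id), table(ev$roi_id))
  expect_true(all(sh$time_s >= 0 & sh$time_s < attr(ev, "duration_s")))
  expect_false(identical(sh$time_s, ev$time_s))
})
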