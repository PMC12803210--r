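test_that("parameter validation names the offending field", {
  expect_error(sim_params(n_cells = 0), "n_cells")
  expect_error(sim_params(recruitment_fraction = 1.2), "recruitment_fraction")
  expect_error(sim_params(tau_rise_s = 0), "tau_rise_s")
  expect_error(sim_params(baseline_f = -1), "baseline_f")
  expect_error(sim_params(noise_sd = -0.1), "noise_sd")
  expect_error(effect_spec(burst_rate_multiplier = 0), "burst_rate_multiplier")
})

test_that("frame-rate presets match the two recording modalities", {
  expect_equal(sim_params(preset = "invitro")$frame_rate_hz, 4)
  expect_equal(sim_params(preset = "invivo")$frame_rate_hz, 1)
})

test_that("raster with no event sources is empty; full recruitment recruits all cells", {
  p <- sim_params(n_cells = 10, duration_s = 60, burst_rate_per_min = 0,
                  background_rate_hz = 0, seed = 5)
  r <- simulate_spike_raster(p)
  expect_equal(sum(lengths(r$spikes)), 0)
  expect_length(r$burst_truth, 0)

  p2 <- sim_params(n_cells = 10, duration_s = 120, burst_rate_per_min = 5,
                   background_rate_hz = 0, recruitment_fraction = 1, seed = 5)
  r2 <- simulate_spike_raster(p2)
  expect_gt(length(r2$burst_truth), 0)
  for (b in r2$burst_truth) expect_equal(b$cells, 1:10)
})

test_that("every burst recruits exactly round(recruitment_fraction * n_cells) distinct cells", {
  for (frac in c(0.3, 0.57, 0.61, 0.9)) {
    p <- sim_params(n_cells = 23, duration_s = 300, burst_rate_per_min = 4,
                    recruitment_fraction = frac, seed = 11)
    r <- simulate_spike_raster(p)
    k <- round(frac * 23)
    for (b in r$burst_truth) {
      expect_length(b$cells, k)
      expect_equal(anyDuplicated(b$cells), 0)
    }
  }
})

test_that("spike times stay inside the recording and are sorted per cell", {
  p <- sim_params(n_cells = 20, duration_s = 120, seed = 7)
  r <- simulate_spike_raster(p)
  for (i in seq_len(r$n_cells)) {
    s <- r$spikes[[i]]
    expect_true(all(s >= 0 & s < r$duration_s))
    expect_true(!is.unsorted(s))
  }
})

test_that("ground-truth burst count matches the Poisson closed form over 200 seeds", {
  # 600 s at 3 bursts/min -> Poisson(30); the empirical mean over 200 seeds
  # must lie within 3 standard errors of 30
  counts <- vapply(1:200, function(s) {
    p <- sim_params(n_cells = 50, duration_s = 600, burst_rate_per_min = 3,
                    background_rate_hz = 0, seed = s)
    length(simulate_spike_raster(p)$burst_truth)
  }, numeric(1))
  se <- sqrt(30 / 200)
  expect_lt(abs(mean(counts) - 30), 3 * se)
  # Poisson dispersion: variance/mean ratio near 1
  expect_gt(var(counts) / mean(counts), 0.6)
  expect_lt(var(counts) / mean(counts), 1.5)
})

test_that("seed determinism: identical params give bit-identical raster and traces", {
  p <- sim_params(n_cells = 8, duration_s = 60, seed = 99)
  r1 <- simulate_spike_raster(p)
  r2 <- simulate_spike_raster(p)
  expect_identical(r1, r2)
  expect_identical(render_fluorescence(r1, p), render_fluorescence(r2, p))
})

test_that("noise-free, drift-free rendering of an empty raster is exactly the baseline", {
  p <- sim_params(n_cells = 3, duration_s = 30, burst_rate_per_min = 0,
                  background_rate_hz = 0, noise_sd = 0, drift_amplitude = 0,
                  baseline_f = 100, seed = 1)
  tr <- render_fluorescence(simulate_spike_raster(p), p)
  expect_true(all(tr$values == 100))
})

test_that("a single transient peaks at unitary_amplitude up to frame-grid discretization", {
  p <- sim_params(n_cells = 1, duration_s = 30, burst_rate_per_min = 0,
                  background_rate_hz = 0, noise_sd = 0, drift_amplitude = 0,
                  baseline_f = 100, unitary_amplitude = 0.5, seed = 1)
  r <- simulate_spike_raster(p)
  spike_t <- 10.0
  r$spikes[[1]] <- spike_t
  r$amp_scales[[1]] <- 1
  tr <- render_fluorescence(r, p)
  peak <- max((tr$values[, 1] - 100) / 100)
  # oracle: the normalized kernel evaluated on the frame grid
  grid_t <- (0:(30 * 4 - 1)) / 4
  expected <- 0.5 * max(indicator_kernel(grid_t - spike_t, 0.2, 1.0))
  expect_equal(peak, expected, tolerance = 1e-12)
  expect_lte(peak, 0.5)
  expect_gt(peak, 0.5 * indicator_kernel(0.358 + 0.25, 0.2, 1.0))
})

test_that("spike count is conserved through noise-free rendering at low rates", {
  p <- sim_params(n_cells = 5, duration_s = 200, burst_rate_per_min = 0,
                  background_rate_hz = 0, noise_sd = 0, drift_amplitude = 0,
                  unitary_amplitude = 0.8, seed = 21)
  r <- simulate_spike_raster(p)
  # well-separated spikes (>> transient support) so every onset is resolvable
  for (i in seq_len(r$n_cells)) {
    r$spikes[[i]] <- seq(5 + i, 190, by = 17.3)
    r$amp_scales[[i]] <- rep(1, length(r$spikes[[i]]))
  }
  tr <- render_fluorescence(r, p)
  # count kernel onsets on the frame grid: frames where the signal rises
  # through 5% dF/F0 from (near) baseline
  dff <- (tr$values - 100) / 100
  onsets <- colSums(dff[-1, , drop = FALSE] > 0.05 & dff[-nrow(dff), , drop = FALSE] <= 0.05)
  expect_equal(sum(onsets), sum(lengths(r$spikes)))
})

test_that("with no background and vanishing jitter all burst spikes land in one frame", {
  p <- sim_params(n_cells = 12, duration_s = 120, burst_rate_per_min = 3,
                  background_rate_hz = 0, burst_jitter_s = 0, seed = 3)
  r <- simulate_spike_raster(p)
  for (b in r$burst_truth) {
    frames <- vapply(b$cells, function(i) {
      s <- r$spikes[[i]]
      floor(s[which.min(abs(s - b$time))] * p$frame_rate_hz)
    }, numeric(1))
    expect_equal(length(unique(frames)), 1)
  }
})

test_that("paired simulation preserves cell identities and injects exact rate effects", {
  p <- sim_params(n_cells = 15, duration_s = 120, seed = 17)
  eff <- effect_spec(burst_rate_multiplier = 0.5, burst_amplitude_multiplier = 2,
                     burst_duration_multiplier = 1.5)
  sim <- simulate_paired_experiment(p, eff)
  expect_identical(sim$baseline$roi_ids, sim$post$roi_ids)
  expect_equal(sim$truth$post$burst_rate_per_min,
               0.5 * sim$truth$baseline$burst_rate_per_min)
  expect_equal(sim$truth$post$burst_amplitude, 2 * sim$truth$baseline$burst_amplitude)
  expect_equal(sim$truth$post$burst_jitter_s, 1.5 * sim$truth$baseline$burst_jitter_s)

  # identity effect: post drawn from the same generative law
  sim0 <- simulate_paired_experiment(p, effect_spec())
  expect_equal(sim0$truth$post$burst_rate_per_min,
               sim0$truth$baseline$burst_rate_per_min)
  # determinism of the pair
  sim0b <- simulate_paired_experiment(p, effect_spec())
  expect_identical(sim0$baseline$values, sim0b$baseline$values)
  expect_identical(sim0$post$values, sim0b$post$values)
})
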