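#' Simulation parameters for a synthetic bursting-network recording
#'
#' Full generative description of one synthetic calcium-imaging recording of a
#' dissociated cortical network: sparse background firing plus recurrent
#' network bursts that recruit a large fraction of cells, rendered to
#' fluorescence through a calcium-indicator kernel with additive noise and slow
#' baseline drift. The defaults describe a 10-minute in vitro recording of 50
#' cells at 4 frames/s with network bursts at 3 per minute recruiting 60% of
#' cells.
#'
#' @param n_cells Number of neurons (>= 1).
#' @param duration_s Recording length in seconds (> 0).
#' @param frame_rate_hz Sampling rate, frames per second (> 0). The presets
#'   below override this.
#' @param background_rate_hz Per-cell Poisson rate of asynchronous background
#'   events outside bursts, in events/s.
#' @param burst_rate_per_min Network-burst occurrence rate, bursts/minute
#'   (homogeneous Poisson process).
#' @param recruitment_fraction Fraction of cells firing in each burst, in
#'   \\[0, 1\\]; each burst recruits exactly
#'   `round(recruitment_fraction * n_cells)` distinct cells.
#' @param burst_jitter_s Within-burst spike-time spread (Gaussian SD, seconds).
#' @param unitary_amplitude Peak dF/F0 of a single-event transient (unitless).
#' @param tau_rise_s,tau_decay_s Indicator kernel time constants in seconds
#'   (both > 0).
#' @param baseline_f Mean raw baseline fluorescence, arbitrary units (> 0).
#' @param noise_sd Additive Gaussian noise SD, same units as `baseline_f`
#'   (>= 0).
#' @param drift_amplitude Amplitude of the slow multiplicative sinusoidal
#'   baseline drift, as a fraction of baseline (>= 0). One drift period spans
#'   the recording; its phase is seed-determined.
#' @param min_interburst_s Minimum interval between network bursts (seconds);
#'   0 (the default) leaves the burst process purely Poisson.
#' @param seed Integer RNG seed; identical parameters including the seed give
#'   bit-identical output at every stage.
#' @param preset Optional frame-rate preset: `"invitro"` (4 Hz epifluorescence)
#'   or `"invivo"` (1 Hz two-photon).
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_cells = 50, duration_s = 600, frame_rate_hz = 4,
                       background_rate_hz = 0.05, burst_rate_per_min = 3,
                       recruitment_fraction = 0.6, burst_jitter_s = 0.3,
                       unitary_amplitude = 0.5, tau_rise_s = 0.2,
                       tau_decay_s = 1.0, baseline_f = 100, noise_sd = 2,
                       drift_amplitude = 0.05, min_interburst_s = 0,
                       seed = 1L, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("invitro", "invivo"))
    frame_rate_hz <- if (preset == "invitro") 4 else 1
  }
  p <- list(
    n_cells = n_cells, duration_s = duration_s, frame_rate_hz = frame_rate_hz,
    background_rate_hz = background_rate_hz,
    burst_rate_per_min = burst_rate_per_min,
    recruitment_fraction = recruitment_fraction,
    burst_jitter_s = burst_jitter_s, unitary_amplitude = unitary_amplitude,
    tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
    baseline_f = baseline_f, noise_sd = noise_sd,
    drift_amplitude = drift_amplitude, min_interburst_s = min_interburst_s,
    seed = as.integer(seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  check_scalar(p$n_cells, "n_cells", lower = 1)
  if (p$n_cells != round(p$n_cells)) stop("parameter 'n_cells' must be an integer", call. = FALSE)
  check_scalar(p$duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(p$frame_rate_hz, "frame_rate_hz", lower = 0, strict_lower = TRUE)
  check_scalar(p$background_rate_hz, "background_rate_hz", lower = 0)
  check_scalar(p$burst_rate_per_min, "burst_rate_per_min", lower = 0)
  check_scalar(p$recruitment_fraction, "recruitment_fraction", lower = 0, upper = 1)
  check_scalar(p$burst_jitter_s, "burst_jitter_s", lower = 0)
  check_scalar(p$unitary_amplitude, "unitary_amplitude", lower = 0)
  check_scalar(p$tau_rise_s, "tau_rise_s", lower = 0, strict_lower = TRUE)
  check_scalar(p$tau_decay_s, "tau_decay_s", lower = 0, strict_lower = TRUE)
  check_scalar(p$baseline_f, "baseline_f", lower = 0, strict_lower = TRUE)
  check_scalar(p$noise_sd, "noise_sd", lower = 0)
  check_scalar(p$drift_amplitude, "drift_amplitude", lower = 0)
  check_scalar(p$min_interburst_s, "min_interburst_s", lower = 0)
  check_scalar(p$seed, "seed")
  invisible(p)
}

#' Treatment effect specification for paired simulations
#'
#' Multiplicative effects injected into the post condition of a paired
#' baseline/post simulation, mirroring the three phenotype axes of network
#' pharmacology experiments: burst frequency, burst amplitude and burst
#' duration.
#'
#' @param burst_rate_multiplier Scales the network-burst rate (> 0).
#' @param burst_amplitude_multiplier Scales the unitary transient amplitude of
#'   burst spikes (> 0); background events are unaffected.
#' @param burst_duration_multiplier Scales the within-burst jitter, hence the
#'   burst envelope duration (> 0).
#' @param applies_to Condition the effect modifies; only `"post"` is defined.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(burst_rate_multiplier = 1,
                        burst_amplitude_multiplier = 1,
                        burst_duration_multiplier = 1,
                        applies_to = "post") {
  applies_to <- match.arg(applies_to, "post")
  e <- list(burst_rate_multiplier = burst_rate_multiplier,
            burst_amplitude_multiplier = burst_amplitude_multiplier,
            burst_duration_multiplier = burst_duration_multiplier,
            applies_to = applies_to)
  for (f in names(e)[1:3]) check_scalar(e[[f]], f, lower = 0, strict_lower = TRUE)
  structure(e, class = "effect_spec")
}

#' Simulate a spike raster with network-burst structure
#'
#' Draws per-cell homogeneous Poisson background spikes, then superimposes
#' network bursts: burst centers follow a Poisson process at
#' `burst_rate_per_min`; each burst recruits exactly
#' `round(recruitment_fraction * n_cells)` distinct cells chosen uniformly at
#' random, each receiving one spike at the burst center plus Gaussian jitter
#' (SD `burst_jitter_s`), clipped to the recording bounds.
#'
#' @param params A `sim_params` object.
#' @param amp_scale Internal amplitude scale applied to burst spikes (used by
#'   [simulate_paired_experiment()] to inject amplitude effects); background
#'   spikes always carry scale 1.
#' @return A `spike_raster`: per-cell sorted spike times (with per-spike
#'   amplitude scales) plus the ground-truth burst list (`time`, recruited
#'   `cells`).
#' @export
simulate_spike_raster <- function(params, amp_scale = 1) {
  validate_sim_params(params)
  check_scalar(amp_scale, "amp_scale", lower = 0, strict_lower = TRUE)
  seeds <- derive_seeds(params$seed, 2L)
  set.seed(seeds[1L])

  n <- as.integer(params$n_cells)
  dur <- params$duration_s
  eps <- 1e-9 * max(1, dur)

  spikes <- vector("list", n)
  scales <- vector("list", n)
  n_bg <- rpois(n, params$background_rate_hz * dur)
  for (i in seq_len(n)) {
    spikes[[i]] <- sort(runif(n_bg[i], 0, dur))
    scales[[i]] <- rep(1, n_bg[i])
  }

  n_bursts <- rpois(1L, params$burst_rate_per_min * dur / 60)
  centers <- sort(runif(n_bursts, 0, dur))
  if (params$min_interburst_s > 0 && length(centers) > 1L) {
    # greedy thinning: drop any center closer than the refractory gap to the
    # last kept one
    kept <- numeric(0)
    for (ct in centers) {
      if (length(kept) == 0 || ct - kept[length(kept)] >= params$min_interburst_s)
        kept <- c(kept, ct)
    }
    centers <- kept
  }
  k <- as.integer(round(params$recruitment_fraction * n))
  burst_truth <- vector("list", length(centers))
  for (b in seq_along(centers)) {
    cells <- if (k > 0L) sort(sample.int(n, k)) else integer(0)
    times <- centers[b] + rnorm(k, 0, params$burst_jitter_s)
    times <- pmin(pmax(times, 0), dur - eps)
    for (j in seq_along(cells)) {
      i <- cells[j]
      spikes[[i]] <- c(spikes[[i]], times[j])
      scales[[i]] <- c(scales[[i]], amp_scale)
    }
    burst_truth[[b]] <- list(time = centers[b], cells = cells)
  }
  for (i in seq_len(n)) {
    o <- order(spikes[[i]])
    spikes[[i]] <- spikes[[i]][o]
    scales[[i]] <- scales[[i]][o]
  }
  structure(
    list(spikes = spikes, amp_scales = scales, n_cells = n, duration_s = dur,
         burst_truth = burst_truth, render_seed = seeds[2L]),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d cells, %.1f s, %d spikes, %d ground-truth bursts\n",
              x$n_cells, x$duration_s, sum(lengths(x$spikes)),
              length(x$burst_truth)))
  invisible(x)
}

#' Calcium-indicator impulse response
#'
#' Difference-of-exponentials kernel normalized to unit peak:
#' `g(t) = (1 - exp(-t/tau_rise)) * exp(-t/tau_decay)` for `t >= 0`, scaled so
#' its maximum is 1. The analytic peak time is
#' `tau_rise * log(1 + tau_decay/tau_rise)`.
#'
#' @param t Times in seconds (values < 0 give 0).
#' @param tau_rise_s,tau_decay_s Kernel time constants (seconds, > 0).
#' @return Kernel values in \\[0, 1\\].
#' @export
indicator_kernel <- function(t, tau_rise_s, tau_decay_s) {
  g <- function(u) (1 - exp(-u / tau_rise_s)) * exp(-u / tau_decay_s)
  t_peak <- tau_rise_s * log(1 + tau_decay_s / tau_rise_s)
  out <- ifelse(t >= 0, g(t) / g(t_peak), 0)
  out
}

#' Render a spike raster to raw fluorescence traces
#'
#' Each spike contributes a unit-peak indicator transient scaled by
#' `unitary_amplitude` (times the spike's amplitude scale); transients sum
#' linearly. The raw trace is
#' `F(t) = baseline_f * (1 + drift(t)) * (1 + sum of transients) + noise`,
#' sampled on the frame grid, with `drift(t)` a one-period sinusoid of
#' amplitude `drift_amplitude` and seed-determined phase, and i.i.d. Gaussian
#' noise of SD `noise_sd`.
#'
#' @param raster A `spike_raster` from [simulate_spike_raster()].
#' @param params The `sim_params` used to build the raster.
#' @return A raw `trace_set` (frames x cells).
#' @export
render_fluorescence <- function(raster, params) {
  validate_sim_params(params)
  if (!inherits(raster, "spike_raster")) stop("expected a spike_raster", call. = FALSE)
  set.seed(raster$render_seed)

  nf <- max(1L, as.integer(round(params$duration_s * params$frame_rate_hz)))
  tt <- (seq_len(nf) - 1) / params$frame_rate_hz
  n <- raster$n_cells
  # kernel support: follow the decay until the transient is < 1e-4 of peak
  support_s <- params$tau_rise_s + params$tau_decay_s * log(1e4)

  phase <- runif(1, 0, 2 * pi)
  drift <- if (params$drift_amplitude > 0) {
    params$drift_amplitude * sin(2 * pi * tt / params$duration_s + phase)
  } else rep(0, nf)

  values <- matrix(0, nrow = nf, ncol = n)
  for (i in seq_len(n)) {
    sig <- numeric(nf)
    sp <- raster$spikes[[i]]
    sc <- raster$amp_scales[[i]]
    for (j in seq_along(sp)) {
      f0 <- as.integer(ceiling(sp[j] * params$frame_rate_hz - 1e-9)) + 1L
      f1 <- min(nf, as.integer(floor((sp[j] + support_s) * params$frame_rate_hz)) + 1L)
      if (f0 > nf || f1 < f0) next
      idx <- f0:f1
      sig[idx] <- sig[idx] + params$unitary_amplitude * sc[j] *
        indicator_kernel(tt[idx] - sp[j], params$tau_rise_s, params$tau_decay_s)
    }
    noise <- if (params$noise_sd > 0) rnorm(nf, 0, params$noise_sd) else 0
    values[, i] <- params$baseline_f * (1 + drift) * (1 + sig) + noise
  }
  trace_set(values, params$frame_rate_hz, kind = "raw")
}

#' Simulate a paired baseline/post experiment with a known injected effect
#'
#' Generates two recordings of the same cells: a baseline recording from
#' `params` unmodified and a post recording with the `effect_spec` multipliers
#' applied (burst rate, burst-spike amplitude, within-burst jitter). ROI
#' identities and ordering are preserved across the pair, so neurons can be
#' matched one-to-one downstream. The two conditions use independent spike
#' realizations (derived sub-seeds), as two separate recording epochs would.
#'
#' @param params A `sim_params` object (the baseline condition).
#' @param effect An `effect_spec`; all multipliers 1 simulates a null effect.
#' @return A list with `baseline` and `post` raw `trace_set`s and `truth`, a
#'   ground-truth record holding both conditions' generative parameters,
#'   realized burst counts and rasters.
#' @export
simulate_paired_experiment <- function(params, effect = effect_spec()) {
  validate_sim_params(params)
  if (!inherits(effect, "effect_spec")) stop("expected an effect_spec", call. = FALSE)
  seeds <- derive_seeds(params$seed, 4L)

  base_p <- params
  base_p$seed <- seeds[1L]
  post_p <- params
  post_p$seed <- seeds[2L]
  post_p$burst_rate_per_min <- params$burst_rate_per_min * effect$burst_rate_multiplier
  post_p$burst_jitter_s <- params$burst_jitter_s * effect$burst_duration_multiplier

  raster_base <- simulate_spike_raster(base_p)
  raster_post <- simulate_spike_raster(post_p, amp_scale = effect$burst_amplitude_multiplier)
  tr_base <- render_fluorescence(raster_base, base_p)
  tr_post <- render_fluorescence(raster_post, post_p)

  truth <- list(
    baseline = list(burst_rate_per_min = base_p$burst_rate_per_min,
                    burst_amplitude = params$unitary_amplitude,
                    burst_jitter_s = base_p$burst_jitter_s,
                    n_bursts = length(raster_base$burst_truth)),
    post = list(burst_rate_per_min = post_p$burst_rate_per_min,
                burst_amplitude = params$unitary_amplitude * effect$burst_amplitude_multiplier,
                burst_jitter_s = post_p$burst_jitter_s,
                n_bursts = length(raster_post$burst_truth)),
    effect = effect,
    rasters = list(baseline = raster_base, post = raster_post)
  )
  list(baseline = tr_base, post = tr_post, truth = truth)
}
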