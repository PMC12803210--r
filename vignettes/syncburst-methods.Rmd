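---
title: "Methods: trace normalization, event detection, and synchronized-burst analysis"
author: "syncburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trace normalization, event detection, and synchronized-burst analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncburst)
```

## Scope

`syncburst` analyzes fluorescence calcium-imaging traces from populations of
neurons — the per-ROI time series produced by upstream segmentation tools such
as Suite2p — and quantifies single-neuron activity and population-level
synchronized network bursts, the recurrent near-simultaneous firing episodes
characteristic of dissociated cortical cultures. It covers four stages:
ΔF/F₀ normalization, calcium-event detection, synchronized-burst detection
and quantification, and neuron-matched paired statistics across recording
conditions. A seeded simulator of bursting networks generates ground-truth
recordings so that every stage is validated by parameter recovery rather
than by eye. ROI segmentation, spike inference and raw-movie handling are out
of scope.

## ΔF/F₀ with a sliding-minimum baseline

Raw fluorescence `F(t)` is normalized as `ΔF/F₀ = (F − F₀)/F₀`, where the
baseline `F₀(t)` is the minimum of `F` within a sliding window of
`window_s` seconds (default 20 s) around frame `t`. The window length in
frames is `round(window_s × frame_rate_hz)`, at least 1. Two alignments are
offered:

* `centered` (default): the window straddles the frame (±10 s at the
  default). A centered minimum does not lag behind slow drift, which a
  trailing window systematically does on rising baselines.
* `trailing`: the window ends at the frame, for strictly causal processing.

At the recording edges windows truncate — they are never padded, since
padding would fabricate data — and a window longer than the recording clamps
to the whole recording (with a warning). Because the window always contains
the current frame, `F₀(t) ≤ F(t)` and ΔF/F₀ is non-negative everywhere; it
is exactly zero on constant traces and invariant under multiplicative
rescaling of the raw input. The production sliding minimum is an O(n)
monotonic-deque implementation in C++; the test suite checks it against an
independent O(n·w) brute force on 1,000 random traces.

### Noise floor of a minimum-window baseline

Taking the *minimum* over `w` frames biases the baseline low: for i.i.d.
Gaussian frame noise of standard deviation σ, the expected window minimum is
about 2.2σ below the true baseline at `w = 80` (20 s at 4 frames/s). The
ΔF/F₀ trace therefore rides on a noise floor of ≈ 2.2σ/F₀ with fluctuations
of ≈ σ/F₀. For the 0.20 event threshold to sit clear of this floor one needs
roughly `2.2σ + 4σ < 0.20·F₀`, i.e. σ below ~3% of the baseline
fluorescence. This is an intrinsic property of the minimum-window method,
not of any particular implementation: at σ = 5% of baseline the floor
reaches 0.14 ± 0.06 and noise local-maxima above 0.20 occur on roughly one
frame in seven, swamping event detection and saturating the population
activity trace. The method is only operable on recordings whose per-frame
noise is a few percent of baseline — the regime modern genetically encoded
indicators provide and, evidently, the regime of the data the method was
developed on.

## Event detection

An event is a local maximum of ΔF/F₀ that *exceeds* (strict `>`) the
amplitude threshold `threshold_dff` (default 0.20, i.e. 20% ΔF/F₀), with a
minimum inter-peak distance `min_distance_frames` (default 1 frame, which
imposes no pruning). Conventions the definition leaves open are fixed as
follows:

* a plateau of equal values flanked by strictly lower values yields one
  event, at the plateau's first frame (deterministic tie-break);
* recording endpoints may qualify as peaks against their single neighbor,
  so events at the edges are not systematically missed;
* when `min_distance_frames > 1`, conflicting candidates are resolved
  greedily in order of descending amplitude, ties to the earlier frame —
  the standard peak-pruning convention.

Event count is non-increasing in both the threshold and the minimum
distance. Per-neuron summaries report event frequency in events/minute
(`n/(duration/60)`) and mean peak amplitude; neurons without events have
frequency 0 and an undefined (NA, flagged) mean amplitude.

## Population activity and synchronized bursts

The population activity trace is the fraction of recorded cells
simultaneously active, in [0, 1]. Two definitions of "active" are provided
because the field's raster-plus-trace figures rarely state one:

* `event_bin` (default): time is tiled into `bin_s`-second bins (default
  1 s) and a cell is active in a bin if it has ≥ 1 detected event there.
  Binning absorbs the within-burst spike-time jitter, so co-bursting cells
  need not peak on the same frame.
* `suprathreshold`: per frame, a cell is active if its ΔF/F₀ exceeds the
  event threshold. Finer-grained, but sensitive to exact peak alignment at
  high frame rates.

The mode and bin width are recorded in all outputs. A synchronized burst is
a *maximal* run of consecutive bins whose active fraction strictly exceeds
`sync_fraction` (default 0.30 — 30% of recorded cells); a bin exactly at the
threshold is outside any burst. Runs separated by at most `min_gap_bins`
sub-threshold bins can be merged (default 0, the simplest faithful reading
of a threshold crossing). Bursts touching a recording edge are kept and
flagged truncated: they count toward burst frequency and amplitude but are
excluded from mean duration by default, because truncated durations are
biased low (configurable).

Burst amplitude is defined as the maximum population-mean ΔF/F₀ within the
burst interval. The peak active fraction is reported alongside, but it is
bounded at 1 and saturates for strongly recruiting bursts, so it captures
graded amplitude changes poorly. Per-recording summaries give burst
frequency (bursts/min), mean amplitude and mean duration; paired recordings
yield post/baseline ratios of the three, with division-by-zero and
empty-summary cases flagged undefined rather than propagated as errors.

As a surrogate control, `shuffle_events()` circularly shifts each neuron's
event train by an independent uniform offset. This preserves every neuron's
event count and inter-event intervals while destroying population
coincidence, so burst counts on shuffled data estimate the chance level.

## Paired statistics

Paired analyses use only neurons tracked in both conditions: matching is by
ROI identifier intersection (tracking itself is upstream of this package;
identifiers are assumed consistent across epochs). Unmatched neurons are
counted and reported. Per-neuron comparison/baseline ratios of event
frequency and mean amplitude are computed with zero-baseline and
undefined-amplitude neurons flagged and excluded from ratio summaries;
because ratios are right-skewed, summaries report the geometric mean
(exponentiated mean log-ratio) alongside the arithmetic mean.

Hypothesis tests are one-tailed Student t-tests with the direction supplied
explicitly per hypothesis — no direction is ever inferred from the data. The
paired test uses the differences `d = y − x` with `t = mean(d)/(sd(d)/√n)`
on `n − 1` degrees of freedom. The unpaired test defaults to Welch's
unequal-variance form with Satterthwaite degrees of freedom, the safer
default when group variances are unknown; the pooled-variance form is an
option. Degenerate inputs (constant differences, both groups constant)
raise errors rather than returning p-values. No multiple-testing correction
is applied across recording sets or measures.

## The synthetic-data generator

The generator emulates a dissociated cortical network's activity statistics
and renders them through indicator kinetics:

1. **Spiking.** Each cell fires background events as an independent
   homogeneous Poisson process (`background_rate_hz`). Network bursts occur
   as a Poisson process at `burst_rate_per_min` (an optional minimum
   inter-burst interval is available but defaults to 0, keeping the process
   Poisson so that closed-form count statistics hold in validation). Each
   burst recruits exactly `round(recruitment_fraction × n_cells)` distinct
   cells uniformly at random; each recruited cell fires once at the burst
   center plus Gaussian jitter (`burst_jitter_s`), clipped to the recording.
2. **Rendering.** Every spike contributes a difference-of-exponentials
   transient `g(t) = (1 − e^(−t/τ_rise)) e^(−t/τ_decay)` normalized to unit
   peak and scaled by `unitary_amplitude`; transients sum linearly (no
   indicator saturation). The raw trace is
   `F(t) = baseline_f (1 + drift(t)) (1 + Σ transients) + ε(t)` on the frame
   grid, with `drift(t)` a one-period sinusoid of amplitude
   `drift_amplitude` and seed-determined phase, and ε i.i.d. Gaussian with
   SD `noise_sd`.

Paired experiments reuse the same cell identities for a baseline and a post
epoch (independent spike realizations, as two recording epochs would be) and
inject known multiplicative effects on burst rate, burst-spike amplitude and
within-burst jitter — the three phenotype axes used in network pharmacology.

Defaults describe a 10-minute in vitro recording: 50 cells at 4 frames/s
(preset `invitro`; `invivo` selects 1 Hz), background 0.05 events/s/cell,
3 bursts/min recruiting 60% of cells with 0.3 s jitter, unitary amplitude
0.5 ΔF/F₀, τ_rise 0.2 s and τ_decay 1.0 s (multi-frame transients at both
frame rates), baseline 100 a.u., drift 5%. The background rate, recruitment
fraction and jitter are plausible values for mature cultures, not measured
constants. The default noise SD is 2 a.u. — 2% of baseline — placing the
simulator inside the minimum-window baseline's validity region derived
above (σ < ~3%), with the 0.20 threshold about 7σ above the noise floor;
per-frame ΔF/F₀ noise of 1–3% is typical of modern red indicators at these
frame rates. All randomness flows from one integer seed through derived
per-stage sub-streams, so identical parameters give bit-identical outputs
and adding a stage never perturbs an earlier one.

What the generator deliberately does not model: shot noise
(signal-dependent variance), indicator saturation and nonlinearity, burst
refractoriness and adaptation, correlated background firing, neuropil
contamination, motion artifacts, and pixel-level imaging. Passing recovery
tests therefore demonstrates that the pipeline's detectors and statistics
are correct on data matching its assumptions — linear transients on a
slowly drifting baseline with Gaussian noise — not that they are robust to
every pathology of real recordings.

## Validation design and problem sizes

Every operation is checked against an independent oracle: the deque sliding
minimum against a vectorized O(n·w) brute force (1,000 random traces, 10 to
5,000 frames, windows 1–100 frames, both alignments); peak calling against
exhaustive enumeration plus greedy pruning (1,000 random traces); burst
calling against linear-scan run enumeration on constructed activity vectors
(1,000 cases); the t-tests against closed-form Student-t computations at
10⁻¹⁰ relative tolerance, plus a 1,000-repetition null calibration of the
paired test's type-I error at α = 0.05. Recovery experiments use the default
study conditions — 50 cells, 10 minutes, 3 bursts/min ground truth — over 20
seeds: detected burst frequency, the injected rate-halving effect (recovered
mean frequency ratio within [0.4, 0.6]), a null effect (mean ratio within
3 SE of 1), and a 50-shuffle surrogate control (median shuffled burst count
≤ 10% of unshuffled). These sizes keep the full suite around one minute on a
single CPU while leaving Monte-Carlo standard errors well inside the asserted
bounds.

## Known limitations

* The minimum-window baseline requires per-frame noise below ~3% of
  baseline fluorescence (see above); noisier recordings need smoothing or a
  different baseline estimator, both outside this package's scope.
* Event-binned population activity inherits the event detector's noise
  sensitivity; at 1-s bins, bursts whose jitter straddles a bin boundary
  can split recruitment across bins, costing a few percent of detections
  (the dominant term in the ~8% underestimate of burst frequency at the
  default conditions).
* Burst duration is resolved only to one bin (1 s by default).
* Neuron matching trusts ROI identifiers; no spatial registration is
  attempted.
* Amplitude effects injected at the spike level interact with the
  baseline estimator: stronger transients can raise the local window
  minimum, so recovered amplitude ratios should be expected to compress
  toward 1 relative to the injected multiplier rather than match it
  exactly.
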