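#' Build the population activity trace
#'
#' Converts per-neuron events (and the dF/F0 matrix) into a per-bin population
#' activity trace: the fraction of recorded cells simultaneously active, in
#' \\[0, 1\\], together with the population-mean dF/F0.
#'
#' Two definitions of "active" are offered. In `event_bin` mode (default) time
#' is tiled into bins of `bin_s` seconds and a cell is active in a bin when it
#' has at least one detected event there; binning makes coincidence detection
#' robust to within-burst jitter. In `suprathreshold` mode each frame is its
#' own bin and a cell is active when its dF/F0 exceeds `threshold_dff` at that
#' frame.
#'
#' @param events An `event_set` from [detect_events()] (used in `event_bin`
#'   mode).
#' @param dff The `trace_set` (kind `"dff"`) the events came from; must share
#'   ROI ids, duration and frame rate.
#' @param activity_mode `"event_bin"` or `"suprathreshold"`.
#' @param bin_s Bin width in seconds for `event_bin` mode (default 1).
#' @param threshold_dff Activity threshold for `suprathreshold` mode; defaults
#'   to the detection threshold stored in `events`.
#' @return A `population_activity` data frame with columns `bin_start_s`,
#'   `bin_end_s`, `active_fraction`, `mean_dff`, carrying `n_cells`, the mode
#'   and the recording geometry as attributes.
#' @export
build_population_activity <- function(events, dff,
                                      activity_mode = c("event_bin", "suprathreshold"),
                                      bin_s = 1.0, threshold_dff = NULL) {
  activity_mode <- match.arg(activity_mode)
  stopifnot_trace(dff)
  if (dff$kind != "dff") stop("population activity requires a dff trace_set", call. = FALSE)
  roi_ids <- attr(events, "roi_ids")
  if (is.null(roi_ids) || !identical(roi_ids, dff$roi_ids)) {
    stop("events and dff must come from the same recording (matching roi_ids)", call. = FALSE)
  }
  if (!isTRUE(all.equal(attr(events, "frame_rate_hz"), dff$frame_rate_hz))) {
    stop("events and dff disagree on frame rate", call. = FALSE)
  }
  n_cells <- length(roi_ids)
  dur <- trace_duration_s(dff)
  tt <- trace_times_s(dff)

  if (activity_mode == "event_bin") {
    check_scalar(bin_s, "bin_s", lower = 0, strict_lower = TRUE)
    n_bins <- max(1L, as.integer(ceiling(dur / bin_s - 1e-9)))
    starts <- (seq_len(n_bins) - 1) * bin_s
    ends <- pmin(starts + bin_s, dur)
    bin_of <- function(t) pmin(n_bins, as.integer(floor(t / bin_s)) + 1L)
    active <- matrix(FALSE, nrow = n_bins, ncol = n_cells,
                     dimnames = list(NULL, roi_ids))
    if (nrow(events) > 0L) {
      active[cbind(bin_of(events$time_s), match(events$roi_id, roi_ids))] <- TRUE
    }
    frac <- rowSums(active) / n_cells
    fbin <- bin_of(tt)
    mean_dff <- as.numeric(tapply(rowMeans(dff$values), fbin, mean))
    # bins past the last frame (possible only if bin_s < frame period) are empty
    md <- rep(NA_real_, n_bins)
    md[sort(unique(fbin))] <- mean_dff
    pop <- data.frame(bin_start_s = starts, bin_end_s = ends,
                      active_fraction = frac, mean_dff = md)
  } else {
    if (is.null(threshold_dff)) threshold_dff <- attr(events, "threshold_dff")
    if (is.null(threshold_dff)) threshold_dff <- 0.20
    check_scalar(threshold_dff, "threshold_dff", lower = 0, strict_lower = TRUE)
    frac <- rowSums(dff$values > threshold_dff) / n_cells
    pop <- data.frame(bin_start_s = tt,
                      bin_end_s = tt + 1 / dff$frame_rate_hz,
                      active_fraction = frac,
                      mean_dff = rowMeans(dff$values))
    bin_s <- 1 / dff$frame_rate_hz
  }
  structure(pop,
            class = c("population_activity", "data.frame"),
            n_cells = n_cells, bin_s = bin_s, duration_s = dur,
            frame_rate_hz = dff$frame_rate_hz, activity_mode = activity_mode)
}

#' Detect synchronized network bursts
#'
#' A synchronized burst is a maximal run of consecutive bins whose population
#' active fraction strictly exceeds `sync_fraction` (default 0.30, i.e. 30% of
#' recorded cells; a bin exactly at the threshold is not part of a burst).
#' Runs separated by at most `min_gap_bins` sub-threshold bins are merged
#' (default 0: no merging). Bursts touching either recording edge are kept and
#' flagged `truncated`.
#'
#' @param pop A `population_activity` from [build_population_activity()].
#' @param sync_fraction Synchronization threshold, fraction of cells in
#'   (0, 1\\] (default 0.30).
#' @param min_gap_bins Maximum number of consecutive sub-threshold bins
#'   bridged inside one burst (default 0).
#' @return A `burst_set` data frame, one row per burst: `start_s`, `end_s`
#'   (left edges of the first and last bin), `duration_s` (= `end_s` -
#'   `start_s` + one bin width), `peak_active_fraction`, `amplitude` (maximum
#'   population-mean dF/F0 inside the burst), `truncated`.
#' @export
detect_bursts <- function(pop, sync_fraction = 0.30, min_gap_bins = 0L) {
  if (!inherits(pop, "population_activity")) {
    stop("expected a population_activity", call. = FALSE)
  }
  check_scalar(sync_fraction, "sync_fraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(min_gap_bins, "min_gap_bins", lower = 0)
  above <- pop$active_fraction > sync_fraction
  runs <- suprathreshold_runs(above, as.integer(min_gap_bins))
  n_bins <- length(above)
  bin_w <- attr(pop, "bin_s")
  out <- data.frame(
    start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0),
    peak_active_fraction = numeric(0), amplitude = numeric(0),
    truncated = logical(0)
  )
  if (nrow(runs) > 0L) {
    out <- data.frame(
      start_s = pop$bin_start_s[runs$start],
      end_s = pop$bin_start_s[runs$end],
      duration_s = pop$bin_start_s[runs$end] - pop$bin_start_s[runs$start] + bin_w,
      peak_active_fraction = vapply(seq_len(nrow(runs)), function(i)
        max(pop$active_fraction[runs$start[i]:runs$end[i]]), numeric(1)),
      amplitude = vapply(seq_len(nrow(runs)), function(i)
        max(pop$mean_dff[runs$start[i]:runs$end[i]], na.rm = TRUE), numeric(1)),
      truncated = runs$start == 1L | runs$end == n_bins
    )
  }
  structure(out,
            class = c("burst_set", "data.frame"),
            duration_s = attr(pop, "duration_s"),
            sync_fraction = sync_fraction, bin_s = bin_w,
            activity_mode = attr(pop, "activity_mode"),
            n_cells = attr(pop, "n_cells"))
}

# Maximal TRUE-runs of a logical vector, merging runs separated by <= max_gap
# FALSE bins. Returns a data.frame(start, end) of 1-based inclusive indices.
suprathreshold_runs <- function(above, max_gap = 0L) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  if (length(idx) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  s <- starts[idx]
  e <- ends[idx]
  if (max_gap > 0L && length(s) > 1L) {
    merged_s <- s[1L]
    merged_e <- e[1L]
    for (i in 2L:length(s)) {
      gap <- s[i] - merged_e[length(merged_e)] - 1L
      if (gap <= max_gap) {
        merged_e[length(merged_e)] <- e[i]
      } else {
        merged_s <- c(merged_s, s[i])
        merged_e <- c(merged_e, e[i])
      }
    }
    s <- merged_s
    e <- merged_e
  }
  data.frame(start = s, end = e)
}

#' Summarize synchronized bursts of one recording
#'
#' @param bursts A `burst_set` from [detect_bursts()].
#' @param duration_s Recording duration in seconds; defaults to the duration
#'   stored in `bursts`.
#' @param exclude_truncated_duration Exclude edge-truncated bursts from the
#'   mean duration (default TRUE; their durations are biased low). They always
#'   count toward frequency and amplitude.
#' @return One-row data frame: `n_bursts`, `burst_frequency` (bursts/minute),
#'   `mean_amplitude`, `mean_duration_s`, `has_bursts`. Means are `NA` when no
#'   (eligible) bursts exist.
#' @export
summarize_bursts <- function(bursts, duration_s = NULL,
                             exclude_truncated_duration = TRUE) {
  if (is.null(duration_s)) duration_s <- attr(bursts, "duration_s")
  if (is.null(duration_s) || duration_s <= 0) {
    stop("positive recording duration required", call. = FALSE)
  }
  n <- nrow(bursts)
  dur_pool <- if (exclude_truncated_duration) {
    bursts$duration_s[!bursts$truncated]
  } else bursts$duration_s
  data.frame(
    n_bursts = n,
    burst_frequency = n / (duration_s / 60),
    mean_amplitude = if (n > 0L) mean(bursts$amplitude) else NA_real_,
    mean_duration_s = if (length(dur_pool) > 0L) mean(dur_pool) else NA_real_,
    has_bursts = n > 0L
  )
}

#' Post/baseline relative change in burst properties
#'
#' Element-wise post/baseline ratios of burst frequency, amplitude and
#' duration for one recording set. A ratio is `NA` (flagged undefined) when
#' either side is undefined or the baseline value is 0.
#'
#' @param baseline,post One-row burst summaries from [summarize_bursts()].
#' @return One-row data frame: `frequency_ratio`, `amplitude_ratio`,
#'   `duration_ratio`.
#' @export
relative_change <- function(baseline, post) {
  ratio <- function(b, p) {
    if (is.na(b) || is.na(p) || b == 0) NA_real_ else p / b
  }
  data.frame(
    frequency_ratio = ratio(baseline$burst_frequency, post$burst_frequency),
    amplitude_ratio = ratio(baseline$mean_amplitude, post$mean_amplitude),
    duration_ratio = ratio(baseline$mean_duration_s, post$mean_duration_s)
  )
}

#' Circularly shift each neuron's event train (shuffle control)
#'
#' Destroys population synchrony while preserving every neuron's event count
#' and inter-event structure: each ROI's event times are shifted by an
#' independent uniform random offset, modulo the recording duration. Used as a
#' surrogate control — synchronized bursts detected in shifted data indicate
#' chance coincidence.
#'
#' @param events An `event_set`.
#' @param seed Integer seed for the per-neuron offsets.
#' @return A new `event_set` with shifted `time_s`/`frame` values.
#' @export
shuffle_events <- function(events, seed = 1L) {
  dur <- attr(events, "duration_s")
  rate <- attr(events, "frame_rate_hz")
  roi_ids <- attr(events, "roi_ids")
  set.seed(as.integer(seed))
  offsets <- runif(length(roi_ids), 0, dur)
  names(offsets) <- roi_ids
  ev <- as.data.frame(events)
  if (nrow(ev) > 0L) {
    ev$time_s <- (ev$time_s + offsets[ev$roi_id]) %% dur
    ev$frame <- as.integer(round(ev$time_s * rate)) + 1L
    ev <- ev[order(match(ev$roi_id, roi_ids), ev$frame), , drop = FALSE]
    rownames(ev) <- NULL
  }
  attrs <- attributes(events)
  attrs$row.names <- attr(ev, "row.names")
  attrs$names <- names(ev)
  attributes(ev) <- attrs
  ev
}
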