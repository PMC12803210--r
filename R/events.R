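#' Detect calcium events on dF/F0 traces
#'
#' An event is a local maximum of the dF/F0 trace exceeding the amplitude
#' threshold (strict `>`, default 0.20). A frame qualifies as a local maximum
#' when its value strictly dominates its neighbors; a plateau of equal values
#' flanked by strictly lower values yields one event at the plateau's first
#' frame, and recording endpoints may qualify against their single neighbor.
#' Candidates closer than `min_distance_frames` are resolved greedily in order
#' of descending amplitude (ties broken by earlier frame); with the default
#' distance of 1 frame no pruning occurs.
#'
#' @param dff A `trace_set` of kind `"dff"`.
#' @param threshold_dff Amplitude threshold, unitless dF/F0 (default 0.20).
#' @param min_distance_frames Minimum inter-peak distance in frames
#'   (default 1).
#' @return An `event_set`: a data frame with columns `roi_id`, `frame`
#'   (1-based), `time_s`, `amplitude`, sorted by ROI then frame, carrying the
#'   recording duration, frame rate, full ROI list and detection settings as
#'   attributes.
#' @export
detect_events <- function(dff, threshold_dff = 0.20, min_distance_frames = 1L) {
  stopifnot_trace(dff)
  if (dff$kind != "dff") stop("detect_events expects a dff trace_set (run compute_dff first)", call. = FALSE)
  check_scalar(threshold_dff, "threshold_dff", lower = 0, strict_lower = TRUE)
  check_scalar(min_distance_frames, "min_distance_frames", lower = 1)
  min_distance_frames <- as.integer(min_distance_frames)

  res <- lapply(seq_along(dff$roi_ids), function(i) {
    frames <- find_peaks(dff$values[, i], threshold_dff, min_distance_frames)
    if (length(frames) == 0L) return(NULL)
    data.frame(roi_id = dff$roi_ids[i], frame = frames,
               time_s = (frames - 1) / dff$frame_rate_hz,
               amplitude = dff$values[frames, i],
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, res)
  if (is.null(ev)) {
    ev <- data.frame(roi_id = character(0), frame = integer(0),
                     time_s = numeric(0), amplitude = numeric(0),
                     stringsAsFactors = FALSE)
  }
  rownames(ev) <- NULL
  structure(ev,
            class = c("event_set", "data.frame"),
            duration_s = trace_duration_s(dff),
            frame_rate_hz = dff$frame_rate_hz,
            roi_ids = dff$roi_ids,
            threshold_dff = threshold_dff,
            min_distance_frames = min_distance_frames)
}

# Candidate peaks: compress runs of equal values; a run is a candidate iff its
# value exceeds the threshold and strictly dominates the adjacent runs where
# they exist (endpoint runs check their single neighbor). The candidate frame
# is the first frame of the run. Then greedy amplitude-first pruning enforces
# the minimum inter-peak distance.
find_peaks <- function(v, threshold, min_distance) {
  n <- length(v)
  if (n == 0L) return(integer(0))
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- r$values
  k <- length(vals)
  left_ok <- c(TRUE, vals[-1L] > vals[-k])
  right_ok <- c(vals[-k] > vals[-1L], TRUE)
  cand <- which(vals > threshold & left_ok & right_ok)
  frames <- starts[cand]
  if (length(frames) <= 1L || min_distance <= 1L) return(sort(frames))
  amps <- v[frames]
  ord <- order(-amps, frames)
  kept <- integer(0)
  for (f in frames[ord]) {
    if (all(abs(kept - f) >= min_distance)) kept <- c(kept, f)
  }
  sort(kept)
}

#' Per-neuron event summaries
#'
#' Summarizes an `event_set` into one row per ROI: event count, event
#' frequency in events/minute (`n_events / (duration_s / 60)`), and mean peak
#' amplitude. ROIs with zero events get frequency 0 and `NA` mean amplitude
#' (undefined, flagged by `has_events`).
#'
#' @param events An `event_set` from [detect_events()].
#' @return Data frame with columns `roi_id`, `n_events`, `event_frequency`,
#'   `mean_amplitude`, `has_events`, one row per ROI of the source recording
#'   (including silent ones), in the recording's ROI order.
#' @export
summarize_neurons <- function(events) {
  roi_ids <- attr(events, "roi_ids")
  duration_s <- attr(events, "duration_s")
  if (is.null(roi_ids) || is.null(duration_s) || duration_s <= 0) {
    stop("events must be an event_set with positive recording duration", call. = FALSE)
  }
  counts <- table(factor(events$roi_id, levels = roi_ids))
  mean_amp <- tapply(events$amplitude, factor(events$roi_id, levels = roi_ids),
                     mean)
  out <- data.frame(
    roi_id = roi_ids,
    n_events = as.integer(counts),
    event_frequency = as.numeric(counts) / (duration_s / 60),
    mean_amplitude = as.numeric(mean_amp),
    stringsAsFactors = FALSE
  )
  out$has_events <- out$n_events > 0L
  attr(out, "duration_s") <- duration_s
  rownames(out) <- NULL
  out
}
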