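#' Construct a trace set
#'
#' A `trace_set` holds a fluorescence time-series matrix for one recording:
#' one column per ROI (neuron), one row per frame, together with the frame
#' rate and a flag saying whether the values are raw fluorescence (arbitrary
#' units) or unitless dF/F0.
#'
#' @param values Numeric matrix, frames in rows, ROIs in columns.
#' @param frame_rate_hz Sampling rate in frames per second (> 0).
#' @param roi_ids Character vector of unique ROI identifiers, one per column.
#'   Defaults to the column names of `values`, or `roi_001`, `roi_002`, ...
#' @param kind Either `"raw"` or `"dff"`.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(values, frame_rate_hz, roi_ids = NULL, kind = c("raw", "dff")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
  }
  if (nrow(values) < 1L) stop("trace_set requires at least one frame", call. = FALSE)
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L || frame_rate_hz <= 0) {
    stop("frame_rate_hz must be a single positive number", call. = FALSE)
  }
  if (is.null(roi_ids)) {
    roi_ids <- colnames(values)
    if (is.null(roi_ids)) roi_ids <- sprintf("roi_%03d", seq_len(ncol(values)))
  }
  roi_ids <- as.character(roi_ids)
  if (length(roi_ids) != ncol(values)) {
    stop("roi_ids must have one entry per trace column", call. = FALSE)
  }
  if (anyDuplicated(roi_ids)) stop("roi_ids must be unique", call. = FALSE)
  if (any(!is.finite(values))) stop("trace values must be finite", call. = FALSE)
  colnames(values) <- roi_ids
  structure(
    list(values = values, frame_rate_hz = as.numeric(frame_rate_hz),
         roi_ids = roi_ids, kind = kind),
    class = "trace_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d ROIs x %d frames, %g Hz, kind = %s (%.1f s)\n",
              length(x$roi_ids), nrow(x$values), x$frame_rate_hz, x$kind,
              trace_duration_s(x)))
  invisible(x)
}

#' Number of frames in a trace set
#' @param trace A `trace_set`.
#' @return Integer frame count.
#' @export
n_frames <- function(trace) nrow(trace$values)

#' Recording duration of a trace set
#' @param trace A `trace_set`.
#' @return Duration in seconds (`n_frames / frame_rate_hz`).
#' @export
trace_duration_s <- function(trace) nrow(trace$values) / trace$frame_rate_hz

#' Frame times of a trace set
#' @param trace A `trace_set`.
#' @return Numeric vector of frame times in seconds, starting at 0.
#' @export
trace_times_s <- function(trace) (seq_len(nrow(trace$values)) - 1) / trace$frame_rate_hz

stopifnot_trace <- function(trace) {
  if (!inherits(trace, "trace_set")) stop("expected a trace_set", call. = FALSE)
  invisible(trace)
}
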