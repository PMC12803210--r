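#' Per-frame baseline fluorescence by sliding-window minimum
#'
#' The baseline F0 at each frame is the minimum raw fluorescence within a
#' sliding window of `window_s` seconds around (or trailing up to) that frame.
#' The window length in frames is `round(window_s * frame_rate_hz)`, minimum 1;
#' at the recording edges the window is truncated, never padded, and always
#' contains the current frame, so F0(t) <= F(t) everywhere.
#'
#' @param trace A raw `trace_set` with strictly positive values.
#' @param window_s Window length in seconds (default 20).
#' @param alignment `"centered"` (window straddles the frame, default) or
#'   `"trailing"` (window ends at the frame).
#' @return Numeric matrix of baselines, same shape as `trace$values`.
#' @export
compute_baseline <- function(trace, window_s = 20, alignment = c("centered", "trailing")) {
  stopifnot_trace(trace)
  alignment <- match.arg(alignment)
  if (trace$kind != "raw") stop("compute_baseline expects a raw trace_set", call. = FALSE)
  if (any(trace$values <= 0)) {
    stop("raw fluorescence must be strictly positive for baseline division", call. = FALSE)
  }
  check_scalar(window_s, "window_s", lower = 0, strict_lower = TRUE)
  nf <- n_frames(trace)
  width <- max(1L, as.integer(round(window_s * trace$frame_rate_hz)))
  if (width > nf) {
    warning(sprintf("baseline window (%d frames) exceeds recording length (%d frames); clamping to full recording",
                    width, nf), call. = FALSE)
    # the window is the whole recording for every frame
    mins <- apply(trace$values, 2L, min)
    return(matrix(rep(mins, each = nf), nrow = nf,
                  dimnames = dimnames(trace$values)))
  }
  out <- apply(trace$values, 2L, sliding_min_cpp, width = width,
               centered = (alignment == "centered"))
  out <- matrix(out, nrow = nf, dimnames = dimnames(trace$values))
  out
}

#' Convert raw fluorescence to dF/F0
#'
#' Normalizes each trace as `(F - F0) / F0` with F0 the sliding-window minimum
#' baseline of [compute_baseline()]. Because the window always contains the
#' current frame, the result is non-negative everywhere, exactly zero on
#' constant traces, and invariant under multiplicative rescaling of the raw
#' input.
#'
#' @inheritParams compute_baseline
#' @return A `trace_set` of kind `"dff"` with the same shape, frame rate and
#'   ROI identifiers as the input.
#' @export
compute_dff <- function(trace, window_s = 20, alignment = c("centered", "trailing")) {
  alignment <- match.arg(alignment)
  f0 <- compute_baseline(trace, window_s = window_s, alignment = alignment)
  if (any(f0 == 0)) stop("zero baseline encountered; raw input must be strictly positive", call. = FALSE)
  dff <- (trace$values - f0) / f0
  trace_set(dff, trace$frame_rate_hz, roi_ids = trace$roi_ids, kind = "dff")
}
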