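#' Write a trace set to the package's trace CSV dialect
#'
#' Plain comma-separated text: leading `#`-comment lines carry `key=value`
#' metadata (at least `frame_rate_hz` and `kind`), then a header row
#' `time_s,<roi_id_1>,...` and one row per frame. The time column starts at 0
#' and steps by `1/frame_rate_hz`.
#'
#' @param trace A `trace_set`.
#' @param path Output file path.
#' @param extra_metadata Named character/numeric vector of additional
#'   `key=value` metadata lines (e.g. `source`, `config_hash`).
#' @return `path`, invisibly.
#' @export
write_traces <- function(trace, path, extra_metadata = NULL) {
  stopifnot_trace(trace)
  meta <- c(frame_rate_hz = format(trace$frame_rate_hz, digits = 15),
            kind = trace$kind)
  if (!is.null(extra_metadata)) {
    meta <- c(meta, vapply(extra_metadata, function(v) as.character(v), character(1)))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
  tt <- trace_times_s(trace)
  header <- paste(c("time_s", trace$roi_ids), collapse = ",")
  writeLines(header, con)
  body <- apply(cbind(tt, trace$values), 1L, function(row)
    paste(sprintf("%.12g", row), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a trace set from the trace CSV dialect
#'
#' Parses `#` metadata lines, the header row and the frame rows written by
#' [write_traces()]. `frame_rate_hz` metadata is required; a missing `kind`
#' defaults to `"raw"` with a warning; unknown metadata keys are accepted with
#' a warning (metadata is open). The time column must be strictly increasing
#' with a constant step of `1/frame_rate_hz` (relative tolerance 1e-6);
#' violations are reported with the offending file line.
#'
#' @param path Path to a trace CSV file.
#' @return A `trace_set`; extra metadata is attached as the `metadata`
#'   attribute.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop(sprintf("trace file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- parse_metadata(lines[seq_len(n_meta)])
  known <- c("frame_rate_hz", "kind", "source", "config_hash")
  unknown <- setdiff(names(meta), known)
  if (length(unknown) > 0L) {
    warning(sprintf("unknown metadata key(s) ignored for validation: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!"frame_rate_hz" %in% names(meta)) {
    stop(sprintf("format error in %s: missing required metadata 'frame_rate_hz'", path),
         call. = FALSE)
  }
  rate <- suppressWarnings(as.numeric(meta[["frame_rate_hz"]]))
  if (!is.finite(rate) || rate <= 0) {
    stop(sprintf("format error in %s: invalid frame_rate_hz '%s'", path,
                 meta[["frame_rate_hz"]]), call. = FALSE)
  }
  kind <- meta[["kind"]]
  if (is.null(kind)) {
    warning("missing 'kind' metadata; assuming raw", call. = FALSE)
    kind <- "raw"
  }
  if (!kind %in% c("raw", "dff")) {
    stop(sprintf("format error in %s: kind must be 'raw' or 'dff', got '%s'",
                 path, kind), call. = FALSE)
  }
  tab <- utils::read.csv(text = lines[(n_meta + 1L):length(lines)],
                         check.names = FALSE)
  if (names(tab)[1L] != "time_s") {
    stop(sprintf("format error in %s: first column must be time_s", path), call. = FALSE)
  }
  if (ncol(tab) < 2L) stop(sprintf("format error in %s: no ROI columns", path), call. = FALSE)
  for (j in seq_along(tab)) {
    if (!is.numeric(tab[[j]])) {
      stop(sprintf("format error in %s: column '%s' is not numeric", path,
                   names(tab)[j]), call. = FALSE)
    }
  }
  tt <- tab$time_s
  step <- 1 / rate
  if (length(tt) > 1L) {
    d <- diff(tt)
    bad <- which(d <= 0 | abs(d - step) > 1e-6 * step)
    if (length(bad) > 0L) {
      # file line = metadata lines + header + 1-based row of the bad frame
      stop(sprintf("format error in %s, line %d: time column must increase by %g s per frame",
                   path, n_meta + 1L + bad[1L] + 1L, step), call. = FALSE)
    }
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  ts <- trace_set(values, rate, roi_ids = names(tab)[-1L], kind = kind)
  attr(ts, "metadata") <- meta
  ts
}

parse_metadata <- function(lines) {
  lines <- sub("^\\s*#\\s*", "", lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) == 2L) out[[trimws(p[1L])]] <- trimws(p[2L])
  }
  out
}

#' Write detected events to CSV
#'
#' One row per event (`roi_id, frame, time_s, amplitude`); `#` header comments
#' carry the detection configuration and recording geometry so the event set
#' can be reloaded losslessly with [read_events()].
#'
#' @param events An `event_set`.
#' @param path Output file path.
#' @param extra_metadata Optional named vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, extra_metadata = NULL) {
  meta <- c(duration_s = format(attr(events, "duration_s"), digits = 15),
            frame_rate_hz = format(attr(events, "frame_rate_hz"), digits = 15),
            threshold_dff = format(attr(events, "threshold_dff"), digits = 15),
            min_distance_frames = format(attr(events, "min_distance_frames")),
            roi_ids = paste(attr(events, "roi_ids"), collapse = ";"))
  if (!is.null(extra_metadata)) meta <- c(meta, vapply(extra_metadata, as.character, character(1)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
  writeLines("roi_id,frame,time_s,amplitude", con)
  if (nrow(events) > 0L) {
    writeLines(sprintf("%s,%d,%.12g,%.12g", events$roi_id, events$frame,
                       events$time_s, events$amplitude), con)
  }
  invisible(path)
}

#' Read an event CSV written by [write_events()]
#' @param path Path to an event CSV.
#' @return An `event_set` with its recording attributes restored.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("event file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- parse_metadata(lines[seq_len(n_meta)])
  req <- c("duration_s", "frame_rate_hz", "threshold_dff", "min_distance_frames", "roi_ids")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0L) {
    stop(sprintf("format error in %s: missing metadata %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tab <- utils::read.csv(text = lines[(n_meta + 1L):length(lines)],
                         colClasses = c("character", "integer", "numeric", "numeric"))
  structure(tab,
            class = c("event_set", "data.frame"),
            duration_s = as.numeric(meta$duration_s),
            frame_rate_hz = as.numeric(meta$frame_rate_hz),
            roi_ids = strsplit(meta$roi_ids, ";", fixed = TRUE)[[1L]],
            threshold_dff = as.numeric(meta$threshold_dff),
            min_distance_frames = as.integer(meta$min_distance_frames))
}

#' Write detected bursts to CSV
#'
#' One row per synchronized burst (`start_s, end_s, duration_s,
#' peak_active_fraction, amplitude, truncated`), with the detection settings
#' in `#` header comments.
#'
#' @param bursts A `burst_set`.
#' @param path Output file path.
#' @param extra_metadata Optional named vector of extra metadata lines.
#' @return `path`, invisibly.
#' @export
write_bursts <- function(bursts, path, extra_metadata = NULL) {
  meta <- c(duration_s = format(attr(bursts, "duration_s"), digits = 15),
            sync_fraction = format(attr(bursts, "sync_fraction"), digits = 15),
            bin_s = format(attr(bursts, "bin_s"), digits = 15),
            activity_mode = attr(bursts, "activity_mode"),
            n_cells = format(attr(bursts, "n_cells")))
  if (!is.null(extra_metadata)) meta <- c(meta, vapply(extra_metadata, as.character, character(1)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s", names(meta), unname(meta)), con)
  writeLines("start_s,end_s,duration_s,peak_active_fraction,amplitude,truncated", con)
  if (nrow(bursts) > 0L) {
    writeLines(sprintf("%.12g,%.12g,%.12g,%.12g,%.12g,%s", bursts$start_s,
                       bursts$end_s, bursts$duration_s,
                       bursts$peak_active_fraction, bursts$amplitude,
                       ifelse(bursts$truncated, "true", "false")), con)
  }
  invisible(path)
}
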