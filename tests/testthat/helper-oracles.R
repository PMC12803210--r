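# Independent brute-force oracles used to check the production implementations.
# These are written from the definitions, not from the package code paths.

# O(n*w) sliding-window minimum with truncation at the edges.
brute_sliding_min <- function(x, width, centered = TRUE) {
  n <- length(x)
  if (centered) {
    left <- (width - 1L) %/% 2L
    right <- width - 1L - left
  } else {
    left <- width - 1L
    right <- 0L
  }
  vapply(seq_len(n), function(t) {
    min(x[max(1L, t - left):min(n, t + right)])
  }, numeric(1))
}

# Exhaustive peak enumeration: a frame is a candidate iff it exceeds the
# threshold, is the first frame of its plateau, and the nearest differing
# values on each side (where any exist) are strictly lower. Greedy
# amplitude-first pruning then enforces the minimum inter-peak distance.
brute_find_peaks <- function(v, threshold, min_distance) {
  n <- length(v)
  is_cand <- logical(n)
  for (t in seq_len(n)) {
    if (!(v[t] > threshold)) next
    if (t > 1L && v[t - 1L] == v[t]) next  # not the first frame of a plateau
    ok <- TRUE
    j <- t - 1L
    while (j >= 1L && v[j] == v[t]) j <- j - 1L
    if (j >= 1L && v[j] >= v[t]) ok <- FALSE
    j <- t + 1L
    while (j <= n && v[j] == v[t]) j <- j + 1L
    if (j <= n && v[j] >= v[t]) ok <- FALSE
    is_cand[t] <- ok
  }
  frames <- which(is_cand)
  if (length(frames) <= 1L || min_distance <= 1L) return(frames)
  ord <- order(-v[frames], frames)
  kept <- integer(0)
  for (f in frames[ord]) {
    if (all(abs(kept - f) >= min_distance)) kept <- c(kept, f)
  }
  sort(kept)
}

# Maximal strict-suprathreshold runs by linear scan.
brute_runs <- function(frac, threshold) {
  above <- frac > threshold
  runs <- list()
  start <- NA_integer_
  for (i in seq_along(above)) {
    if (above[i] && is.na(start)) start <- i
    if (!above[i] && !is.na(start)) {
      runs[[length(runs) + 1L]] <- c(start, i - 1L)
      start <- NA_integer_
    }
  }
  if (!is.na(start)) runs[[length(runs) + 1L]] <- c(start, length(above))
  if (length(runs) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, runs)
  data.frame(start = m[, 1L], end = m[, 2L])
}

# Closed-form one-tailed Student-t computations.
closed_form_paired_t <- function(x, y, direction) {
  d <- y - x
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  p <- if (direction == "greater") pt(t_stat, n - 1, lower.tail = FALSE)
       else pt(t_stat, n - 1, lower.tail = TRUE)
  list(t = t_stat, df = n - 1, p = p)
}

closed_form_welch_t <- function(a, b, direction) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t_stat <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  p <- if (direction == "greater") pt(t_stat, df, lower.tail = FALSE)
       else pt(t_stat, df, lower.tail = TRUE)
  list(t = t_stat, df = df, p = p)
}

# Small helpers to build fixtures.
make_raw_trace <- function(values, frame_rate_hz = 1, roi_ids = NULL) {
  trace_set(matrix(values, ncol = 1, dimnames = list(NULL, roi_ids %||% "roi_001")),
            frame_rate_hz, kind = "raw")
}

make_dff_trace <- function(values, frame_rate_hz = 1) {
  if (!is.matrix(values)) values <- matrix(values, ncol = 1)
  colnames(values) <- sprintf("roi_%03d", seq_len(ncol(values)))
  trace_set(values, frame_rate_hz, kind = "dff")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-constructed population_activity for burst-detection tests.
make_pop <- function(frac, bin_s = 1, mean_dff = NULL) {
  n <- length(frac)
  pop <- data.frame(bin_start_s = (seq_len(n) - 1) * bin_s,
                    bin_end_s = seq_len(n) * bin_s,
                    active_fraction = frac,
                    mean_dff = mean_dff %||% frac)
  structure(pop, class = c("population_activity", "data.frame"),
            n_cells = 10L, bin_s = bin_s, duration_s = n * bin_s,
            frame_rate_hz = 1, activity_mode = "event_bin")
}
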