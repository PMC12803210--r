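#' Match neurons across two conditions by ROI identity
#'
#' Paired analyses use only neurons reliably tracked in both recordings:
#' the intersection of ROI ids, in the baseline table's order. Unmatched
#' neurons on either side are reported via a message and returned in the
#' `dropped` attribute.
#'
#' @param baseline,comparison Per-neuron summary data frames (from
#'   [summarize_neurons()]) each carrying a `roi_id` column.
#' @return Data frame of matched pairs: `roi_id`, baseline columns suffixed
#'   `_baseline`, comparison columns suffixed `_comparison`.
#' @export
match_neurons <- function(baseline, comparison) {
  if (!"roi_id" %in% names(baseline) || !"roi_id" %in% names(comparison)) {
    stop("both summary tables must carry a roi_id column", call. = FALSE)
  }
  common <- intersect(baseline$roi_id, comparison$roi_id)
  if (length(common) == 0L) {
    stop("no neurons could be matched across conditions (empty roi_id intersection)",
         call. = FALSE)
  }
  common <- baseline$roi_id[baseline$roi_id %in% common]  # preserve order
  dropped <- list(baseline_only = setdiff(baseline$roi_id, common),
                  comparison_only = setdiff(comparison$roi_id, common))
  n_drop <- lengths(dropped)
  if (sum(n_drop) > 0L) {
    message(sprintf("match_neurons: matched %d neurons; dropped %d baseline-only, %d comparison-only",
                    length(common), n_drop[[1L]], n_drop[[2L]]))
  }
  b <- baseline[match(common, baseline$roi_id), , drop = FALSE]
  cc <- comparison[match(common, comparison$roi_id), , drop = FALSE]
  out <- data.frame(roi_id = common, stringsAsFactors = FALSE)
  for (col in setdiff(names(b), "roi_id")) out[[paste0(col, "_baseline")]] <- b[[col]]
  for (col in setdiff(names(cc), "roi_id")) out[[paste0(col, "_comparison")]] <- cc[[col]]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Per-neuron comparison/baseline ratios
#'
#' Computes, for each matched neuron, the ratio of the comparison-condition
#' value to the baseline value for event frequency and mean peak amplitude.
#' Neurons whose baseline frequency is 0, or whose amplitude is undefined in
#' either condition, are flagged `excluded` (their ratios are `NA`); the
#' exclusion count is reported via a message.
#'
#' @param pairs Matched-pair table from [match_neurons()].
#' @return Data frame: `roi_id`, `frequency_ratio`, `amplitude_ratio`,
#'   `excluded`. The attribute `n_excluded` carries the exclusion count.
#' @export
condition_ratios <- function(pairs) {
  if (nrow(pairs) < 1L) stop("at least one matched pair required", call. = FALSE)
  fb <- pairs$event_frequency_baseline
  fc <- pairs$event_frequency_comparison
  ab <- pairs$mean_amplitude_baseline
  ac <- pairs$mean_amplitude_comparison
  freq_ok <- !is.na(fb) & fb > 0
  amp_ok <- !is.na(ab) & !is.na(ac) & ab > 0
  out <- data.frame(
    roi_id = pairs$roi_id,
    frequency_ratio = ifelse(freq_ok, fc / fb, NA_real_),
    amplitude_ratio = ifelse(amp_ok, ac / ab, NA_real_),
    excluded = !(freq_ok & amp_ok),
    stringsAsFactors = FALSE
  )
  n_excl <- sum(out$excluded)
  if (n_excl > 0L) {
    message(sprintf("condition_ratios: %d of %d neurons excluded (zero/undefined baseline)",
                    n_excl, nrow(out)))
  }
  attr(out, "n_excluded") <- n_excl
  out
}

new_test_result <- function(method, t, df, p, direction, n) {
  structure(list(method = method, t_statistic = unname(t),
                 degrees_of_freedom = unname(df), p_value = unname(p),
                 direction = direction, n = n),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("%s (one-tailed, %s): t = %.4f, df = %.2f, p = %.4g, n = %s\n",
              x$method, x$direction, x$t_statistic, x$degrees_of_freedom,
              x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Paired one-tailed t-test
#'
#' Tests the mean of the paired differences `d = y - x` against zero with a
#' Student t-statistic `t = mean(d) / (sd(d)/sqrt(n))` (sample SD, n - 1
#' denominator) on n - 1 degrees of freedom, and a one-tailed p-value in the
#' stated direction: `"greater"` tests whether `y` exceeds `x`.
#'
#' @param x Baseline values.
#' @param y Comparison values, same neurons and order as `x`.
#' @param direction `"greater"` or `"less"` (of `y` relative to `x`); no
#'   direction is inferred from the data.
#' @return A `t_test_result` (t, df, one-tailed p, direction, n).
#' @export
paired_t_one_tailed <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L) stop("paired t-test requires at least 2 complete pairs", call. = FALSE)
  d <- y - x
  if (sd(d) == 0) stop("degenerate variance: paired differences are constant", call. = FALSE)
  tt <- t.test(y, x, paired = TRUE, alternative = direction)
  new_test_result("paired t-test", tt$statistic, tt$parameter, tt$p.value,
                  direction, n)
}

#' Unpaired one-tailed t-test (Welch)
#'
#' Two-sample t-test without the equal-variance assumption (Welch's t with
#' Satterthwaite degrees of freedom; set `var_equal = TRUE` for the pooled
#' variant). The one-tailed direction refers to `group_b` relative to
#' `group_a`: `"greater"` tests whether `group_b`'s mean exceeds `group_a`'s.
#'
#' @param group_a Reference-group values.
#' @param group_b Comparison-group values.
#' @param direction `"greater"` or `"less"` (of `group_b` relative to
#'   `group_a`).
#' @param var_equal Use the pooled-variance test instead of Welch's (default
#'   FALSE).
#' @return A `t_test_result`; `n` holds both group sizes.
#' @export
unpaired_t_one_tailed <- function(group_a, group_b,
                                  direction = c("greater", "less"),
                                  var_equal = FALSE) {
  direction <- match.arg(direction)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group requires at least 2 observations", call. = FALSE)
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    stop("degenerate variance: both groups are constant", call. = FALSE)
  }
  tt <- t.test(group_b, group_a, alternative = direction, var.equal = var_equal)
  new_test_result(if (var_equal) "pooled two-sample t-test" else "Welch two-sample t-test",
                  tt$statistic, tt$parameter, tt$p.value, direction,
                  c(length(group_a), length(group_b)))
}

#' Summarize per-neuron ratios
#'
#' Ratios are right-skewed, so alongside the arithmetic mean this reports the
#' geometric mean (the exponentiated mean log-ratio), computed over defined,
#' strictly positive ratios only.
#'
#' @param ratios Numeric vector of per-neuron ratios (NAs allowed).
#' @return One-row data frame: `n`, `mean`, `geometric_mean`, `median`.
#' @export
summarize_ratios <- function(ratios) {
  r <- ratios[!is.na(ratios) & ratios > 0]
  data.frame(
    n = length(r),
    mean = if (length(r)) mean(r) else NA_real_,
    geometric_mean = if (length(r)) exp(mean(log(r))) else NA_real_,
    median = if (length(r)) stats::median(r) else NA_real_
  )
}
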