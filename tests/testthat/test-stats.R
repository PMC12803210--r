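make_summary <- function(ids, freq, amp) {
  data.frame(roi_id = ids, n_events = round(freq * 10),
             event_frequency = freq, mean_amplitude = amp,
             has_events = freq > 0, stringsAsFactors = FALSE)
}

test_that("neuron matching intersects by roi_id, reports drops, and is symmetric", {
  a <- make_summary(c("a", "b", "c"), c(1, 2, 3), c(0.3, 0.4, 0.5))
  b <- make_summary(c("b", "c", "d"), c(2, 2, 2), c(0.4, 0.4, 0.4))
  expect_message(pairs <- match_neurons(a, b), "dropped 1 baseline-only, 1 comparison-only")
  expect_equal(pairs$roi_id, c("b", "c"))
  expect_equal(attr(pairs, "dropped")$baseline_only, "a")
  expect_equal(attr(pairs, "dropped")$comparison_only, "d")
  # symmetric pair set
  pairs_rev <- suppressMessages(match_neurons(b, a))
  expect_setequal(pairs$roi_id, pairs_rev$roi_id)
  # identical sets: all matched, no message
  expect_silent(p2 <- match_neurons(a, a))
  expect_equal(nrow(p2), 3)
  # disjoint sets
  d <- make_summary(c("x", "y"), c(1, 1), c(0.2, 0.2))
  expect_error(match_neurons(a, d), "matched")
})

test_that("condition ratios divide comparison by baseline with division guards", {
  a <- make_summary(c("a", "b", "c"), c(2, 0, 1), c(0.3, NA, 0.5))
  b <- make_summary(c("a", "b", "c"), c(3, 1, 2), c(0.6, 0.2, 0.5))
  pairs <- match_neurons(a, b)
  expect_message(r <- condition_ratios(pairs), "excluded")
  expect_equal(r$frequency_ratio, c(1.5, NA, 2))
  expect_equal(r$amplitude_ratio, c(2, NA, 1))
  expect_equal(r$excluded, c(FALSE, TRUE, FALSE))
  expect_equal(attr(r, "n_excluded"), 1L)
  # identical conditions give unit ratios
  r1 <- condition_ratios(match_neurons(a, a))
  expect_true(all(r1$frequency_ratio[!r1$excluded] == 1))
})

test_that("paired one-tailed t matches the closed-form Student-t computation", {
  # symmetric differences: t = 0, p = 0.5
  res <- paired_t_one_tailed(c(0, 0), c(-1, 1), direction = "greater")
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 0.5)

  # differences (1, 2, 3): t = 2 / (1/sqrt(3))
  x <- c(0, 0, 0); y <- c(1, 2, 3)
  res2 <- paired_t_one_tailed(x, y, "greater")
  oracle <- closed_form_paired_t(x, y, "greater")
  expect_equal(res2$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res2$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(res2$degrees_of_freedom, 2)
  expect_equal(res2$p_value, oracle$p, tolerance = 1e-12)

  # random vectors, both directions, against the closed form
  set.seed(6)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    for (dir in c("greater", "less")) {
      got <- paired_t_one_tailed(x, y, dir)
      want <- closed_form_paired_t(x, y, dir)
      expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
      expect_equal(got$p_value, want$p, tolerance = 1e-10)
    }
    # the two one-tailed p-values partition the unit interval
    pg <- paired_t_one_tailed(x, y, "greater")$p_value
    pl <- paired_t_one_tailed(x, y, "less")$p_value
    expect_equal(pg + pl, 1, tolerance = 1e-12)
  }

  expect_error(paired_t_one_tailed(c(0, 0, 0), c(1, 1, 1)), "degenerate")
  expect_error(paired_t_one_tailed(1, 2), "at least 2")
})

test_that("unpaired one-tailed Welch t matches the closed-form computation", {
  res <- unpaired_t_one_tailed(c(1, 2, 3), c(1, 2, 3), "greater")
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 0.5)

  res2 <- unpaired_t_one_tailed(c(1, 2, 3), c(11, 12, 13), "greater")
  expect_lt(res2$p_value, 1e-3)

  set.seed(9)
  for (i in 1:25) {
    a <- rnorm(sample(3:30, 1), 0, 1)
    b <- rnorm(sample(3:30, 1), 0.5, 2)
    for (dir in c("greater", "less")) {
      got <- unpaired_t_one_tailed(a, b, dir)
      want <- closed_form_welch_t(a, b, dir)
      expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
      expect_equal(got$degrees_of_freedom, want$df, tolerance = 1e-10)
      expect_equal(got$p_value, want$p, tolerance = 1e-10)
    }
  }

  expect_error(unpaired_t_one_tailed(c(1), c(1, 2)), "at least 2")
  expect_error(unpaired_t_one_tailed(c(1, 1), c(2, 2)), "degenerate")
})

test_that("type-I error of the paired test is nominal under a simulated null", {
  set.seed(123)
  reps <- 400
  alpha <- 0.05
  rejections <- sum(vapply(seq_len(reps), function(i) {
    x <- rnorm(30, 1, 0.3)
    y <- rnorm(30, 1, 0.3)
    paired_t_one_tailed(x, y, "greater")$p_value < alpha
  }, logical(1)))
  # binomial 99% bounds around alpha
  bound <- 2.576 * sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(rejections / reps - alpha), bound + 1e-12)
})

test_that("ratio summaries report arithmetic and geometric context", {
  r <- c(0.5, 1, 2, NA)
  s <- summarize_ratios(r)
  expect_equal(s$n, 3)
  expect_equal(s$mean, mean(c(0.5, 1, 2)))
  expect_equal(s$geometric_mean, 1)
})
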