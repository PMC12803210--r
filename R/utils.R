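#' Derive independent per-stage seeds from one top-level seed
#'
#' All randomness in the package flows from a single integer seed. Each stage
#' draws its own sub-seed from a stream keyed only by the top-level seed, so
#' adding a downstream stage never perturbs the draws of an earlier one.
#'
#' @param seed Top-level integer seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("parameter '%s' must be a single finite number", field), call. = FALSE)
  }
  bad_lo <- if (strict_lower) x <= lower else x < lower
  bad_hi <- if (strict_upper) x >= upper else x > upper
  if (bad_lo || bad_hi) {
    stop(sprintf("parameter '%s' (= %g) is outside its valid range", field, x), call. = FALSE)
  }
  invisible(x)
}
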