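# Internal numeric helpers shared across modules.

#' Geometric mean
#'
#' Computed in the log domain for numerical robustness with many factors.
#'
#' @param x Positive numeric vector.
#' @param na.rm Drop missing values before averaging.
#' @return The geometric mean of `x`.
#' @examples
#' geometric_mean(c(4, 9)) # 6
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0, na.rm = TRUE)) {
    stop("geometric mean requires strictly positive values", call. = FALSE)
  }
  exp(mean(log(x)))
}

# mean absolute deviation from the arithmetic mean (not the median-based
# stats::mad); this is the dispersion BestKeeper reports for raw Cq values
mean_abs_deviation <- function(x) {
  mean(abs(x - mean(x)))
}

# stop() with sprintf-style formatting, never with the call prefix
abort_fmt <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
}

# ranks with midpoint ties: 1 = smallest (most stable)
rank_ascending <- function(x) {
  rank(x, ties.method = "average")
}
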