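#' Lilliefors test statistic
#'
#' Kolmogorov-Smirnov distance between the empirical CDF of `x` and the
#' normal CDF with mean and SD *estimated from the sample*. Because the
#' parameters are estimated, the usual KS null distribution does not apply;
#' see [lilliefors_test()] for calibrated p-values.
#'
#' @param x numeric vector, length >= 4, non-degenerate
#' @return the sup-norm distance D in \[0, 1\]
#' @export
lilliefors_stat <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n < 4)
    stop_msrs("need at least 4 observations", class = "msrs_insufficient_data")
  s <- stats::sd(x)
  if (s == 0)
    stop_msrs("test undefined for constant data (sd = 0)", class = "msrs_degenerate_error")
  z <- stats::pnorm(x, mean(x), s)
  # sup over the step function: check both sides of each jump
  max(seq_len(n) / n - z, z - (seq_len(n) - 1) / n)
}

#' Lilliefors normality test with Monte-Carlo p-value
#'
#' The p-value is calibrated by simulation: `n_mc` standard-normal samples
#' of the same size are drawn, the statistic recomputed on each (location
#' and scale are estimated per replicate, so the null is exact up to
#' Monte-Carlo error), and `p = (1 + #\{D* >= D\}) / (n_mc + 1)`.
#'
#' @inheritParams lilliefors_stat
#' @param n_mc number of Monte-Carlo null replicates
#' @param seed RNG seed for reproducibility (`NULL` = current stream)
#' @param null_stats optional pre-computed vector of null statistics for this
#'   sample size (e.g. to amortize the null over many tests); when supplied,
#'   `n_mc` and `seed` are ignored.
#' @return list with `statistic`, `p.value`, `n`, `n_mc`
#' @export
lilliefors_test <- function(x, n_mc = 10000, seed = NULL, null_stats = NULL) {
  x <- x[!is.na(x)]
  D <- lilliefors_stat(x)
  n <- length(x)
  if (is.null(null_stats)) {
    null_stats <- with_seed(seed, lilliefors_null(n, n_mc))
  }
  p <- (1 + sum(null_stats >= D)) / (length(null_stats) + 1)
  list(statistic = D, p.value = p, n = n, n_mc = length(null_stats))
}

#' Monte-Carlo null distribution of the Lilliefors statistic
#'
#' @param n sample size
#' @param n_mc number of replicates
#' @return numeric vector of `n_mc` null statistics (uses the current RNG
#'   stream; wrap in your own `set.seed()` for reproducibility)
#' @export
lilliefors_null <- function(n, n_mc = 10000) {
  i_over_n <- seq_len(n) / n
  im1_over_n <- (seq_len(n) - 1) / n
  vapply(seq_len(n_mc), function(b) {
    y <- sort(stats::rnorm(n))
    z <- stats::pnorm(y, mean(y), stats::sd(y))
    max(i_over_n - z, z - im1_over_n)
  }, numeric(1))
}
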