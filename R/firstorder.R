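# First-order intensity statistics.

FIRSTORDER_NAMES <- c("Mean", "Median", "Minimum", "Maximum", "Range",
                      "Variance", "StdDev", "Skewness", "Kurtosis", "Energy",
                      "Entropy", "Uniformity", "RMS", "MeanAbsDev",
                      "P10", "P90")

# Core 16 statistics of a numeric vector. `hist_probs`, when supplied, is the
# probability histogram used for Entropy and Uniformity (otherwise the 64-bin
# discretized histogram of the values themselves). Variance/StdDev use the
# population convention (denominator n); Kurtosis is excess kurtosis.
# Zero-variance convention: Skewness = Kurtosis = 0.
firstorder_stats <- function(x, hist_probs = NULL, n_levels = 64L) {
  x <- x[!is.na(x)]
  if (!length(x)) stop("first-order statistics of an empty patch")
  n <- length(x)
  mu <- mean(x)
  v <- mean((x - mu)^2)
  s <- sqrt(v)
  if (v > 0) {
    skew <- mean((x - mu)^3) / s^3
    kurt <- mean((x - mu)^4) / v^2 - 3
  } else {
    skew <- 0; kurt <- 0
  }
  if (is.null(hist_probs)) {
    lev <- discretize(x, n_levels)
    hist_probs <- tabulate(lev, nbins = n_levels) / n
  }
  q <- unname(stats::quantile(x, c(0.1, 0.5, 0.9), type = 7))
  out <- c(mu, q[2], min(x), max(x), max(x) - min(x), v, s, skew, kurt,
           sum(x^2), shannon_entropy(hist_probs), sum(hist_probs^2),
           sqrt(mean(x^2)), mean(abs(x - mu)), q[1], q[3])
  names(out) <- FIRSTORDER_NAMES
  out
}

#' First-order features of an ROI patch
#'
#' The 16 first-order statistics of the masked voxel intensities: mean,
#' median, minimum, maximum, range, variance and standard deviation
#' (population convention), skewness and excess kurtosis (0 for constant
#' input), energy (sum of squares), entropy and uniformity of the 64-bin
#' discretized histogram (bits; constant input has entropy 0, uniformity 1),
#' root-mean-square, mean absolute deviation, and the 10th/90th percentiles.
#'
#' @param patch Numeric array/vector of voxel intensities, `NA` outside ROI.
#' @param n_levels Gray levels for the entropy/uniformity histogram.
#' @return Named numeric vector of length 16.
#' @export
firstorder_features <- function(patch, n_levels = 64L) {
  firstorder_stats(as.numeric(patch), n_levels = n_levels)
}
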