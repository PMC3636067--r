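#' Z-score a sample
#'
#' Removes the mean and divides by the sample standard deviation (`n - 1`
#' denominator).  Errors on constant samples.
#'
#' @param x numeric vector, `length(x) >= 2`.
#' @return standardized vector with mean 0 and SD 1.
#' @export
zscore <- function(x) {
  if (length(x) < 2L) stop_field("x", "need at least 2 observations")
  if (any(!is.finite(x))) stop_field("x", "must be finite")
  s <- sd(x)
  if (s <= 0) stop_field("x", "sample is constant (zero standard deviation)")
  (x - mean(x)) / s
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' `D` is the supremum over all points of the absolute difference of the two
#' empirical CDFs (right-continuous, so ties are handled naturally); the
#' p-value comes from the asymptotic Kolmogorov distribution evaluated at
#' `sqrt(n_eff) * D` with effective size `n_eff = n1 * n2 / (n1 + n2)`.
#' With `zscore_first = TRUE` each sample is independently standardized
#' before comparison, so the test asks whether the distributions agree up to
#' location and scale.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param zscore_first standardize each sample first? (default `FALSE`).
#' @return object of class `ks_comparison` with fields `D`, `p_value`,
#'   `n1`, `n2`, `zscored`.
#' @export
ks_two_sample <- function(a, b, zscore_first = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    stop_field("a/b", "each sample needs at least 2 observations")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_field("a/b", "samples must be finite")
  if (zscore_first) {
    a <- zscore(a)
    b <- zscore(b)
  }
  n1 <- length(a); n2 <- length(b)
  pts <- sort(unique(c(a, b)))
  Fa <- findInterval(pts, sort(a)) / n1
  Fb <- findInterval(pts, sort(b)) / n2
  D <- max(abs(Fa - Fb))
  n_eff <- n1 * n2 / (n1 + n2)
  structure(list(D = D, p_value = kolmogorov_sf(sqrt(n_eff) * D),
                 n1 = n1, n2 = n2, zscored = isTRUE(zscore_first)),
            class = "ks_comparison")
}

# Survival function of the Kolmogorov distribution,
# P(K > lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2).
kolmogorov_sf <- function(lambda) {
  if (lambda <= 0) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @export
print.ks_comparison <- function(x, ...) {
  cat(sprintf("<ks_comparison> D = %.4f, p = %.4g (n1 = %d, n2 = %d%s)\n",
              x$D, x$p_value, x$n1, x$n2,
              if (x$zscored) ", z-scored" else ""))
  invisible(x)
}

#' Paired empirical quantiles for a quantile-quantile plot
#'
#' Quantiles of each sample at the plotting-position probabilities
#' `(i - 0.5) / n_points`, using linear interpolation between the closest
#' order statistics (the type-5 rule, whose plotting positions are exactly
#' `(i - 0.5) / n`).  If the two distributions agree up to an affine map,
#' the pairs fall on a straight line.
#'
#' @param a,b nonempty numeric samples.
#' @param n_points number of probability points (>= 2, default 100).
#' @return data frame of class `qq_pairs` with columns `prob`, `q_a`, `q_b`.
#' @export
qq_pairs <- function(a, b, n_points = 100) {
  n_points <- check_count(n_points, "n_points", min = 2)
  if (!length(a) || !length(b)) stop_field("a/b", "samples must be nonempty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop_field("a/b", "samples must be finite")
  probs <- (seq_len(n_points) - 0.5) / n_points
  out <- data.frame(prob = probs,
                    q_a = quantile(a, probs, type = 5, names = FALSE),
                    q_b = quantile(b, probs, type = 5, names = FALSE))
  class(out) <- c("qq_pairs", "data.frame")
  out
}
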