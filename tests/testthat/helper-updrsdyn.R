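# Shared fixtures and independent oracles for the test suite.

# A small deterministic series: linear trend plus fixed perturbations.
make_series <- function(n = 12, id = "T01", slope = 2, intercept = 10,
                        bumps = NULL, t_max = 3) {
  times <- seq(0.1, t_max, length.out = n)
  y <- intercept + slope * times
  if (!is.null(bumps)) y <- y + bumps
  list(patient_id = id, times = times, scores = y)
}

# Independent brute-force two-sample KS statistic: max ECDF difference
# scanned over every pooled sample point, with ECDFs computed by counting.
brute_force_ks_D <- function(a, b) {
  pts <- c(a, b)
  max(vapply(pts, function(p) {
    abs(mean(a <= p) - mean(b <= p))
  }, 0))
}

# Independent quantile oracle: plotting position (i - 0.5)/n with linear
# interpolation between the two nearest order statistics.
brute_force_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  vapply(p, function(pp) {
    h <- n * pp + 0.5
    lo <- floor(h)
    if (lo < 1) return(xs[1L])
    if (lo >= n) return(xs[n])
    xs[lo] + (h - lo) * (xs[lo + 1L] - xs[lo])
  }, 0)
}

# Independent curvature computation: explicit loop over interior points.
brute_force_curvature <- function(times, values) {
  total <- 0
  for (i in 2:(length(times) - 1)) {
    s_right <- (values[i + 1] - values[i]) / (times[i + 1] - times[i])
    s_left <- (values[i] - values[i - 1]) / (times[i] - times[i - 1])
    total <- total + abs(s_right - s_left)
  }
  total
}

# KKT certificate for the trend-filter optimum: recover the dual vector by
# least squares from y - x = t(D) nu and check the subgradient conditions.
# Returns the worst violation (0 at a verified optimum).
kkt_violation <- function(times, y, fit, lam, slope_tol = 1e-6) {
  D <- updrsdyn:::slope_diff_matrix(times)
  x <- fit$trend
  nu <- qr.solve(t(D), y - x)
  consistency <- max(abs(t(D) %*% nu - (y - x)))
  Dx <- as.numeric(D %*% x)
  box <- max(0, max(abs(nu)) - lam)
  sign_err <- 0
  for (j in seq_along(Dx)) {
    if (abs(Dx[j]) > slope_tol)
      sign_err <- max(sign_err, abs(nu[j] - lam * sign(Dx[j])))
  }
  max(consistency, box, sign_err)
}

# Run the scipy epigraph-QP oracle; returns NULL if python is unusable.
trend_oracle <- function(times, y, lam) {
  script <- system.file("oracle", "trend_qp_oracle.py", package = "updrsdyn")
  inp <- as.character(jsonlite::toJSON(list(t = times, y = y, lam = lam),
                                       digits = NA, auto_unbox = TRUE))
  out <- tryCatch(
    suppressWarnings(system2("python", script, input = inp, stdout = TRUE,
                             stderr = FALSE)),
    error = function(e) NULL)
  if (is.null(out) || !length(out)) return(NULL)
  tryCatch(jsonlite::fromJSON(paste(out, collapse = "")),
           error = function(e) NULL)
}
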