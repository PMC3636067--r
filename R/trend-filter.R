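#' Total absolute curvature of values on an irregular grid
#'
#' Total variation of the discrete slope: with divided differences
#' `s_i = (x[i+1] - x[i]) / (t[i+1] - t[i])`, returns `sum |s_{i+1} - s_i|`
#' over interior points.  Zero iff the values are exactly collinear in time.
#'
#' @param times strictly increasing numeric vector, length >= 3.
#' @param values numeric vector, same length.
#' @return nonnegative scalar (points per year).
#' @export
curvature_penalty <- function(times, values) {
  if (length(times) < 3L) stop_field("times", "need at least 3 points")
  if (length(values) != length(times))
    stop_field("values", "must match `times` in length")
  if (is.unsorted(times, strictly = TRUE))
    stop_field("times", "must be strictly increasing (collapse duplicates upstream)")
  sum(abs(diff(diff(values) / diff(times))))
}

as_series_ty <- function(series) {
  if (inherits(series, "symptom_series"))
    list(t = series$times, y = as.numeric(series$scores),
         id = series$patient_id)
  else if (is.list(series) && !is.null(series$times) && !is.null(series$scores))
    list(t = as.numeric(series$times), y = as.numeric(series$scores),
         id = if (!is.null(series$patient_id)) series$patient_id else NA)
  else stop_field("series", "must be a symptom_series (or have times/scores)")
}

#' Critical regularization constant
#'
#' The smallest `lambda` at which the trend-filter solution is the ordinary
#' least-squares straight line.  Computed in closed form: the OLS residual
#' `y - x_ols` lies in the range of `t(D)`, so solving
#' `(D %*% t(D)) nu = D y` gives the dual certificate and
#' `lambda_max = max(abs(nu))`.
#'
#' @param times strictly increasing numeric vector, length >= 3.
#' @param y numeric data vector.
#' @return `lambda_max >= 0`.
#' @export
trend_lambda_max <- function(times, y) {
  n <- length(times)
  if (n < 3L) stop_field("times", "need at least 3 points")
  D <- slope_diff_matrix(times)
  nu <- solve(D %*% t(D), D %*% y)
  max(abs(nu))
}

# Dense slope-difference operator (m x n, m = n - 2); row j maps x to the
# change of divided-difference slope at interior point j + 1.
slope_diff_matrix <- function(times) {
  n <- length(times)
  h <- diff(times)
  if (any(h <= 0)) stop_field("times", "must be strictly increasing")
  m <- n - 2L
  D <- matrix(0, m, n)
  for (j in seq_len(m)) {
    D[j, j] <- 1 / h[j]
    D[j, j + 1L] <- -(1 / h[j] + 1 / h[j + 1L])
    D[j, j + 2L] <- 1 / h[j + 1L]
  }
  D
}

#' Fit a piecewise-linear convex trend
#'
#' Solves the convex program
#' `minimize 0.5 * sum((y - x)^2) + lambda * curvature_penalty(t, x)`,
#' whose solutions are piecewise linear in time with slope changes (knots)
#' only at data points.  `lambda = 0` interpolates the data;
#' `lambda >= trend_lambda_max()` returns the OLS straight line.  The solver
#' is coordinate descent on the dual box-constrained QP, terminated when the
#' primal-dual gap certifies the objective to within `tol` (relative).
#'
#' @param series a [symptom_series()] (or list with `times`/`scores`), at
#'   least 3 reports with distinct times.
#' @param lam regularization constant `>= 0` (points^2 per (points/year)).
#' @param knot_tol slope changes below this (points/year) are not knots
#'   (default 1e-6).
#' @param tol relative duality-gap tolerance (default 1e-10).
#' @return object of class `trend_fit`: `times`, `y`, `trend`, `lam`,
#'   `objective`, `slopes` (per segment), `knots` (interior indices),
#'   `slope_changes`, and `diagnostics` (iterations, duality gap).
#' @export
fit_trend <- function(series, lam, knot_tol = 1e-6, tol = 1e-10) {
  st <- as_series_ty(series)
  fits <- fit_trend_path(st$t, st$y, lam, knot_tol = knot_tol, tol = tol)
  fit <- fits[[1L]]
  fit$patient_id <- st$id
  fit
}

# Fit a whole lambda path at once (warm-started in C++); returns a list of
# trend_fit objects aligned with `lambdas`.
fit_trend_path <- function(times, y, lambdas, knot_tol = 1e-6, tol = 1e-10) {
  n <- length(times)
  if (n < 3L) stop_field("series", "need at least 3 reports with distinct times")
  if (length(y) != n) stop_field("series", "times/scores length mismatch")
  if (any(!is.finite(times)) || any(!is.finite(y)))
    stop_field("series", "times and scores must be finite")
  if (is.unsorted(times, strictly = TRUE))
    stop_field("series", "times must be strictly increasing")
  if (any(!is.finite(lambdas)) || any(lambdas < 0))
    stop_field("lam", "must be finite and >= 0")
  sol <- tf_path_cpp(times, y, lambdas, tol, 500L)
  lapply(seq_along(lambdas), function(l) {
    x <- sol$x[, l]
    slopes <- diff(x) / diff(times)
    dslope <- diff(slopes)
    knots <- which(abs(dslope) > knot_tol) + 1L
    structure(
      list(times = times, y = y, trend = x, lam = lambdas[l],
           objective = sol$objective[l], slopes = slopes,
           knots = knots, slope_changes = dslope[knots - 1L],
           diagnostics = list(iterations = sol$iterations[l],
                              duality_gap = sol$gap[l])),
      class = "trend_fit")
  })
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> n = %d, lambda = %.4g, objective = %.4g, %d knot(s)\n",
              length(x$times), x$lam, x$objective, length(x$knots)))
  invisible(x)
}

#' Cross-validate the trend regularization constant
#'
#' Builds a log-spaced grid of `n_lambdas` values over
#' `[lambda_max * 1e-4, lambda_max]`, randomly partitions the interior
#' reports into `n_folds` folds (the first and last report are never held
#' out, so held-out times always lie inside the fitted range), fits the
#' trend on the retained reports for every `lambda`, scores held-out
#' reports by linear interpolation of the fitted trend at their times, and
#' selects the `lambda` with the smallest mean squared test error.
#'
#' @param series a [symptom_series()] with at least `max(6, n_folds + 2)`
#'   reports.
#' @param n_lambdas grid size (default 30).
#' @param n_folds number of folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return object of class `cv_curve`: `lambdas`, `mean_test_error`,
#'   `se_test_error`, `lambda_star`, `folds`, `seed`.
#' @export
cross_validate_lambda <- function(series, n_lambdas = 30, n_folds = 5,
                                  seed = 1L) {
  st <- as_series_ty(series)
  n <- length(st$t)
  n_lambdas <- check_count(n_lambdas, "n_lambdas", min = 2)
  n_folds <- check_count(n_folds, "n_folds", min = 2)
  if (n < max(6, n_folds + 2))
    stop_field("series", sprintf("need at least %d reports for %d-fold CV",
                                 max(6, n_folds + 2), n_folds))
  lam_max <- trend_lambda_max(st$t, st$y)
  if (lam_max <= 0) lam_max <- 1e-8  # exactly collinear data
  lambdas <- exp(seq(log(lam_max * 1e-4), log(lam_max),
                     length.out = n_lambdas))
  interior <- seq(2L, n - 1L)
  folds <- with_seed(seed, {
    sample(rep_len(seq_len(n_folds), length(interior)))
  })
  err <- matrix(NA_real_, n_folds, n_lambdas)
  for (f in seq_len(n_folds)) {
    hold <- interior[folds == f]
    if (!length(hold)) next
    keep <- setdiff(seq_len(n), hold)
    fits <- fit_trend_path(st$t[keep], st$y[keep], lambdas)
    err[f, ] <- vapply(fits, function(fit) {
      pred <- approx(fit$times, fit$trend, xout = st$t[hold])$y
      mean((st$y[hold] - pred)^2)
    }, 0)
  }
  mean_err <- colMeans(err, na.rm = TRUE)
  se_err <- apply(err, 2, function(e) {
    e <- e[!is.na(e)]
    sd(e) / sqrt(length(e))
  })
  best <- which.min(mean_err)
  structure(
    list(lambdas = lambdas, mean_test_error = mean_err,
         se_test_error = se_err, lambda_star = lambdas[best],
         folds = folds, seed = seed),
    class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("<cv_curve> %d lambdas in [%.3g, %.3g]; lambda* = %.4g\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas),
              x$lambda_star))
  invisible(x)
}

#' Fit a trend with a cross-validated regularization constant
#'
#' Convenience wrapper: [cross_validate_lambda()] then [fit_trend()] at the
#' selected `lambda`.
#'
#' @inheritParams cross_validate_lambda
#' @param ... passed to [fit_trend()].
#' @return a `trend_fit` with the `cv_curve` attached as `$cv`.
#' @export
fit_trend_cv <- function(series, n_lambdas = 30, n_folds = 5, seed = 1L, ...) {
  cv <- cross_validate_lambda(series, n_lambdas, n_folds, seed)
  fit <- fit_trend(series, cv$lambda_star, ...)
  fit$cv <- cv
  fit
}

#' Detect abrupt trend changes
#'
#' Returns the fitted knots whose absolute slope change exceeds a threshold
#' (large, rapid shifts in progression rate).
#'
#' @param fit a `trend_fit`.
#' @param slope_jump_threshold minimum absolute slope change, points/year.
#' @return data frame with columns `index`, `time`, `slope_change`
#'   (possibly zero rows).
#' @export
detect_abrupt_changes <- function(fit, slope_jump_threshold) {
  stopifnot(inherits(fit, "trend_fit"))
  check_nonneg_inf <- function(v)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop_field("slope_jump_threshold", "must be a nonnegative number")
  check_nonneg_inf(slope_jump_threshold)
  sel <- abs(fit$slope_changes) > slope_jump_threshold
  data.frame(index = fit$knots[sel], time = fit$times[fit$knots[sel]],
             slope_change = fit$slope_changes[sel], row.names = NULL)
}

#' Flag outlier reports relative to a fitted trend
#'
#' Flags reports whose absolute residual exceeds `k` times the median
#' absolute residual of the series (a robust scale, so isolated large
#' deviations stand out).  Returns an empty vector when all residuals are
#' zero.
#'
#' @param series the fitted [symptom_series()].
#' @param fit the corresponding `trend_fit`.
#' @param k multiplier of the median absolute residual (default 3).
#' @return integer vector of report indices.
#' @export
detect_outlier_reports <- function(series, fit, k = 3) {
  st <- as_series_ty(series)
  stopifnot(inherits(fit, "trend_fit"))
  if (length(st$t) != length(fit$times))
    stop_field("fit", "does not match the series (length mismatch)")
  check_nonneg(k, "k")
  r <- abs(st$y - fit$trend)
  if (all(r == 0)) return(integer(0))
  which(r > k * median(r))
}
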