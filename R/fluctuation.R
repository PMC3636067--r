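#' Compute detrended residual records for one patient
#'
#' `r_i = y_i - trend_i` at each report time; the record keeps the time
#' since diagnosis so residuals can be pooled across patients without
#' losing the heteroscedasticity structure.
#'
#' @param series a [symptom_series()].
#' @param fit the matching `trend_fit` from [fit_trend()].
#' @return data frame with columns `patient_id`, `t`, `r`, `abs_r`.
#' @export
compute_residuals <- function(series, fit) {
  st <- as_series_ty(series)
  stopifnot(inherits(fit, "trend_fit"))
  if (length(st$y) != length(fit$trend))
    stop_field("fit", "does not match the series (length mismatch)")
  r <- st$y - fit$trend
  data.frame(patient_id = rep(as.character(st$id), length(r)),
             t = st$t, r = r, abs_r = abs(r), stringsAsFactors = FALSE)
}

#' Pool residual records across patients
#'
#' @param records list of data frames from [compute_residuals()].
#' @return single row-bound data frame.
#' @export
pool_residuals <- function(records) {
  do.call(rbind, c(records, list(make.row.names = FALSE)))
}

#' Fit the gamma fluctuation model
#'
#' Models the mean absolute residual as a log-linear function of time since
#' diagnosis, `E[|r| | t] = exp(beta0 + beta1 * t)`, with a gamma GLM
#' (log link) fitted by iteratively reweighted least squares.  Records with
#' `|r|` at or below `zero_tol` fall outside the gamma support and are
#' dropped (their count is reported).  Dispersion is estimated from Pearson
#' residuals; the coefficient covariance is scaled by it.
#'
#' @param records data frame with columns `t` and `abs_r` (e.g. from
#'   [pool_residuals()]).
#' @param zero_tol absolute residuals at or below this are dropped
#'   (default 1e-8).
#' @return object of class `gamma_fluctuation_fit`: `beta0`, `beta1`,
#'   `vcov` (2x2), `dispersion`, `n_used`, `n_dropped_zero`, `beta1_p`
#'   (two-sided Wald p-value for `beta1 = 0`).
#' @export
fit_gamma_glm <- function(records, zero_tol = 1e-8) {
  if (!is.data.frame(records) || !all(c("t", "abs_r") %in% names(records)))
    stop_field("records", "must be a data frame with columns `t` and `abs_r`")
  keep <- records$abs_r > zero_tol
  n_dropped <- sum(!keep)
  d <- records[keep, , drop = FALSE]
  if (nrow(d) < 10L)
    stop_field("records",
               sprintf("need at least 10 records with |r| > %g (have %d; %d dropped as zero)",
                       zero_tol, nrow(d), n_dropped))
  if (length(unique(d$t)) < 2L)
    stop_field("records", "need at least 2 distinct times")
  # muffle only the NaN warning from the gamma AIC term, which fires when
  # data are (near-)noiseless and the dispersion estimate underflows
  fit <- withCallingHandlers(
    glm(abs_r ~ t, family = Gamma(link = "log"), data = d,
        control = glm.control(epsilon = 1e-12, maxit = 200)),
    warning = function(w) {
      if (grepl("NaNs produced", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  # polish with Newton steps on the score equations sum((y/mu - 1) x) = 0,
  # which glm's deviance-based stopping rule leaves slightly unsolved
  X <- cbind(1, d$t)
  for (iter in seq_len(50)) {
    mu <- exp(X %*% beta)
    w <- d$abs_r / mu
    score <- crossprod(X, w - 1)
    if (max(abs(score)) < 1e-10) break
    J <- crossprod(X, X * as.numeric(w))
    beta <- beta + solve(J, score)
  }
  beta <- setNames(as.numeric(beta), names(coef(fit)))
  V <- vcov(fit)  # scaled by the Pearson dispersion estimate
  sm <- summary(fit)
  z <- beta[["t"]] / sqrt(V[2, 2])
  structure(
    list(beta0 = unname(beta[1L]), beta1 = unname(beta[2L]),
         vcov = unname(V), dispersion = sm$dispersion,
         n_used = nrow(d), n_dropped_zero = n_dropped,
         beta1_p = 2 * pnorm(-abs(z))),
    class = "gamma_fluctuation_fit")
}

#' @export
print.gamma_fluctuation_fit <- function(x, ...) {
  cat(sprintf("<gamma_fluctuation_fit> E|r| = exp(%.4f + %.4f t); dispersion %.3f; n = %d (%d zero dropped)\n",
              x$beta0, x$beta1, x$dispersion, x$n_used, x$n_dropped_zero))
  invisible(x)
}

#' Predict mean absolute fluctuation at given times
#'
#' Point prediction `exp(beta0 + beta1 * t)` with a Wald confidence
#' interval formed on the linear predictor and exponentiated (delta method
#' on the coefficient covariance), so the interval is symmetric on the log
#' scale.
#'
#' @param fit a `gamma_fluctuation_fit`.
#' @param t numeric vector of times since diagnosis (years, finite,
#'   `>= 0`).
#' @param level confidence level (default 0.95).
#' @return data frame with columns `t`, `mean`, `ci_low`, `ci_high`
#'   (UPDRS points).
#' @export
predict_mean_fluctuation <- function(fit, t, level = 0.95) {
  stopifnot(inherits(fit, "gamma_fluctuation_fit"))
  if (any(!is.finite(t)) || any(t < 0))
    stop_field("t", "must be finite and >= 0")
  eta <- fit$beta0 + fit$beta1 * t
  se <- sqrt(fit$vcov[1, 1] + 2 * t * fit$vcov[1, 2] + t^2 * fit$vcov[2, 2])
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(t = t, mean = exp(eta), ci_low = exp(eta - z * se),
             ci_high = exp(eta + z * se))
}

#' Adjusted Fisher-Pearson sample skewness
#'
#' Bias-corrected standardized third moment,
#' `G1 = g1 * sqrt(n (n - 1)) / (n - 2)` with `g1 = m3 / m2^(3/2)`.
#'
#' @param x numeric vector, `length(x) >= 3`, nonconstant.
#' @return sample skewness.
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  if (n < 3L) stop_field("x", "need at least 3 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop_field("x", "sample is constant")
  g1 <- mean((x - m)^3) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Bootstrap test of residual skewness
#'
#' Resamples the signed residuals with replacement `B` times and computes
#' the adjusted Fisher-Pearson skewness of each replicate.  The bootstrap
#' spread of the replicates estimates the sampling distribution of the
#' skewness statistic, so the test statistic is the replicate mean divided
#' by the replicate standard deviation, referred to a t distribution with
#' `B - 1` degrees of freedom (two-sided).  Dividing instead by the
#' standard error of the replicate mean would reject any sample whose
#' skewness is not exactly zero once `B` is large.
#'
#' @param residuals numeric vector of signed residuals, `n >= 8`,
#'   nonconstant.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @return object of class `skewness_test`: `observed`, `B`,
#'   `replicate_mean`, `replicate_sd`, `t`, `p_value`, `seed`.
#' @export
bootstrap_skewness_test <- function(residuals, B = 1000, seed = 1L) {
  B <- check_count(B, "B", min = 2)
  n <- length(residuals)
  if (n < 8L) stop_field("residuals", "need at least 8 residuals")
  if (any(!is.finite(residuals))) stop_field("residuals", "must be finite")
  if (sd(residuals) <= 0) stop_field("residuals", "zero-variance sample")
  observed <- sample_skewness(residuals)
  sk <- with_seed(seed, {
    vapply(seq_len(B), function(b)
      sample_skewness(residuals[sample.int(n, n, replace = TRUE)]), 0)
  })
  t_stat <- mean(sk) / sd(sk)
  structure(
    list(observed = observed, B = B, replicate_mean = mean(sk),
         replicate_sd = sd(sk), t = t_stat,
         p_value = 2 * pt(-abs(t_stat), df = B - 1), seed = seed),
    class = "skewness_test")
}

#' @export
print.skewness_test <- function(x, ...) {
  cat(sprintf("<skewness_test> observed %.3f; %d replicates (mean %.3f, SD %.3f); t = %.2f, p = %.3g\n",
              x$observed, x$B, x$replicate_mean, x$replicate_sd, x$t,
              x$p_value))
  invisible(x)
}

#' Scale a total-UPDRS clinically important difference to Parts I+II
#'
#' The Parts I+II subscale spans 0-68 of the 0-176 total (Parts I-III)
#' scale, so a CID established on the total scale maps to
#' `sub_max / total_max * cid`, rounded half-up to one decimal.  The
#' minimal CID of 4.3 total points maps to 1.7 subscale points and a
#' moderate CID of 8.5 maps to 3.3.
#'
#' @param total_updrs_cid CID on the total UPDRS scale (points, > 0).
#' @param sub_max maximum of the subscale (default 68).
#' @param total_max maximum of the total scale (default 176).
#' @return scaled CID in subscale points, one decimal.
#' @export
scale_cid <- function(total_updrs_cid, sub_max = 68, total_max = 176) {
  check_positive(total_updrs_cid, "total_updrs_cid")
  check_positive(sub_max, "sub_max")
  check_positive(total_max, "total_max")
  round_half_up(sub_max / total_max * total_updrs_cid, 1)
}
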