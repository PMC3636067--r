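test_that("curvature penalty is zero on lines and matches direct computation", {
  t <- c(0, 0.5, 1.2, 2, 3.3)
  expect_equal(curvature_penalty(t, 2 + 3 * t), 0)
  expect_equal(curvature_penalty(c(0, 1, 2), c(0, 1, 0)), 2)
  set.seed(5)
  for (rep in 1:5) {
    tt <- sort(runif(10, 0, 4))
    vv <- rnorm(10)
    expect_equal(curvature_penalty(tt, vv), brute_force_curvature(tt, vv))
  }
  expect_error(curvature_penalty(c(0, 0, 1), c(1, 2, 3)),
               "strictly increasing")
  expect_error(curvature_penalty(c(0, 1), c(1, 2)), "at least 3")
})

test_that("lambda = 0 interpolates the data and large lambda gives the OLS line", {
  set.seed(13)
  t <- sort(runif(15, 0, 4))
  y <- 12 + 2 * t + rnorm(15)
  s <- list(times = t, scores = y)
  f0 <- fit_trend(s, 0)
  expect_equal(f0$trend, y, tolerance = 1e-12)
  expect_equal(f0$objective, 0)

  lmax <- trend_lambda_max(t, y)
  ols <- unname(fitted(lm(y ~ t)))
  for (mult in c(1.05, 2, 10)) {
    f <- fit_trend(s, lmax * mult)
    expect_lt(max(abs(f$trend - ols)), 1e-6)
    expect_equal(length(f$knots), 0L)
  }
  # just below lambda_max the fit is no longer the straight line
  f_below <- fit_trend(s, lmax * 0.5)
  expect_gt(curvature_penalty(t, f_below$trend), 1e-8)
})

test_that("solutions satisfy the KKT subgradient certificate", {
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(5:25, 1)
    t <- sort(runif(n, 0, 5))
    y <- cumsum(rnorm(n)) + 15
    lam <- trend_lambda_max(t, y) * 10^runif(1, -3, 0)
    f <- fit_trend(list(times = t, scores = y), lam)
    expect_lt(kkt_violation(t, y, f, lam), 1e-5)
  }
})

test_that("regularization path is monotone and equivariant", {
  set.seed(19)
  t <- sort(runif(20, 0, 4))
  y <- 10 + 3 * t + rnorm(20, sd = 2)
  s <- list(times = t, scores = y)
  lmax <- trend_lambda_max(t, y)
  lams <- exp(seq(log(lmax * 1e-3), log(lmax), length.out = 12))
  fits <- lapply(lams, function(l) fit_trend(s, l))
  pen <- vapply(fits, function(f) curvature_penalty(t, f$trend), 0)
  fit_term <- vapply(fits, function(f) 0.5 * sum((y - f$trend)^2), 0)
  expect_true(all(diff(pen) <= 1e-8))
  expect_true(all(diff(fit_term) >= -1e-8))
  # fitted values stay within the hull of the data and the OLS line (the
  # two ends of the regularization path; the line itself may overshoot the
  # data range)
  ols <- unname(fitted(lm(y ~ t)))
  lo <- min(y, ols); hi <- max(y, ols)
  for (f in fits) {
    expect_gte(min(f$trend), lo - 1e-8)
    expect_lte(max(f$trend), hi + 1e-8)
  }
  # shift equivariance: y + c -> trend + c
  lam <- lams[6]
  f <- fit_trend(s, lam)
  f_shift <- fit_trend(list(times = t, scores = y + 7), lam)
  expect_equal(f_shift$trend, f$trend + 7, tolerance = 1e-7)
  # scale equivariance: a*y with a*lambda -> a*trend
  f_scale <- fit_trend(list(times = t, scores = 3 * y), 3 * lam)
  expect_equal(f_scale$trend, 3 * f$trend, tolerance = 1e-6)
})

test_that("cross-validation is deterministic and prefers smooth fits on near-linear data", {
  set.seed(23)
  t <- sort(runif(30, 0, 4))
  y <- 10 + 2 * t + rnorm(30, sd = 0.01)
  s <- list(times = t, scores = y)
  cv1 <- cross_validate_lambda(s, seed = 5)
  cv2 <- cross_validate_lambda(s, seed = 5)
  expect_identical(cv1, cv2)
  # near-linear truth: selected lambda in the upper half of the grid and the
  # selected fit nearly curvature-free
  expect_gte(which(cv1$lambdas == cv1$lambda_star), 15)
  f <- fit_trend(s, cv1$lambda_star)
  expect_lt(curvature_penalty(t, f$trend), 0.1)
  expect_equal(cv1$mean_test_error[which(cv1$lambdas == cv1$lambda_star)],
               min(cv1$mean_test_error))
})

test_that("a large slope break is recovered near the true change point", {
  set.seed(29)
  t <- sort(runif(40, 0, 4))
  truth <- archetype_trend("abrupt_change",
                           list(intercept = 10, slope1 = 1, slope2 = 9,
                                change_time = 2), t)
  y <- truth + rnorm(40, sd = 0.3)
  f <- fit_trend_cv(list(times = t, scores = y), seed = 3)
  ev <- detect_abrupt_changes(f, slope_jump_threshold = 3)
  expect_gte(nrow(ev), 1L)
  # strongest detected jump within one report of the true break
  best <- ev$time[which.max(abs(ev$slope_change))]
  idx_break <- findInterval(2, t)
  expect_lte(abs(findInterval(best, t) - idx_break), 1)
})

test_that("abrupt-change detection is empty for line fits and infinite thresholds", {
  set.seed(31)
  t <- sort(runif(20, 0, 4))
  y <- 10 + 2 * t + rnorm(20)
  lmax <- trend_lambda_max(t, y)
  f_line <- fit_trend(list(times = t, scores = y), lmax * 2)
  expect_equal(nrow(detect_abrupt_changes(f_line, 0)), 0L)
  f_wiggly <- fit_trend(list(times = t, scores = y), lmax * 1e-3)
  expect_equal(nrow(detect_abrupt_changes(f_wiggly, Inf)), 0L)
})

test_that("outlier reports are flagged against the robust residual scale", {
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 5, zero_noise = TRUE,
                                         seed = 44))
  s <- sim$cohort[[1L]]
  spiked <- s
  k_idx <- 7L
  spiked$scores <- as.integer(pmin(spiked$scores + 15L * (seq_along(spiked$scores) == k_idx), 68L))
  f <- fit_trend_cv(spiked, seed = 2)
  out <- detect_outlier_reports(spiked, f, k = 3)
  expect_true(k_idx %in% out)
  expect_lte(length(out), 3L)

  # equal-magnitude residuals: nothing exceeds k * median for k > 1
  t <- seq(0.1, 2, length.out = 10)
  y <- 10 + 2 * t + rep(c(1, -1), 5)
  f2 <- fit_trend(list(times = t, scores = y), trend_lambda_max(t, y) * 2)
  expect_length(detect_outlier_reports(list(times = t, scores = y), f2, k = 2),
                0L)
  # k = 0 flags every nonzero residual
  expect_length(detect_outlier_reports(list(times = t, scores = y), f2, k = 0),
                10L)
  # all-zero residuals give an empty list
  f3 <- fit_trend(list(times = t, scores = 10 + 2 * t), 1)
  expect_length(detect_outlier_reports(list(times = t, scores = 10 + 2 * t),
                                       f3, k = 0), 0L)
})
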