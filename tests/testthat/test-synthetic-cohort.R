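test_that("archetype trends follow their closed forms", {
  # piecewise-linear with one slope jump: plain arithmetic
  expect_equal(
    archetype_trend("abrupt_change",
                    list(intercept = 10, slope1 = 1, slope2 = 5,
                         change_time = 2),
                    0:4),
    c(10, 11, 12, 17, 22))
  # saturating increase starts at its intercept
  expect_equal(
    archetype_trend("smooth_increase",
                    list(intercept = 12, amplitude = 20, timescale = 6), 0),
    12)
  # decay to plateau: far past the timescale the plateau is reached
  far <- archetype_trend("plateau_decrease",
                         list(plateau = 8, start = 30, timescale = 2), 60)
  expect_lt(abs(far - 8), 1e-6)
  expect_error(archetype_trend("sigmoid", list(), 0:3), "unknown archetype")
  expect_error(archetype_trend("smooth_increase", list(), c(1, 1, 2)),
               "strictly increasing")
})

test_that("invalid simulation specs name the offending field", {
  expect_error(cohort_sim_spec(n_patients = 0), "n_patients")
  expect_error(cohort_sim_spec(reports_sd = -1), "reports_sd")
  expect_error(cohort_sim_spec(noise_shape = 0), "noise_shape")
  expect_error(cohort_sim_spec(archetype_weights = c(a = 1)),
               "archetype_weights")
  expect_error(cohort_sim_spec(reports_mean = 5), "reports_mean")
})

test_that("generator marginals match the cohort descriptives", {
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 100, seed = 1))
  expect_length(sim$cohort, 100L)
  d <- cohort_descriptives(sim$cohort)
  expect_lt(abs(d$reports_mean - 29), 3)
  expect_lt(abs(d$interval_mean_days - 45), 5)
  expect_lt(abs(d$age_mean - 54), 3)
  expect_true(all(vapply(sim$cohort,
                         function(s) length(s$times) >= 15, TRUE)))
  first <- vapply(sim$cohort, function(s) s$times[1L], 0)
  expect_true(all(first >= 0.7 - 1e-9 & first <= 1.3 + 1e-9))
})

test_that("zero-noise cohorts equal the rounded clipped ground-truth trend", {
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 20, zero_noise = TRUE,
                                         seed = 4))
  for (id in names(sim$cohort)) {
    g <- sim$ground_truth$patients[[id]]
    expect_equal(as.numeric(sim$cohort[[id]]$scores),
                 pmin(pmax(updrsdyn:::round_half_up(g$trend), 0), 68))
    expect_true(all(g$residuals == 0))
    expect_true(all(g$spikes == 0))
  }
})

test_that("simulation is bit-identical under a repeated seed and differs across seeds", {
  a <- simulate_cohort(cohort_sim_spec(n_patients = 10, seed = 11))
  b <- simulate_cohort(cohort_sim_spec(n_patients = 10, seed = 11))
  c <- simulate_cohort(cohort_sim_spec(n_patients = 10, seed = 12))
  expect_identical(a, b)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("pooled true residuals are zero-mean and positively skewed", {
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 100, seed = 8))
  r <- unlist(lapply(sim$ground_truth$patients, `[[`, "residuals"))
  expect_gt(length(r), 1000)
  expect_gt(sample_skewness(r), 0)
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
})

test_that("mean absolute residual follows exp(beta0 + beta1 t) within binned error", {
  spec <- cohort_sim_spec(n_patients = 150, seed = 21)
  sim <- simulate_cohort(spec)
  gt <- sim$ground_truth
  t <- unlist(lapply(gt$patients, `[[`, "times"))
  ar <- abs(unlist(lapply(gt$patients, `[[`, "residuals")))
  bins <- cut(t, breaks = quantile(t, seq(0, 1, 0.2)), include.lowest = TRUE)
  for (b in levels(bins)) {
    in_bin <- bins == b
    target <- mean(exp(spec$beta0 + spec$beta1 * t[in_bin]))
    se <- sd(ar[in_bin]) / sqrt(sum(in_bin))
    expect_lt(abs(mean(ar[in_bin]) - target), 3 * se)
  }
})

test_that("centered-gamma scaling constant matches Monte Carlo", {
  k <- 2
  m_closed <- updrsdyn:::gamma_centered_mad(k)
  set.seed(99)
  m_mc <- mean(abs(rgamma(2e5, shape = k) - k))
  expect_lt(abs(m_closed - m_mc), 4 * sd(abs(rgamma(1e4, k) - k)) / sqrt(2e5))
})

test_that("cross-section generator matches its spec", {
  cs <- simulate_cross_section(cross_section_spec(n_subjects = 500, seed = 7))
  expect_equal(nrow(cs), 500L)
  expect_lt(abs(mean(cs$age_at_diagnosis) - 59), 1.5)
  expect_true(all(cs$updrs_1_2 >= 0 & cs$updrs_1_2 <= 68))
  expect_true(all(cs$state %in% c("on", "off")))

  two <- simulate_cross_section(cross_section_spec(n_subjects = 2, seed = 1))
  expect_equal(nrow(two), 2L)

  flat <- simulate_cross_section(
    cross_section_spec(n_subjects = 10, age_sd_years = 0, seed = 3))
  expect_true(all(flat$age_at_diagnosis == 59))
})

test_that("ground truth sidecar JSON round-trips the key parameters", {
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 3, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth_json(sim$ground_truth, path)
  back <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  expect_equal(back$beta0, sim$ground_truth$beta0)
  expect_equal(back$beta1, sim$ground_truth$beta1)
  expect_setequal(names(back$patients), names(sim$cohort))
})
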