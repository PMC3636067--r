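test_that("Parts I+II scoring sums items and enforces the item structure", {
  expect_identical(score_parts_1_2(rep(0, 4), rep(0, 13)), 0L)
  expect_identical(score_parts_1_2(rep(4, 4), rep(4, 13)), 68L)
  expect_identical(score_parts_1_2(c(1, 0, 2, 1), rep(1, 13)), 17L)
  expect_error(score_parts_1_2(rep(1, 3), rep(1, 13)), "part1_items")
  expect_error(score_parts_1_2(rep(1, 4), rep(1, 12)), "part2_items")
  expect_error(score_parts_1_2(c(5, 0, 0, 0), rep(0, 13)), "item")
  expect_error(score_parts_1_2(c(-1, 0, 0, 0), rep(0, 13)), "item")
})

test_that("symptom series validates, sorts, and collapses duplicate times", {
  s <- symptom_series("a", c(0.3, 0.1, 0.2), c(5, 3, 4))
  expect_equal(s$times, c(0.1, 0.2, 0.3))
  expect_equal(s$scores, c(3L, 4L, 5L))
  # duplicate timestamps: mean score, rounded half-up
  d <- symptom_series("b", c(0.1, 0.1, 0.5), c(3, 4, 7))
  expect_equal(d$times, c(0.1, 0.5))
  expect_equal(d$scores, c(4L, 7L))  # mean 3.5 rounds up
  expect_error(symptom_series("c", c(0.1, 0.2), c(70, 2)), "scores")
  expect_error(symptom_series("c", c(-0.1, 0.2), c(5, 2)), "times")
})

filter_fixture <- function() {
  day <- 1 / 365.25
  pd_cohort(list(
    # exactly 15 reports spaced exactly 65 days: boundary, must be included
    symptom_series("boundary", seq(0, by = 65 * day, length.out = 15),
                   rep(10, 15)),
    # 14 reports spaced 10 days: too few
    symptom_series("sparse_count", seq(0, by = 10 * day, length.out = 14),
                   rep(10, 14)),
    # 20 reports spaced 80 days: interval too long
    symptom_series("slow", seq(0, by = 80 * day, length.out = 20),
                   rep(10, 20)),
    # 30 reports spaced 45 days: clearly included
    symptom_series("dense", seq(0, by = 45 * day, length.out = 30),
                   rep(10, 30)),
    # 10 reports spaced 90 days: fails both
    symptom_series("both_bad", seq(0, by = 90 * day, length.out = 10),
                   rep(10, 10))))
}

test_that("inclusion filter applies both thresholds with inclusive boundaries", {
  rep_ <- apply_inclusion_filter(filter_fixture())
  expect_setequal(rep_$included, c("boundary", "dense"))
  ex <- setNames(rep_$excluded$reason, rep_$excluded$patient_id)
  expect_equal(ex[["sparse_count"]], "too_few_reports")
  expect_equal(ex[["slow"]], "interval_too_long")
  expect_equal(ex[["both_bad"]], "too_few_reports")
  # included and excluded partition the cohort
  expect_setequal(c(rep_$included, rep_$excluded$patient_id),
                  names(filter_fixture()))
})

test_that("single-report series are excluded with the documented reason", {
  one <- pd_cohort(list(symptom_series("solo", 0.5, 12)))
  expect_equal(apply_inclusion_filter(one)$excluded$reason, "too_few_reports")
  expect_equal(apply_inclusion_filter(one, min_reports = 1)$excluded$reason,
               "interval_too_long")
})

test_that("filter is idempotent and monotone in its thresholds", {
  cohort <- filter_fixture()
  r1 <- apply_inclusion_filter(cohort)
  kept <- filter_cohort(cohort, r1)
  r2 <- apply_inclusion_filter(kept)
  expect_setequal(r2$included, r1$included)
  expect_equal(nrow(r2$excluded), 0L)
  # relaxing thresholds never removes an included patient
  relaxed <- apply_inclusion_filter(cohort, min_reports = 10,
                                    max_mean_interval_days = 85)
  expect_true(all(r1$included %in% relaxed$included))
})

test_that("cohort CSV writes and reads back losslessly", {
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 3, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(sim$cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(names(back), names(sim$cohort))
  for (id in names(back)) {
    expect_identical(back[[id]]$times, sim$cohort[[id]]$times)
    expect_identical(back[[id]]$scores, sim$cohort[[id]]$scores)
    expect_identical(back[[id]]$labels, sim$cohort[[id]]$labels)
  }
})

test_that("malformed cohort CSV rows are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,t_years,updrs_1_2,label",
               "p1,0.1,10,on",
               "p1,0.2,12,off",
               "p1,0.3,70,on",
               "p1,0.4,11,on"), path)
  expect_error(read_cohort_csv(path), "line 4")

  writeLines(c("patient_id,t_years,updrs_1_2,label",
               "p1,abc,10,on"), path)
  expect_error(read_cohort_csv(path), "line 2")

  writeLines(c("patient_id,t_years,updrs_1_2", "p1,0.1,10"), path)
  expect_error(read_cohort_csv(path), "missing column")
})

test_that("out-of-order rows are sorted within patient with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,t_years,updrs_1_2,label",
               "p1,0.3,12,on",
               "p1,0.1,10,on",
               "p1,0.2,11,off"), path)
  expect_warning(cohort <- read_cohort_csv(path), "out of time order")
  expect_equal(cohort[["p1"]]$times, c(0.1, 0.2, 0.3))
  expect_equal(cohort[["p1"]]$scores, c(10L, 11L, 12L))
})
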