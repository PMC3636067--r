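ARCHETYPES <- c("smooth_increase", "plateau_decrease", "abrupt_change",
                "outlier_spikes")

#' Specify a synthetic longitudinal cohort
#'
#' Parameterizes the generator that emulates a high-frequency self-report
#' cohort: per-patient report counts and intervals, age at diagnosis, a
#' ground-truth trend drawn from conforming (smooth saturating increase,
#' decrease to plateau) and nonconforming (abrupt slope change, isolated
#' spikes) archetypes, and zero-mean positively skewed residuals whose mean
#' absolute value grows as `exp(beta0 + beta1 * t)` with `t` years since
#' diagnosis.
#'
#' Report counts are drawn from a rounded truncated normal with minimum
#' `reports_min`; the underlying location is calibrated numerically so the
#' post-truncation mean equals `reports_mean` (a normal truncated below at
#' 15 would otherwise have mean above its nominal location).
#'
#' @param n_patients number of patients (default 100).
#' @param age_mean_years,age_sd_years age-at-diagnosis distribution
#'   (defaults 54, 9).
#' @param reports_mean,reports_sd target mean and nominal SD of per-patient
#'   report counts (defaults 29, 14).
#' @param reports_min minimum report count (default 15).
#' @param interval_mean_days,interval_sd_days inter-report gap distribution,
#'   truncated positive (defaults 45, 12).
#' @param first_report_offset_years mean time of the first report after
#'   diagnosis (default 1.0; per-patient jitter of +/- 0.3 yr uniform).
#' @param beta0,beta1 intercept (log points) and slope (per year) of the
#'   log mean-absolute-residual law (defaults 0.9555, 0.0512, so that mean
#'   absolute fluctuation is about 2.6 points at diagnosis and 5.9 points
#'   16 years later).
#' @param noise_shape gamma shape of the centered-gamma residual law
#'   (default 2; skewness `2/sqrt(shape)`).
#' @param archetype_weights nonnegative sampling weights over the four
#'   archetypes (default 0.55/0.2/0.15/0.1).
#' @param label_probs probabilities of per-report treatment labels
#'   on/off/unknown (default 0.6/0.1/0.3).
#' @param score_floor,score_ceiling score clipping bounds (0 and 68).
#' @param zero_noise if `TRUE`, residuals and spikes are suppressed so
#'   observed scores equal the rounded clipped true trend.
#' @param seed integer RNG seed.
#' @return validated object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_patients = 100,
                            age_mean_years = 54, age_sd_years = 9,
                            reports_mean = 29, reports_sd = 14,
                            reports_min = 15,
                            interval_mean_days = 45, interval_sd_days = 12,
                            first_report_offset_years = 1.0,
                            beta0 = 0.9555, beta1 = 0.0512,
                            noise_shape = 2,
                            archetype_weights = c(smooth_increase = 0.55,
                                                  plateau_decrease = 0.2,
                                                  abrupt_change = 0.15,
                                                  outlier_spikes = 0.1),
                            label_probs = c(on = 0.6, off = 0.1,
                                            unknown = 0.3),
                            score_floor = 0, score_ceiling = 68,
                            zero_noise = FALSE,
                            seed = 1L) {
  spec <- list(
    n_patients = check_count(n_patients, "n_patients"),
    age_mean_years = check_positive(age_mean_years, "age_mean_years"),
    age_sd_years = check_positive(age_sd_years, "age_sd_years"),
    reports_mean = check_positive(reports_mean, "reports_mean"),
    reports_sd = check_positive(reports_sd, "reports_sd"),
    reports_min = check_count(reports_min, "reports_min", min = 2),
    interval_mean_days = check_positive(interval_mean_days,
                                        "interval_mean_days"),
    interval_sd_days = check_positive(interval_sd_days, "interval_sd_days"),
    first_report_offset_years = check_nonneg(first_report_offset_years,
                                             "first_report_offset_years"),
    beta0 = beta0, beta1 = beta1,
    noise_shape = check_positive(noise_shape, "noise_shape"),
    archetype_weights = archetype_weights,
    label_probs = label_probs,
    score_floor = check_nonneg(score_floor, "score_floor"),
    score_ceiling = check_positive(score_ceiling, "score_ceiling"),
    zero_noise = isTRUE(zero_noise),
    seed = check_count(seed, "seed", min = 0))
  if (!is.numeric(c(beta0, beta1)) || any(!is.finite(c(beta0, beta1))))
    stop_field("beta0/beta1", "must be finite numbers")
  w <- archetype_weights
  if (length(w) != 4L || is.null(names(w)) ||
      !setequal(names(w), ARCHETYPES) || any(w < 0) || sum(w) <= 0)
    stop_field("archetype_weights",
               "must be 4 nonnegative, normalizable weights named after the archetypes")
  if (length(label_probs) != 3L ||
      !setequal(names(label_probs), c("on", "off", "unknown")) ||
      any(label_probs < 0) || sum(label_probs) <= 0)
    stop_field("label_probs", "must be nonnegative on/off/unknown weights")
  if (spec$reports_mean < spec$reports_min)
    stop_field("reports_mean", "must be >= reports_min")
  if (spec$score_ceiling <= spec$score_floor)
    stop_field("score_ceiling", "must exceed score_floor")
  structure(spec, class = "cohort_sim_spec")
}

#' Mean absolute deviation of a centered gamma variable
#'
#' For `G ~ Gamma(shape = k, scale = 1)`, returns `E|G - k|` in closed form
#' via the regularized incomplete gamma function.  Used to scale the
#' centered-gamma residual law so `E|residual|` hits its target exactly.
#'
#' @param shape gamma shape `k > 0`.
#' @return `E|G - k|`.
#' @keywords internal
gamma_centered_mad <- function(shape) {
  2 * shape * (stats::pgamma(shape, shape) - stats::pgamma(shape, shape + 1))
}

#' Draw zero-mean positively skewed residuals
#'
#' `r = s(t) * (G - k)` with `G ~ Gamma(k, 1)` and `s(t)` chosen so that
#' `E|r| = exp(beta0 + beta1 * t)`.  Skewness is `2/sqrt(k) > 0`.
#'
#' @param t times since diagnosis (years).
#' @param beta0,beta1 log-linear law of the mean absolute residual.
#' @param shape gamma shape `k`.
#' @return numeric vector of residuals (points).
#' @export
draw_skewed_residuals <- function(t, beta0, beta1, shape = 2) {
  check_positive(shape, "shape")
  s <- exp(beta0 + beta1 * t) / gamma_centered_mad(shape)
  s * (rgamma(length(t), shape = shape, scale = 1) - shape)
}

# Location mu such that a N(mu, sd) truncated below at `lower` has the
# requested mean.  Monotone in mu, solved by uniroot.
calibrate_truncated_mean <- function(target_mean, sd, lower) {
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * dnorm(a) / (1 - pnorm(a))
  }
  if (trunc_mean(target_mean) <= target_mean) return(target_mean)
  uniroot(function(mu) trunc_mean(mu) - target_mean,
          lower = target_mean - 8 * sd, upper = target_mean,
          tol = 1e-10)$root
}

# Rejection sampling from N(mean, sd) truncated below at `lower` (redraw,
# not clamp, to avoid a point mass at the boundary).
rtrunc_normal <- function(n, mean, sd, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Evaluate an archetype trend
#'
#' Ground-truth trend shapes for the generator:
#' * `smooth_increase`: concave saturating rise
#'   `intercept + amplitude * (1 - exp(-t / timescale))`;
#' * `plateau_decrease`: exponential decay to a plateau
#'   `plateau + (start - plateau) * exp(-t / timescale)`;
#' * `abrupt_change`: continuous piecewise-linear with one slope jump,
#'   `intercept + slope1 * t` before `change_time`, slope `slope2` after;
#' * `outlier_spikes`: same smooth saturating rise (isolated spikes are an
#'   observation-level effect recorded in the ground truth, not in the
#'   trend).
#'
#' @param name archetype name.
#' @param params named list of the parameters listed above.
#' @param times strictly increasing evaluation times (years).
#' @return trend values (points) at `times`.
#' @export
archetype_trend <- function(name, params, times) {
  if (length(times) && is.unsorted(times, strictly = TRUE))
    stop_field("times", "must be strictly increasing")
  p <- params
  switch(
    name,
    smooth_increase = ,
    outlier_spikes =
      p$intercept + p$amplitude * (1 - exp(-times / p$timescale)),
    plateau_decrease =
      p$plateau + (p$start - p$plateau) * exp(-times / p$timescale),
    abrupt_change =
      p$intercept + p$slope1 * pmin(times, p$change_time) +
        p$slope2 * pmax(times - p$change_time, 0),
    stop_field("name", sprintf("unknown archetype '%s'", name)))
}

# Draw archetype parameters; ranges keep trends within about [5, 55] so that
# clipping at the score bounds stays rare.
draw_archetype_params <- function(name, t_first, t_last) {
  switch(
    name,
    smooth_increase = ,
    outlier_spikes = list(intercept = runif(1, 8, 20),
                          amplitude = runif(1, 10, 30),
                          timescale = runif(1, 4, 12)),
    plateau_decrease = {
      plateau <- runif(1, 6, 15)
      list(plateau = plateau, start = plateau + runif(1, 8, 25),
           timescale = runif(1, 1.5, 5))
    },
    abrupt_change = list(
      intercept = runif(1, 8, 18),
      slope1 = runif(1, 0.5, 2.5),
      slope2 = runif(1, 0.5, 2.5) + sample(c(-1, 1), 1, prob = c(0.3, 0.7)) *
        runif(1, 3, 8),
      change_time = runif(1, t_first + 0.25 * (t_last - t_first),
                          t_first + 0.75 * (t_last - t_first))))
}

#' Simulate a synthetic longitudinal cohort
#'
#' Generates `spec$n_patients` symptom series with the reporting cadence,
#' demographics, archetypal trends and skewed heteroscedastic residual law
#' of the specification, plus the full ground truth needed for
#' parameter-recovery testing.  Observed scores are
#' `round(clip(trend + residual + spike, floor, ceiling))`; with
#' `zero_noise = TRUE` both residuals and spikes vanish so scores equal the
#' rounded clipped trend.  Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `cohort` (a [pd_cohort()]) and `ground_truth` (class
#'   `cohort_ground_truth`: per-patient archetype, parameters, true trend,
#'   residual and spike draws, plus the generating `beta0`, `beta1`,
#'   `noise_shape`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  with_seed(spec$seed, {
    mu_counts <- calibrate_truncated_mean(spec$reports_mean, spec$reports_sd,
                                          spec$reports_min)
    w <- spec$archetype_weights[ARCHETYPES]
    ids <- sprintf("P%03d", seq_len(spec$n_patients))
    series <- vector("list", spec$n_patients)
    gt_pat <- vector("list", spec$n_patients)
    for (i in seq_len(spec$n_patients)) {
      n_rep <- as.integer(round_half_up(
        rtrunc_normal(1, mu_counts, spec$reports_sd, spec$reports_min)))
      age <- rnorm(1, spec$age_mean_years, spec$age_sd_years)
      sex <- sample(c("female", "male"), 1, prob = c(0.52, 0.48))
      t_first <- max(0, spec$first_report_offset_years + runif(1, -0.3, 0.3))
      gaps <- rtrunc_normal(n_rep - 1, spec$interval_mean_days,
                            spec$interval_sd_days, 0)
      times <- t_first + cumsum(c(0, gaps)) / DAYS_PER_YEAR
      arch <- sample(ARCHETYPES, 1, prob = w)
      params <- draw_archetype_params(arch, times[1L], times[n_rep])
      trend <- archetype_trend(arch, params, times)
      if (spec$zero_noise) {
        resid <- numeric(n_rep)
        spikes <- numeric(n_rep)
      } else {
        resid <- draw_skewed_residuals(times, spec$beta0, spec$beta1,
                                       spec$noise_shape)
        spikes <- numeric(n_rep)
        if (arch == "outlier_spikes" && n_rep >= 3L) {
          cand <- seq(2L, n_rep - 1L)
          k_spk <- min(sample(1:2, 1), length(cand))
          idx <- cand[sample.int(length(cand), k_spk)]
          spikes[idx] <- runif(k_spk, 8, 18)
        }
      }
      obs <- round_half_up(pmin(pmax(trend + resid + spikes,
                                     spec$score_floor), spec$score_ceiling))
      labels <- sample(c("on", "off", "unknown"), n_rep, replace = TRUE,
                       prob = spec$label_probs[c("on", "off", "unknown")])
      series[[i]] <- symptom_series(ids[i], times, obs, labels,
                                    age_at_diagnosis = age, sex = sex)
      gt_pat[[i]] <- list(archetype = arch, params = params, times = times,
                          trend = trend, residuals = resid, spikes = spikes)
    }
    list(cohort = pd_cohort(series),
         ground_truth = structure(
           list(patients = setNames(gt_pat, ids), beta0 = spec$beta0,
                beta1 = spec$beta1, noise_shape = spec$noise_shape,
                zero_noise = spec$zero_noise),
           class = "cohort_ground_truth"))
  })
}

#' Specify a cross-sectional reference sample
#'
#' Emulates the shape of a clinic-collected reference dataset: ages at
#' diagnosis (default mean 59, SD 10) and one Parts I+II score per subject,
#' labeled `on`/`off` with on-state probability matching the roughly 82/18
#' split of recorded on versus off scores in clinical reference data.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_mean_years,age_sd_years age distribution (SD 0 allowed, giving
#'   a degenerate sample).
#' @param on_score_mean,on_score_sd,off_score_mean,off_score_sd score
#'   distributions by state (truncated to \[0, 68\], rounded).
#' @param p_on probability a subject's score is recorded in the on state.
#' @param seed integer RNG seed.
#' @return object of class `cross_section_spec`.
#' @export
cross_section_spec <- function(n_subjects,
                               age_mean_years = 59, age_sd_years = 10,
                               on_score_mean = 15, on_score_sd = 8,
                               off_score_mean = 20, off_score_sd = 9,
                               p_on = 1612 / (1612 + 354),
                               seed = 1L) {
  spec <- list(
    n_subjects = check_count(n_subjects, "n_subjects", min = 2),
    age_mean_years = check_positive(age_mean_years, "age_mean_years"),
    age_sd_years = check_nonneg(age_sd_years, "age_sd_years"),
    on_score_mean = check_positive(on_score_mean, "on_score_mean"),
    on_score_sd = check_positive(on_score_sd, "on_score_sd"),
    off_score_mean = check_positive(off_score_mean, "off_score_mean"),
    off_score_sd = check_positive(off_score_sd, "off_score_sd"),
    p_on = p_on, seed = check_count(seed, "seed", min = 0))
  if (!is.numeric(p_on) || p_on < 0 || p_on > 1)
    stop_field("p_on", "must be a probability")
  structure(spec, class = "cross_section_spec")
}

#' Simulate a cross-sectional reference sample
#'
#' @param spec a [cross_section_spec()].
#' @return data frame with columns `subject_id`, `age_at_diagnosis`,
#'   `updrs_1_2` (integer in \[0, 68\]) and `state` (`on`/`off`).
#' @export
simulate_cross_section <- function(spec) {
  stopifnot(inherits(spec, "cross_section_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    ages <- rnorm(n, spec$age_mean_years, spec$age_sd_years)
    state <- ifelse(runif(n) < spec$p_on, "on", "off")
    mu <- ifelse(state == "on", spec$on_score_mean, spec$off_score_mean)
    sdv <- ifelse(state == "on", spec$on_score_sd, spec$off_score_sd)
    raw <- rnorm(n, mu, sdv)
    score <- as.integer(round_half_up(pmin(pmax(raw, 0), 68)))
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               age_at_diagnosis = ages, updrs_1_2 = score, state = state,
               stringsAsFactors = FALSE)
  })
}

#' Write a cross-section sample to CSV
#' @param sample data frame from [simulate_cross_section()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cross_section_csv <- function(sample, path) {
  out <- sample
  out$age_at_diagnosis <- sprintf("%.17g", out$age_at_diagnosis)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cross-section sample from CSV
#' @param path CSV path with columns
#'   `subject_id,age_at_diagnosis,updrs_1_2,state`.
#' @return data frame.
#' @export
read_cross_section_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age_at_diagnosis", "updrs_1_2", "state")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  if (!all(df$state %in% c("on", "off")))
    stop("state must be 'on' or 'off'", call. = FALSE)
  df
}

#' Write ground truth to a sidecar JSON file
#'
#' @param ground_truth a `cohort_ground_truth` from [simulate_cohort()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  stopifnot(inherits(ground_truth, "cohort_ground_truth"))
  jsonlite::write_json(unclass(ground_truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
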