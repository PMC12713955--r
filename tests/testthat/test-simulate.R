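test_that("the same seed regenerates byte-identical input files", {
  cfg <- cohort_config(n_subjects = 12, seed = 56)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  for (f in c("epochs.csv", "diary.csv", "melatonin.csv", "survey.csv",
              "truth.json")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("melatonin profiles cross the threshold at the planted time", {
  win <- plan_session_window("23:00")
  # b = 2, r = 4/h: the rise starts 30 min before the crossing
  prof <- generate_melatonin_profile(clock_to_noon("21:30"), win,
                                     baseline = 2, rise = 4, noise_sd = 0)
  expect_equal(oracle_dlmo_grid(prof$noon_min, prof$concentration_pg_ml),
               clock_to_noon("21:30"), tolerance = 1 / 60)
  e <- estimate_dlmo(prof$noon_min, prof$concentration_pg_ml)
  expect_equal(e$status, "ok")
  expect_lte(abs(e$dlmo - clock_to_noon("21:30")), 15)
  # crossing beyond the sampled window: a never-above case
  prof2 <- generate_melatonin_profile(win$end + 60, win, baseline = 2,
                                      rise = 4, noise_sd = 0)
  expect_equal(estimate_dlmo(prof2$noon_min, prof2$concentration_pg_ml)$status,
               "never_above_threshold")
  # supra-threshold baseline: a never-below case
  prof3 <- generate_melatonin_profile(clock_to_noon("21:30"), win,
                                      baseline = 4.5, rise = 4, noise_sd = 0)
  expect_equal(estimate_dlmo(prof3$noon_min, prof3$concentration_pg_ml)$status,
               "never_below_threshold")
})

test_that("activity traces have the configured wake level and sleep structure", {
  set.seed(17)
  tr <- generate_activity_trace(onset = 720, offset = 720 + 480,
                                in_bed = 714, out_of_bed = 720 + 490)
  wake <- tr$count[tr$noon_min < 714 - 0.001 | tr$noon_min >= 720 + 490]
  # 8 h worth of wake epochs for the mean check
  tr2 <- generate_activity_trace(onset = 1200, offset = 1260,
                                 in_bed = 1194, out_of_bed = 1270,
                                 window = c(240, 1300))
  wake2 <- tr2$count[tr2$noon_min < 1194]
  expect_gt(length(wake2), 900)
  expect_lt(abs(mean(wake2) - 180) / 180, 0.05)
  sleep <- tr$count[tr$noon_min >= 720 & tr$noon_min < 1200]
  expect_gt(mean(sleep == 0), 0.8)
  expect_lt(mean(sleep), 5)
  # an all-wake window yields no detectable sleep downstream
  lab <- sadeh_ps(wake2[1:400]) >= 0
  expect_error(detect_sleep_period(lab, 240, 640),
               class = "circsleep_no_sleep")
})

test_that("Sadeh scoring recovers the planted onset within the run-rule lag", {
  set.seed(23)
  for (i in 1:10) {
    onset <- 660 + round(runif(1, 0, 60))
    offset <- onset + 450
    in_bed <- onset - 6; out_ob <- offset + 10
    tr <- generate_activity_trace(onset, offset, in_bed, out_ob)
    ep <- tibble::tibble(subject = "S1",
                         timestamp = noon_to_timestamp(as.Date("2023-03-08"),
                                                       tr$noon_min),
                         count = tr$count)
    mn <- aggregate_to_minutes(as_epoch_series(ep))
    win <- mn$noon_min >= in_bed & mn$noon_min < out_ob
    per <- detect_sleep_period(sadeh_ps(mn$count[win]) >= 0, in_bed, out_ob,
                               times = mn$noon_min[win])
    expect_lte(abs(per$onset - onset), 10)
    expect_lte(abs(per$offset - offset), 15)
  }
})

test_that("planted outcome effects calibrate and null outcomes stay independent", {
  set.seed(31)
  n <- 500
  truth <- tibble::tibble(
    subject = sprintf("S%03d", 1:n),
    dlmo = rnorm(n, 570, 71), phase_angle = runif(n, 9, 232),
    sjl = abs(rnorm(n, 40, 79)), meq_total = round(rnorm(n, 47, 6.5)),
    female = rbinom(n, 1, 0.58), pds_total = rnorm(n, 12.7, 4.2),
    income_band = sample(1:5, n, TRUE)
  ) |> classify_groups()
  for (g in c("phase_group", "alignment_group", "sjl_group", "chronotype_group")) {
    truth[[paste0("in_analysis_", g)]] <- TRUE
  }
  cfg <- cohort_config(n_subjects = n)
  out <- generate_outcomes(truth, cfg)
  cal <- attr(out, "calibration")
  # only the planted effect has a nonzero beta
  expect_gt(cal$depression$beta, 0)
  expect_length(cal$anxiety$beta, 0)
  # independent noise: outcomes without planted shared effects stay uncorrelated
  expect_lt(abs(cor(out$dass_anxiety, out$erq_suppression)), 0.15)
  # marginal moments near Table-level targets at n = 500
  expect_lt(abs(mean(out$dass_depression) - 11.13), 3 * 5.88 / sqrt(n) + 0.3)
  expect_lt(abs(sd(out$dass_anxiety) - 7.76), 1)
  # a zero-target spec plants nothing
  cfg0 <- cohort_config(n_subjects = n,
                        effect_spec = data.frame(grouping = "phase_group",
                                                 outcome = "depression",
                                                 eta_p2 = 0))
  out0 <- generate_outcomes(truth, cfg0)
  expect_length(attr(out0, "calibration")$depression$beta, 1)
  expect_equal(attr(out0, "calibration")$depression$beta, 0)
  # infeasible targets are rejected
  expect_error(cohort_config(effect_spec = data.frame(
    grouping = "phase_group", outcome = "depression", eta_p2 = 1)),
    class = "circsleep_config_error")
})

test_that("cohort marginals track the configured study conditions", {
  fx <- fixture_cohort()
  tr <- fx$cohort$truth
  n <- nrow(tr)
  expect_equal(n, 52)
  # stochastic bounds: 3 SEs around the configured moments
  expect_lt(abs(mean(tr$dlmo) - clock_to_noon("21:30")), 3 * 71 / sqrt(n))
  expect_true(all(tr$phase_angle >= 9 & tr$phase_angle <= 232))
  expect_true(all(tr$sjl >= 0))
  expect_true(all(tr$meq_total >= 16 & tr$meq_total <= 86))
  expect_lt(abs(mean(tr$meq_total) - 47.15), 3 * 6.48 / sqrt(n))
  # negative MEQ-DLMO correlation as configured
  expect_lt(cor(tr$meq_total, tr$dlmo), -0.05)
  # missingness counts mirror the design: 9 actigraphy, 3 + 2 melatonin
  expect_equal(sum(tr$actigraphy_missing), 9)
  expect_equal(sum(tr$melatonin_case == "never_above"), 3)
  expect_equal(sum(tr$melatonin_case == "never_below"), 2)
})

test_that("with noise and missingness off the pipeline recovers truth exactly", {
  cfg <- cohort_config(
    n_subjects = 10, seed = 77, onset_noise_sd = 0, night_duration_sd = 0,
    melatonin_noise_sd = 0, actigraphy_missing = 0, dlmo_never_above = 0,
    dlmo_never_below = 0, income_declined = 0,
    income_probs = c(0.02, 0.18, 0.16, 0.32, 0.32))
  co <- generate_cohort(cfg)
  a <- suppressWarnings(analyze_cohort(co))
  pr <- a$profiles; tr <- co$truth
  expect_true(all(pr$dlmo_status == "ok"))
  expect_true(all(abs(pr$dlmo - tr$dlmo) <= 15))
  expect_true(all(abs(pr$phase_angle - tr$phase_angle) <= 15))
  expect_true(all(abs(pr$sjl - tr$sjl) <= 15))
})
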