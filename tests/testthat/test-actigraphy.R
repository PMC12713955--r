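write_epoch_csv <- function(times, counts, subject = "S1") {
  f <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(subject = subject,
                                  timestamp = format(times, "%Y-%m-%dT%H:%M:%S"),
                                  count = counts), f)
  f
}

t0 <- as.POSIXct("2023-03-08 22:00:00", tz = "UTC")

test_that("epoch CSVs read back with validation and zero-fill of short gaps", {
  f <- write_epoch_csv(t0 + c(0, 30, 60), c(0, 10, 0))
  ep <- read_epoch_series(f)
  expect_equal(nrow(ep), 3)
  expect_equal(ep$count, c(0, 10, 0))
  expect_equal(attr(ep, "epoch_seconds"), 30)

  # one missing epoch -> one zero inserted, with a warning
  f <- write_epoch_csv(t0 + c(0, 30, 90), c(5, 5, 5))
  expect_warning(ep <- read_epoch_series(f), "zero-filled")
  expect_equal(nrow(ep), 4)
  expect_equal(ep$count, c(5, 5, 0, 5))

  # 30 s, 90 s gap (two missing), 30 s -> two zeros inserted
  f <- write_epoch_csv(t0 + c(0, 30, 120, 150), c(5, 5, 5, 5))
  expect_warning(ep <- read_epoch_series(f), "zero-filled")
  expect_equal(nrow(ep), 6)
  expect_equal(ep$count, c(5, 5, 0, 0, 5, 5))

  # more than two missing epochs is unrecoverable
  f <- write_epoch_csv(t0 + c(0, 30, 180), c(5, 5, 5))
  expect_error(read_epoch_series(f), class = "circsleep_malformed_input")
  # off-grid spacing
  f <- write_epoch_csv(t0 + c(0, 30, 75), c(5, 5, 5))
  expect_error(read_epoch_series(f), class = "circsleep_malformed_input")
  # negative counts
  f <- write_epoch_csv(t0 + c(0, 30), c(5, -1))
  expect_error(read_epoch_series(f), class = "circsleep_malformed_input")
})

test_that("gaps of six hours or more separate recording blocks, not errors", {
  f <- write_epoch_csv(t0 + c(0, 30, 60, 24 * 3600 + c(0, 30, 60)),
                       rep(1, 6))
  ep <- read_epoch_series(f)
  expect_equal(nrow(ep), 6)
  expect_equal(unique(ep$block), c(0, 1))
})

test_that("30-s epochs aggregate to minutes by summation", {
  ep <- as_epoch_series(tibble::tibble(
    subject = "S1", timestamp = t0 + 30 * (0:5), count = c(3, 5, 0, 0, 10, 2)))
  mn <- aggregate_to_minutes(ep)
  expect_equal(mn$count, c(8, 0, 12))
  expect_equal(attr(mn, "epoch_seconds"), 60)

  # already at 60 s: unchanged
  ep60 <- as_epoch_series(tibble::tibble(
    subject = "S1", timestamp = t0 + 60 * (0:2), count = c(1, 2, 3)),
    epoch_seconds = 60)
  expect_identical(aggregate_to_minutes(ep60), ep60)

  # trailing partial minute dropped with a warning
  ep7 <- as_epoch_series(tibble::tibble(
    subject = "S1", timestamp = t0 + 30 * (0:6), count = rep(1, 7)))
  expect_warning(mn7 <- aggregate_to_minutes(ep7), "trailing")
  expect_equal(nrow(mn7), 3)
  expect_equal(mn7$count, rep(2, 3))

  ep120 <- as_epoch_series(tibble::tibble(
    subject = "S1", timestamp = t0 + 120 * (0:2), count = rep(1, 3)),
    epoch_seconds = 120)
  expect_error(aggregate_to_minutes(ep120),
               class = "circsleep_unsupported_resolution")
})

test_that("Sadeh scoring matches the discriminant at its fixed points", {
  # all-zero counts: only the intercept survives, every minute is sleep
  expect_true(all(sadeh_scores(rep(0, 60)) == "sleep"))
  expect_equal(sadeh_ps(rep(0, 60)), rep(7.601, 60))
  # constant 200: PS = 7.601 - 13 - 0.703 log(201) everywhere in the interior
  ps200 <- sadeh_ps(rep(200, 60))
  expect_equal(ps200[30], 7.601 - 0.065 * 200 - 0.703 * log(201),
               tolerance = 1e-12)
  expect_true(all(sadeh_scores(rep(200, 60)) == "wake"))
  # constant 64 sits in the [50, 100) band: NAT = 11 in the interior
  ps64 <- sadeh_ps(rep(64, 60))
  expect_equal(ps64[30], 7.601 - 0.065 * 64 - 1.08 * 11 - 0.703 * log(65),
               tolerance = 1e-12)
  expect_lt(ps64[30], 0)
  expect_error(sadeh_scores(numeric(0)), class = "circsleep_empty_input")
})

test_that("Sadeh scoring equals a brute-force per-window recomputation", {
  set.seed(42)
  for (rep in 1:5) {
    x <- round(rgamma(200, shape = 0.8, scale = 120))
    ps <- sadeh_ps(x)
    brute <- vapply(seq_along(x), function(i) oracle_sadeh_ps(x, i), numeric(1))
    expect_equal(ps, brute, tolerance = 1e-10)
  }
})

test_that("Sadeh scoring is translation invariant and saturates at high counts", {
  set.seed(7)
  x <- round(rgamma(120, shape = 1, scale = 100))
  lab <- sadeh_scores(x)
  for (k in c(3, 11)) {
    shifted <- sadeh_scores(c(rep(0, k), x))
    expect_equal(shifted[(k + 1):(k + length(x))], lab)
  }
  # every count at 300 or more scores wake
  y <- 300 + round(runif(120, 0, 500))
  expect_true(all(sadeh_scores(y) == "wake"))
})

test_that("count cap is available but off by default", {
  x <- rep(1000, 30)
  expect_true(all(sadeh_scores(x) == "wake"))
  expect_equal(sadeh_ps(x, cap = 300)[15],
               7.601 - 0.065 * 300 - 0.703 * log(301), tolerance = 1e-12)
})

test_that("sleep period detection applies the consecutive-run rule", {
  ib <- clock_to_noon("23:00"); ob <- clock_to_noon("07:00")
  # degenerate all-sleep window
  p <- detect_sleep_period(rep(TRUE, 480), ib, ob)
  expect_equal(p$onset, ib)
  expect_equal(p$offset, ob)
  # five wake minutes then sleep to the end
  p <- detect_sleep_period(c(rep(FALSE, 5), rep(TRUE, 475)), ib, ob)
  expect_equal(p$onset, ib + 5)
  expect_equal(p$offset, ob)
  # a sub-threshold 8-min run does not start the night; the 400-min run does
  labs <- c(rep(TRUE, 8), rep(FALSE, 4), rep(TRUE, 400))
  p <- detect_sleep_period(labs, ib, ib + length(labs))
  expect_equal(p$onset, ib + 12)
  expect_equal(p$offset, ib + 412)
  # no qualifying run
  expect_error(
    detect_sleep_period(rep(c(TRUE, FALSE), 100), ib, ob),
    class = "circsleep_no_sleep")
})

test_that("turning a wake minute into sleep never delays detected onset", {
  set.seed(11)
  for (rep in 1:20) {
    labs <- runif(120) < 0.7
    base <- tryCatch(detect_sleep_period(labs, 0, 120)$onset,
                     circsleep_no_sleep = function(e) NA)
    i <- sample(which(!labs), 1)
    labs2 <- labs; labs2[i] <- TRUE
    new <- tryCatch(detect_sleep_period(labs2, 0, 120)$onset,
                    circsleep_no_sleep = function(e) NA)
    if (!is.na(base)) {
      expect_false(is.na(new))
      expect_lte(new, base)
    }
  }
})

test_that("bed times are inferred from the activity envelope", {
  # plateau at 500/min, linear decline 22:40-23:00, near-zero to 07:00,
  # high plateau after
  tmin <- clock_to_noon("21:00") + 0:(14 * 60 - 1)   # 21:00 -> 11:00
  counts <- numeric(length(tmin))
  counts[tmin < clock_to_noon("22:40")] <- 500
  dec <- tmin >= clock_to_noon("22:40") & tmin < clock_to_noon("23:00")
  counts[dec] <- round(seq(500, 0, length.out = sum(dec) + 1))[-1]
  counts[tmin >= clock_to_noon("07:00")] <- 500
  bt <- infer_bed_times(tibble::tibble(noon_min = tmin, count = counts))
  expect_equal(bt$in_bed, clock_to_noon("22:40"))
  expect_equal(bt$out_of_bed, clock_to_noon("07:00"))

  # an all-zero trace has no activity trend to anchor on
  expect_error(
    infer_bed_times(tibble::tibble(noon_min = tmin,
                                   count = numeric(length(tmin)))),
    class = "circsleep_cannot_infer")
  # no sustained low block
  expect_error(
    infer_bed_times(tibble::tibble(noon_min = tmin,
                                   count = rep(500, length(tmin)))),
    class = "circsleep_cannot_infer")
})

test_that("nightly summaries compute duration and midsleep on the noon axis", {
  s <- summarize_night(clock_to_noon("23:00"), clock_to_noon("07:00"),
                       as.Date("2023-03-08"))
  expect_equal(s$duration_min, 480)
  expect_equal(s$midsleep_clock, "03:00")
  expect_equal(s$night_class, "school")
  # midpoint crossing midnight
  s <- summarize_night(clock_to_noon("00:30"), clock_to_noon("06:30"),
                       as.Date("2023-03-10"))
  expect_equal(s$midsleep_clock, "03:30")
  expect_equal(s$night_class, "free")
  # a typical adolescent 7.4-h night
  s <- summarize_night(clock_to_noon("22:00"), clock_to_noon("22:00") + 444,
                       as.Date("2023-03-08"))
  expect_equal(s$duration_min, 444)
  # exact midpoint identity
  expect_equal(s$midsleep - s$onset, s$offset - s$midsleep)
})

test_that("consistent diaries pass through; nightly statuses account for all nights", {
  fx <- fixture_cohort()
  nightly <- fx$analysis$nightly
  # every diary night appears exactly once with an explicit status
  expect_equal(nrow(nightly), nrow(fx$cohort$diary))
  expect_true(all(nightly$status %in%
                    c("ok", "excluded_low_coverage", "excluded_cannot_infer",
                      "excluded_no_sleep")))
  # subjects with no recordings have every night excluded
  missing_subj <- fx$cohort$truth$subject[fx$cohort$truth$actigraphy_missing]
  expect_true(all(nightly$status[nightly$subject %in% missing_subj] ==
                    "excluded_low_coverage"))
  # scored nights respect the diary window (diary precedence, not inference)
  ok <- nightly[nightly$status == "ok", ]
  di <- fx$cohort$diary
  key <- paste(di$subject, di$night_date)
  ib <- clock_to_noon(di$in_bed)[match(paste(ok$subject, ok$night_date), key)]
  expect_gte(mean(ok$in_bed == ib, na.rm = TRUE), 0.95)
  expect_true(all(ok$onset >= ok$in_bed & ok$offset <= ok$out_of_bed))
})
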