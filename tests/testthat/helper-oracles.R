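# Independent oracles used across the suite. Each recomputes the target
# quantity by a different route than the package implementation.

# Sadeh probability-of-sleep for one minute, recomputed window by window
# straight from the formula definition.
oracle_sadeh_ps <- function(x, i) {
  z <- c(rep(0, 5), x, rep(0, 5))
  j <- i + 5
  win <- z[(j - 5):(j + 5)]
  mw5 <- mean(win)
  nat <- sum(win >= 50 & win < 100)
  seg <- z[(j - 5):j]
  sd6 <- sqrt(mean((seg - mean(seg))^2))
  7.601 - 0.065 * mw5 - 1.08 * nat - 0.056 * sd6 - 0.703 * log(x[i] + 1)
}

# First time the piecewise-linear interpolant reaches the threshold, found by
# dense 1-second grid search.
oracle_dlmo_grid <- function(times, conc, threshold = 4) {
  tt <- seq(min(times), max(times), by = 1 / 60)
  cc <- stats::approx(times, conc, xout = tt)$y
  i <- which(cc >= threshold)[1]
  if (is.na(i)) NA_real_ else tt[i]
}

# Partial F of the column-2 effect by explicit normal equations.
oracle_partial_F <- function(y, X) {
  b1 <- solve(t(X) %*% X, t(X) %*% y)
  rss1 <- sum((y - X %*% b1)^2)
  X0 <- X[, -2, drop = FALSE]
  b0 <- solve(t(X0) %*% X0, t(X0) %*% y)
  rss0 <- sum((y - X0 %*% b0)^2)
  df2 <- nrow(X) - ncol(X)
  list(F = (rss0 - rss1) / (rss1 / df2), df2 = df2)
}

# Classical one-way ANOVA F from group means/SDs/sizes (textbook sums of
# squares).
oracle_anova_F <- function(means, sds, ns) {
  k <- length(means)
  N <- sum(ns)
  gm <- sum(ns * means) / N
  msb <- sum(ns * (means - gm)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (N - k)
  msb / msw
}

# Small in-memory melatonin series builder.
mel_series <- function(times_clock, conc, subject = "S1") {
  tibble::tibble(subject = subject, sample_time = times_clock,
                 concentration_pg_ml = conc,
                 noon_min = clock_to_noon(times_clock))
}

# One small cached cohort shared by the heavier integration tests.
fixture_env <- new.env()
fixture_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    fixture_env$cohort <- generate_cohort(cohort_config(seed = 101))
    fixture_env$analysis <- suppressWarnings(analyze_cohort(fixture_env$cohort))
  }
  list(cohort = fixture_env$cohort, analysis = fixture_env$analysis)
}
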