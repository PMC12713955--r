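#' Configuration for a synthetic adolescent cohort
#'
#' Defaults reproduce the study conditions of a 52-subject, 10-night
#' adolescent monitoring design: DLMO 21:30 +/- 1:11, phase angle of
#' entrainment 1:45 +/- 1:14 truncated to its observed 0:09-3:52 range,
#' social jetlag 0:40 +/- 1:19 truncated at zero, MEQ 47.15 +/- 6.48
#' (correlated -0.4 with DLMO), sleep duration 7.4 +/- 0.8 h, DASS-21 and ERQ
#' outcome moments as observed, subject-level missingness of 9/52 for
#' actigraphy and 5/52 for melatonin (3 never-above, 2 never-below), and a
#' single planted group effect: partial eta squared of 0.13 for circadian
#' phase on depression.
#'
#' @param n_subjects Cohort size.
#' @param seed RNG seed; the seed fully determines every emitted file.
#' @param start_date First monitoring night (a Wednesday by default, matching
#'   midweek baseline appointments; nights 8-10 then end on a free-morning
#'   Friday night, which stays out of social-jetlag contrast by the
#'   stabilization rule).
#' @param dlmo_mean,dlmo_sd DLMO crossing-time distribution (clock string /
#'   minutes).
#' @param phase_angle_mean,phase_angle_sd,phase_angle_range Phase angle
#'   distribution in minutes, truncated to the range; the latent location is
#'   re-solved so the *truncated* mean equals `phase_angle_mean`.
#' @param sjl_mean,sjl_sd,sjl_max Social jetlag (free-night delay) marginal
#'   distribution in minutes. The delay is gamma-distributed — the observed
#'   SJL distribution is non-negative and strongly right-skewed (SD about
#'   twice the mean), which no zero-truncated normal can reproduce — and
#'   capped at `sjl_max` (default the observed 3:34 maximum) to keep night
#'   windows physical; the gamma mean parameter is re-solved so the capped
#'   mean equals `sjl_mean`.
#' @param meq_mean,meq_sd,meq_dlmo_cor MEQ total distribution and its
#'   correlation with DLMO.
#' @param sleep_duration_mean,sleep_duration_sd Between-subject mean nightly
#'   sleep duration (minutes).
#' @param night_duration_sd,onset_noise_sd Within-subject night-to-night
#'   jitter of duration and onset (minutes).
#' @param outcome_means,outcome_sds Named marginal moments for the five
#'   outcomes.
#' @param effect_spec Data frame `grouping`, `outcome`, `eta_p2`: planted
#'   covariate-adjusted group effects (targets in `[0, 1)`).
#' @param gamma_sex,gamma_pds Generative covariate coefficients shared by all
#'   outcomes.
#' @param melatonin_noise_sd Log-scale SD of multiplicative lognormal assay
#'   noise.
#' @param n_melatonin_samples Samples emitted per session (12 by protocol; 13
#'   covers the inclusive grid).
#' @param baseline_range,rise_range Melatonin baseline (pg/mL) and post-onset
#'   linear rise (pg/mL/h) uniform ranges.
#' @param wake_shape,wake_mean,sleep_zero_prob,sleep_shape,sleep_mean
#'   Per-epoch activity count model: wake counts Gamma(`wake_shape`) with mean
#'   `wake_mean`; sleep epochs zero with probability `sleep_zero_prob`, else
#'   Gamma(`sleep_shape`) with mean `sleep_mean`.
#' @param epoch_seconds Actigraph epoch length (30 s).
#' @param actigraphy_missing,dlmo_never_above,dlmo_never_below Subject-level
#'   missingness rates (fractions of the cohort; realized counts are rounded
#'   and the affected subjects sampled disjointly).
#' @param female_prob,pds_mean,pds_sd,income_probs,income_declined Covariate
#'   generators; `income_probs` are the five reported-band probabilities,
#'   `income_declined` the declined-to-report rate (missing income).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_subjects = 52, seed = 1, start_date = as.Date("2023-03-08"),
    dlmo_mean = "21:30", dlmo_sd = 71,
    phase_angle_mean = 105, phase_angle_sd = 74, phase_angle_range = c(9, 232),
    sjl_mean = 40, sjl_sd = 79, sjl_max = 214,
    meq_mean = 47.15, meq_sd = 6.48, meq_dlmo_cor = -0.4,
    sleep_duration_mean = 444, sleep_duration_sd = 48,
    night_duration_sd = 20, onset_noise_sd = 15,
    outcome_means = c(depression = 11.13, anxiety = 9.86, stress = 13.70,
                      cognitive_reappraisal = 18.90, expressive_suppression = 15.67),
    outcome_sds = c(depression = 5.88, anxiety = 7.76, stress = 5.80,
                    cognitive_reappraisal = 5.02, expressive_suppression = 3.71),
    effect_spec = data.frame(grouping = "phase_group", outcome = "depression",
                             eta_p2 = 0.13),
    gamma_sex = 2, gamma_pds = 0.15,
    melatonin_noise_sd = 0.15, n_melatonin_samples = 12,
    baseline_range = c(0.5, 2.5), rise_range = c(3, 8),
    wake_shape = 2, wake_mean = 180, sleep_zero_prob = 0.9,
    sleep_shape = 1, sleep_mean = 20,
    epoch_seconds = 30,
    actigraphy_missing = 9 / 52, dlmo_never_above = 3 / 52,
    dlmo_never_below = 2 / 52,
    female_prob = 0.58, pds_mean = 12.69, pds_sd = 4.18,
    income_probs = c(0.016, 0.164, 0.148, 0.279, 0.246),
    income_declined = 0.148) {
  cfg <- as.list(environment())
  if (any(cfg$effect_spec$eta_p2 < 0) || any(cfg$effect_spec$eta_p2 >= 1)) {
    abort("target partial eta squared must be in [0, 1)",
          class = "circsleep_config_error")
  }
  stopifnot(dlmo_sd > 0, phase_angle_sd > 0, sjl_sd > 0, meq_sd > 0,
            all(outcome_sds > 0))
  class(cfg) <- "cohort_config"
  cfg
}

# Expected value of the estimated partial eta squared for a 1-df effect with
# noncentrality lambda and error df m: eta-hat ~ noncentral Beta(1/2, m/2,
# lambda), whose mean is a Poisson(lambda/2) mixture of central Beta means.
expected_eta_p2 <- function(lambda, m) {
  jmax <- ceiling(lambda / 2 + 10 * sqrt(lambda / 2 + 1) + 50)
  j <- 0:jmax
  sum(stats::dpois(j, lambda / 2) * (0.5 + j) / (0.5 + j + m / 2))
}

# Solve the noncentrality whose expected estimated eta_p2 equals the target;
# targets at or below the null-mean 1/(1+m) give lambda = 0.
solve_lambda <- function(target, m) {
  if (target <= expected_eta_p2(0, m)) return(0)
  stats::uniroot(function(l) expected_eta_p2(l, m) - target,
                 lower = 0, upper = 1000, tol = 1e-8)$root
}

# inverse-CDF truncated-normal draws: one uniform per draw keeps the RNG
# stream length independent of the truncation bounds
rtruncnorm_inv <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd; b <- (upper - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# location parameter whose truncated-normal mean equals the target, so the
# emitted marginal mean matches the configured one despite truncation
solve_truncnorm_mu <- function(target, sd, lower, upper) {
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, lower, upper) - target,
                 lower = lower - 5 * sd, upper = upper + 5 * sd,
                 tol = 1e-8)$root
}

# gamma draws by inverse CDF with the requested mean/SD; used for the
# free-night delay, whose configured moments (mean well below SD, support
# >= 0) no truncated normal can reproduce
rgamma_inv <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::qgamma(runif(n), shape = shape, scale = sd^2 / mean)
}

# mean of a gamma(mean m, sd s) draw capped (not truncated) at cmax
capped_gamma_mean <- function(m, s, cmax) {
  sh <- (m / s)^2; sc <- s^2 / m
  m * stats::pgamma(cmax, sh + 1, scale = sc) +
    cmax * stats::pgamma(cmax, sh, scale = sc, lower.tail = FALSE)
}

# gamma mean parameter whose capped mean equals the target
solve_capped_gamma_mean <- function(target, s, cmax) {
  stats::uniroot(function(m) capped_gamma_mean(m, s, cmax) - target,
                 lower = target, upper = min(4 * target, cmax),
                 tol = 1e-8)$root
}

#' Simulate one night's epoch-level activity trace
#'
#' Wake epochs draw Gamma-distributed counts (mean `wake_mean`); sleep epochs
#' are zero with probability `sleep_zero_prob`, otherwise small Gamma counts.
#' Between in-bed time and sleep onset, and between sleep offset and
#' out-of-bed time, wake-level counts are tapered to/from zero by a quartic
#' ramp (winding down in bed and waking up), steep enough that the 30-min
#' post-in-bed mean stays below the wake threshold and the diary and trace
#' agree.
#'
#' @param onset,offset True sleep onset/offset, noon-axis minutes.
#' @param in_bed,out_of_bed Diary bed times bracketing them.
#' @param window Noon-axis interval covered by the recording (default
#'   30 min around the bed window).
#' @param epoch_seconds Epoch length (30 s).
#' @inheritParams cohort_config
#' @return Tibble `noon_min` (epoch start), `count`.
#' @export
generate_activity_trace <- function(onset, offset, in_bed = onset - 6,
                                    out_of_bed = offset + 10,
                                    window = c(in_bed - 30, out_of_bed + 30),
                                    epoch_seconds = 30,
                                    wake_shape = 2, wake_mean = 180,
                                    sleep_zero_prob = 0.9, sleep_shape = 1,
                                    sleep_mean = 20) {
  stopifnot(in_bed <= onset, onset < offset, offset <= out_of_bed)
  step <- epoch_seconds / 60
  t <- seq(window[1], window[2] - step, by = step)
  n <- length(t)
  f <- numeric(n)                       # wake-intensity multiplier
  f[t < in_bed | t >= out_of_bed] <- 1
  ti <- t >= in_bed & t < onset
  if (onset > in_bed) f[ti] <- ((onset - t[ti]) / (onset - in_bed))^4
  to <- t >= offset & t < out_of_bed
  if (out_of_bed > offset) f[to] <- ((t[to] - offset) / (out_of_bed - offset))^4
  asleep <- t >= onset & t < offset

  counts <- numeric(n)
  nw <- sum(!asleep)
  counts[!asleep] <- round(rgamma(nw, shape = wake_shape,
                                  scale = wake_mean / wake_shape) * f[!asleep])
  ns <- sum(asleep)
  z <- runif(ns) < sleep_zero_prob
  sc <- numeric(ns)
  sc[!z] <- round(rgamma(sum(!z), shape = sleep_shape,
                         scale = sleep_mean / sleep_shape))
  counts[asleep] <- sc
  tibble(noon_min = t, count = counts)
}

#' Simulate a salivary melatonin sampling session
#'
#' Concentration is a flat baseline `b` before melatonin onset and rises
#' linearly at `r` pg/mL/h after it, with multiplicative lognormal assay
#' noise. The onset is placed so that the noise-free profile crosses
#' `threshold` exactly at `dlmo_crossing`, making the true DLMO closed-form:
#' rise start = crossing − 60 (threshold − b) / r.
#'
#' @param dlmo_crossing True threshold-crossing time, noon-axis minutes. A
#'   crossing beyond the sampled grid yields a profile that never reaches
#'   threshold (a valid `never_above_threshold` case); a baseline at or above
#'   threshold yields `never_below_threshold`.
#' @param session_window List from [plan_session_window()].
#' @param baseline,rise Baseline (pg/mL) and rise slope (pg/mL/h).
#' @param noise_sd Log-scale SD of the lognormal noise (0 = noise-free).
#' @param n_samples Number of 30-min samples from session start (12 or 13).
#' @param threshold Threshold (pg/mL).
#' @return Tibble `noon_min`, `concentration_pg_ml`.
#' @export
generate_melatonin_profile <- function(dlmo_crossing, session_window,
                                       baseline = 1.5, rise = 5,
                                       noise_sd = 0, n_samples = 12,
                                       threshold = 4) {
  t <- session_window$start + 30 * (seq_len(n_samples) - 1)
  rise_start <- dlmo_crossing - 60 * (threshold - baseline) / rise
  conc <- baseline + (rise / 60) * pmax(0, t - rise_start)
  if (noise_sd > 0) conc <- conc * exp(rnorm(length(t), 0, noise_sd))
  tibble(noon_min = t, concentration_pg_ml = conc)
}

#' Simulate survey outcomes with planted group effects
#'
#' Each outcome is `mu + beta * risk + gamma_sex * female + gamma_pds * PDS +
#' noise` (all regressors centred, so marginal means match `mu`). For each
#' planted effect, `beta` is calibrated so the *estimated* partial eta
#' squared is unbiased for the target: the estimator for a 1-df effect is
#' noncentral-Beta(1/2, m/2, lambda) distributed (m the error df), so the
#' noncentrality `lambda` solving `E[eta-hat] = target` is found from the
#' Poisson-mixture series for the noncentral Beta mean, and
#' `beta = sigma * sqrt(lambda * n / (n1 n2))` with `n1`, `n2` the realized
#' analysis-subset group sizes. The residual SD `sigma` is then set so each
#' outcome's marginal variance matches its configured SD.
#'
#' @param truth Tibble with the true group-label columns named in
#'   `effect_spec$grouping`, plus logical `in_analysis` columns per grouping
#'   (see [generate_cohort()]); plus `female` (0/1) and `pds_total`.
#' @param config A [cohort_config()].
#' @return Tibble of the five outcome columns (integer, floored at 0), with
#'   attribute `calibration` recording beta and sigma per outcome.
#' @export
generate_outcomes <- function(truth, config) {
  n <- nrow(truth)
  fem_c <- truth$female - mean(truth$female)
  pds_c <- truth$pds_total - mean(truth$pds_total)
  cov_var <- config$gamma_sex^2 * config$female_prob * (1 - config$female_prob) +
    config$gamma_pds^2 * config$pds_sd^2
  es <- config$effect_spec
  calib <- list()
  out <- list()
  for (oc in names(config$outcome_means)) {
    mu <- config$outcome_means[[oc]]
    v <- config$outcome_sds[[oc]]^2
    rows <- es[es$outcome == oc, , drop = FALSE]
    ks <- 0; pqs <- 0
    betas <- numeric(0)
    risks <- list()
    if (nrow(rows)) {
      for (j in seq_len(nrow(rows))) {
        g <- rows$grouping[j]
        target <- rows$eta_p2[j]
        risk <- as.numeric(truth[[g]] == levels(truth[[g]])[2])
        mask <- truth[[paste0("in_analysis_", g)]]
        n1 <- sum(risk[mask] == 1); n2 <- sum(risk[mask] == 0)
        if (n1 < 2 || n2 < 2) {
          abort(paste0("degenerate group sizes for planted effect ", g, " x ", oc),
                class = "circsleep_config_error")
        }
        m <- (n1 + n2) - 5          # intercept + group + 3 covariates
        lambda <- if (target == 0) 0 else solve_lambda(target, m)
        # effective information about the group effect is the sum of squares
        # of the group indicator residualized on the realized covariates
        Xc <- cbind(1, truth$female[mask], truth$pds_total[mask],
                    truth$income_band[mask])
        n_eff <- sum(lm.fit(Xc, risk[mask])$residuals^2)
        k <- lambda / n_eff
        ks <- ks + k
        pq <- mean(risk) * (1 - mean(risk))
        pqs <- pqs + k * pq
        betas <- c(betas, sqrt(k))   # beta = sigma * sqrt(k); scaled below
        risks[[length(risks) + 1]] <- risk - mean(risk)
      }
    }
    sigma2 <- (v - cov_var) / (1 + pqs)
    if (sigma2 <= 0) {
      abort(paste0("outcome '", oc, "': covariate + effect variance exceeds ",
                   "the configured marginal variance"),
            class = "circsleep_config_error")
    }
    sigma <- sqrt(sigma2)
    y <- mu + config$gamma_sex * fem_c + config$gamma_pds * pds_c +
      rnorm(n, 0, sigma)
    if (length(betas)) {
      for (j in seq_along(betas)) y <- y + sigma * betas[j] * risks[[j]]
    }
    out[[oc]] <- pmax(round(y), 0)
    calib[[oc]] <- list(beta = sigma * betas, sigma = sigma)
  }
  res <- as_tibble(out)
  names(res) <- c("dass_depression", "dass_anxiety", "dass_stress",
                  "erq_reappraisal", "erq_suppression")[
                    match(names(res), c("depression", "anxiety", "stress",
                                        "cognitive_reappraisal",
                                        "expressive_suppression"))]
  attr(res, "calibration") <- calib
  res
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' Draws per-subject latent circadian truths (DLMO crossing time, phase angle,
#' free-night delay, nightly durations, MEQ), builds 10 nights of diary and
#' epoch-level activity per subject, one melatonin session per subject, and a
#' survey table with planted outcome effects. School/free-night structure
#' follows the calendar from `start_date`; nights 8-10 are the fixed-bedtime
#' stabilization nights. Per-night sleep onsets are arranged so each
#' subject's 10-night mean onset equals DLMO + phase angle and the
#' school/free onset contrast equals the drawn social jetlag exactly (before
#' night-level jitter).
#'
#' @param config A [cohort_config()].
#' @return List of class `circ_cohort`: tibbles `epochs`, `diary`,
#'   `melatonin`, `survey`, `truth`, and the `config`. Pass to
#'   [analyze_cohort()] or [write_cohort()].
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_subjects
  subject <- sprintf("S%03d", seq_len(n))

  dlmo <- rnorm(n, clock_to_noon(config$dlmo_mean), config$dlmo_sd)
  alpha_mu <- solve_truncnorm_mu(config$phase_angle_mean,
                                 config$phase_angle_sd,
                                 config$phase_angle_range[1],
                                 config$phase_angle_range[2])
  alpha <- rtruncnorm_inv(n, alpha_mu, config$phase_angle_sd,
                          config$phase_angle_range[1], config$phase_angle_range[2])
  sjl_m <- solve_capped_gamma_mean(config$sjl_mean, config$sjl_sd,
                                   config$sjl_max)
  delta <- pmin(rgamma_inv(n, sjl_m, config$sjl_sd), config$sjl_max)
  dur_mean <- rnorm(n, config$sleep_duration_mean, config$sleep_duration_sd)
  z2 <- rnorm(n)
  zd <- (dlmo - clock_to_noon(config$dlmo_mean)) / config$dlmo_sd
  rho <- config$meq_dlmo_cor
  meq <- round(config$meq_mean +
                 config$meq_sd * (rho * zd + sqrt(1 - rho^2) * z2))
  meq <- pmin(pmax(meq, 16), 86)

  # subject-level missingness, sampled disjointly
  n_act <- round(config$actigraphy_missing * n)
  n_na <- round(config$dlmo_never_above * n)
  n_nb <- round(config$dlmo_never_below * n)
  perm <- sample(n)
  act_missing <- seq_len(n) %in% perm[seq_len(n_act)]
  never_above <- seq_len(n) %in% perm[n_act + seq_len(n_na)]
  never_below <- seq_len(n) %in% perm[n_act + n_na + seq_len(n_nb)]
  melatonin_case <- ifelse(never_above, "never_above",
                           ifelse(never_below, "never_below", "ok"))

  typical_bedtime <- round(dlmo + alpha)
  nights <- config$start_date + 0:9
  nclass <- night_class_of(nights)
  nat <- 1:7
  f_nat <- sum(nclass[nat] == "free") / length(nat)

  # covariates
  female <- rbinom(n, 1, config$female_prob)
  pds <- round(rnorm(n, config$pds_mean, config$pds_sd), 1)
  ip <- config$income_probs / sum(c(config$income_probs, config$income_declined))
  idp <- config$income_declined / sum(c(config$income_probs, config$income_declined))
  income <- sample(c(1:5, NA), n, replace = TRUE, prob = c(ip, idp))

  truth <- tibble(
    subject = subject, dlmo = dlmo, phase_angle = alpha, sjl = delta,
    typical_bedtime = typical_bedtime, sleep_duration_mean = dur_mean,
    meq_total = meq, female = female, pds_total = pds, income_band = income,
    actigraphy_missing = act_missing, melatonin_case = melatonin_case
  ) |> classify_groups()
  truth$dlmo_measurable <- melatonin_case == "ok"
  for (g in c("phase_group", "alignment_group", "sjl_group", "chronotype_group")) {
    needs_dlmo <- g %in% c("phase_group", "alignment_group")
    needs_act <- g %in% c("alignment_group", "sjl_group")
    truth[[paste0("in_analysis_", g)]] <-
      (!needs_dlmo | truth$dlmo_measurable) &
      (!needs_act | !truth$actigraphy_missing) &
      !is.na(truth$income_band)
  }

  # nightly structure: school onset shifted so the 10-night mean equals
  # dlmo + alpha and the school/free contrast equals delta
  diary_rows <- vector("list", n)
  epoch_rows <- vector("list", n)
  onset_true <- matrix(NA_real_, n, 10)
  offset_true <- matrix(NA_real_, n, 10)
  for (i in seq_len(n)) {
    s_i <- typical_bedtime[i] - f_nat * delta[i]
    base_onset <- ifelse(seq_len(10) %in% nat,
                         ifelse(nclass == "free", s_i + delta[i], s_i),
                         typical_bedtime[i])
    on <- round(base_onset + rnorm(10, 0, config$onset_noise_sd))
    dur <- round(dur_mean[i] + rnorm(10, 0, config$night_duration_sd))
    off <- on + pmax(dur, 120)
    onset_true[i, ] <- on
    offset_true[i, ] <- off
    g_in <- round(runif(10, 4, 7))
    g_out <- round(runif(10, 5, 15))
    in_bed <- on - g_in
    out_ob <- off + g_out
    diary_rows[[i]] <- tibble(
      subject = subject[i], night_date = nights,
      in_bed = noon_to_clock(in_bed), out_of_bed = noon_to_clock(out_ob)
    )
    if (!act_missing[i]) {
      tr <- lapply(seq_len(10), function(k) {
        d <- generate_activity_trace(
          on[k], off[k], in_bed[k], out_ob[k],
          epoch_seconds = config$epoch_seconds,
          wake_shape = config$wake_shape, wake_mean = config$wake_mean,
          sleep_zero_prob = config$sleep_zero_prob,
          sleep_shape = config$sleep_shape, sleep_mean = config$sleep_mean)
        d$night_date <- nights[k]
        d
      })
      tr <- bind_rows(tr)
      tr$subject <- subject[i]
      epoch_rows[[i]] <- tr
    }
  }
  diary <- bind_rows(diary_rows)
  epochs <- bind_rows(epoch_rows)
  if (nrow(epochs)) {
    epochs$timestamp <- noon_to_timestamp(epochs$night_date, epochs$noon_min)
    epochs$block <- as.integer(factor(paste(epochs$subject, epochs$night_date)))
    epochs <- epochs[, c("subject", "timestamp", "count", "night_date",
                         "noon_min", "block")]
    attr(epochs, "epoch_seconds") <- config$epoch_seconds
  }

  # melatonin sessions
  b <- runif(n, config$baseline_range[1], config$baseline_range[2])
  b[never_below] <- runif(sum(never_below), 4.5, 6)
  r <- runif(n, config$rise_range[1], config$rise_range[2])
  mel <- lapply(seq_len(n), function(i) {
    win <- plan_session_window(typical_bedtime[i])
    crossing <- if (never_above[i]) win$end + 60 else dlmo[i]
    d <- generate_melatonin_profile(
      crossing, win, baseline = b[i], rise = r[i],
      noise_sd = config$melatonin_noise_sd,
      n_samples = config$n_melatonin_samples)
    d$subject <- subject[i]
    d
  }) |> bind_rows()
  melatonin <- tibble(
    subject = mel$subject,
    sample_time = noon_to_clock(mel$noon_min),
    concentration_pg_ml = round(mel$concentration_pg_ml, 4),
    noon_min = mel$noon_min
  )

  outcomes <- generate_outcomes(truth, config)
  survey <- tibble(
    subject = subject,
    sex = ifelse(female == 1, "female", "male"),
    pds_total = pds, income_band = income, meq_total = meq
  ) |> bind_cols(outcomes)

  truth$baseline <- b
  truth$rise <- r
  truth$onset_true <- onset_true
  truth$offset_true <- offset_true

  structure(
    list(epochs = epochs, diary = diary, melatonin = melatonin,
         survey = survey, truth = truth, config = config,
         outcome_calibration = attr(outcomes, "calibration")),
    class = "circ_cohort"
  )
}

#' Write a synthetic cohort to plain-text input files
#'
#' Emits `epochs.csv`, `diary.csv`, `melatonin.csv`, `survey.csv` and
#' `truth.json` under `dir`. The same configuration (including seed) always
#' produces byte-identical files.
#'
#' @param cohort A `circ_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- cohort$epochs
  readr::write_csv(
    tibble(subject = ep$subject,
           timestamp = format(ep$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
           count = ep$count),
    file.path(dir, "epochs.csv"))
  readr::write_csv(cohort$diary, file.path(dir, "diary.csv"))
  readr::write_csv(cohort$melatonin[c("subject", "sample_time",
                                      "concentration_pg_ml")],
                   file.path(dir, "melatonin.csv"))
  readr::write_csv(cohort$survey, file.path(dir, "survey.csv"))
  truth <- cohort$truth
  truth$onset_true <- NULL
  truth$offset_true <- NULL
  jsonlite::write_json(
    list(generator = "circsleep synthetic cohort",
         note = paste("Melatonin curve shape and activity-count distributions",
                      "are declared generator conventions, not estimates from",
                      "any empirical recording."),
         seed = cohort$config$seed,
         subjects = truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full analysis chain on an in-memory cohort
#'
#' Convenience driver: Sadeh-scores the nights, estimates DLMO per subject,
#' builds profiles, and runs the 4 x 5 comparison grid.
#'
#' @param cohort A `circ_cohort` (or a list with `epochs`, `diary`,
#'   `melatonin`, `survey` tibbles).
#' @param covariates Covariate set for [run_all_comparisons()].
#' @param ... Passed to [score_nights()].
#' @return List: `nightly`, `dlmo`, `profiles`, `comparisons`, `ns`.
#' @export
analyze_cohort <- function(cohort,
                           covariates = c("sex", "pds_total", "income_band"),
                           ...) {
  mel <- cohort$melatonin
  if (!"noon_min" %in% names(mel)) mel$noon_min <- clock_to_noon(mel$sample_time)
  nightly <- score_nights(cohort$epochs, cohort$diary, ...)
  dlmo <- estimate_dlmo_all(mel)
  profiles <- build_profiles(nightly, dlmo, cohort$survey)
  comparisons <- run_all_comparisons(profiles, covariates = covariates)
  list(nightly = nightly, dlmo = dlmo, profiles = profiles,
       comparisons = comparisons, ns = analysis_ns(profiles))
}
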