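#' Mean sleep onset across nights
#'
#' Arithmetic mean of nightly sleep onsets on the noon axis (so onsets either
#' side of midnight average correctly), rounded to the minute. Only nights
#' with `status == "ok"` contribute when a `status` column is present.
#'
#' @param nightly Nightly summary tibble ([score_nights()]) for one subject,
#'   or any tibble with an `onset` column in noon-axis minutes.
#' @return Noon-axis minutes, or `NA` when no valid night exists.
#' @export
mean_sleep_onset <- function(nightly) {
  on <- nightly$onset
  if ("status" %in% names(nightly)) on <- on[nightly$status == "ok"]
  on <- on[!is.na(on)]
  if (!length(on)) return(NA_real_)
  round(mean(on))
}

#' Social jetlag from nightly sleep onsets
#'
#' The absolute difference, in minutes, between mean sleep onset on free
#' nights and on school nights. Nights flagged as part of the fixed-bedtime
#' stabilization period are excluded by default, since schedule-constrained
#' nights carry no naturalistic school/weekend contrast; set
#' `include_stabilization = TRUE` to keep them. Returns `NA` when either night
#' class has no valid night (the subject is then excluded from social-jetlag
#' analyses).
#'
#' @param nightly Nightly tibble for one subject with `onset`, `night_class`
#'   and optionally `status` / `stabilization` columns.
#' @param include_stabilization Keep stabilization nights (default `FALSE`).
#' @return Non-negative minutes, or `NA`.
#' @export
social_jetlag <- function(nightly, include_stabilization = FALSE) {
  d <- nightly
  if ("status" %in% names(d)) d <- d[d$status == "ok", ]
  if (!include_stabilization && "stabilization" %in% names(d)) {
    d <- d[!d$stabilization, ]
  }
  d <- d[!is.na(d$onset), ]
  sch <- d$onset[d$night_class == "school"]
  fre <- d$onset[d$night_class == "free"]
  if (!length(sch) || !length(fre)) return(NA_real_)
  abs(mean(fre) - mean(sch))
}

#' Dichotomous circadian group labels
#'
#' Applies the four printed cut points:
#' \itemize{
#'   \item circadian phase: DLMO before 22:00 `early`, at/after 22:00 `late`;
#'   \item circadian alignment: phase angle (mean sleep onset minus DLMO) in
#'     \[120, 240\] min `aligned`, under 2 h or over 4 h `misaligned`;
#'   \item social jetlag: at most 60 min `minimal`, over 60 min `present`;
#'   \item chronotype: MEQ total at most 41 `eveningness`, 42 or more
#'     `intermediate_morningness`.
#' }
#' Missing inputs give missing labels, never a default. Factor reference
#' levels are the lower-risk groups (early, aligned, minimal, intermediate to
#' morningness) so risk-group effects are positive in downstream models.
#'
#' @param profiles Tibble with (any of) `dlmo`, `phase_angle`, `sjl`,
#'   `meq_total` columns, times in noon-axis minutes.
#' @return `profiles` with `phase_group`, `alignment_group`, `sjl_group`,
#'   `chronotype_group` factor columns (re-derived if already present:
#'   classification is idempotent).
#' @export
classify_groups <- function(profiles) {
  cut_phase <- clock_to_noon("22:00")
  fac <- function(x, levels) factor(x, levels = levels)
  profiles |>
    mutate(
      phase_group = fac(case_when(
        is.na(.data$dlmo) ~ NA_character_,
        .data$dlmo < cut_phase ~ "early",
        TRUE ~ "late"
      ), c("early", "late")),
      alignment_group = fac(case_when(
        is.na(.data$phase_angle) ~ NA_character_,
        .data$phase_angle >= 120 & .data$phase_angle <= 240 ~ "aligned",
        TRUE ~ "misaligned"
      ), c("aligned", "misaligned")),
      sjl_group = fac(case_when(
        is.na(.data$sjl) ~ NA_character_,
        .data$sjl <= 60 ~ "minimal",
        TRUE ~ "present"
      ), c("minimal", "present")),
      chronotype_group = fac(case_when(
        is.na(.data$meq_total) ~ NA_character_,
        .data$meq_total <= 41 ~ "eveningness",
        TRUE ~ "intermediate_morningness"
      ), c("intermediate_morningness", "eveningness"))
    )
}

#' Assemble per-subject circadian profiles
#'
#' Joins nightly actigraphy summaries, DLMO estimates and the survey table
#' into one row per subject: mean sleep onset, social jetlag, phase angle
#' (mean onset minus DLMO), the four dichotomous group labels, covariates and
#' outcomes. Subjects missing a modality keep explicit `NA`s and still
#' contribute to the analyses their data support (e.g. chronotype analyses
#' need no actigraphy), mirroring per-analysis Ns.
#'
#' @param nightly Nightly tibble ([score_nights()]).
#' @param dlmo DLMO tibble ([estimate_dlmo_all()]).
#' @param survey Survey tibble: `subject`, `sex`, `pds_total`, `income_band`,
#'   `meq_total`, `dass_depression`, `dass_anxiety`, `dass_stress`,
#'   `erq_reappraisal`, `erq_suppression`.
#' @param include_stabilization_in_sjl Passed to [social_jetlag()].
#' @return Profiles tibble, one row per survey subject, classified via
#'   [classify_groups()].
#' @export
build_profiles <- function(nightly, dlmo, survey,
                           include_stabilization_in_sjl = FALSE) {
  survey <- as_tibble(survey)
  if (anyDuplicated(survey$subject)) {
    abort("duplicate subject ids in survey table",
          class = "circsleep_malformed_input")
  }
  if (anyDuplicated(dlmo$subject)) {
    abort("duplicate subject ids in DLMO table",
          class = "circsleep_malformed_input")
  }
  acti <- nightly |>
    group_by(.data$subject) |>
    group_modify(function(d, key) {
      tibble(
        n_nights_valid = sum(d$status == "ok"),
        mean_sleep_onset = mean_sleep_onset(d),
        sjl = social_jetlag(d, include_stabilization = include_stabilization_in_sjl)
      )
    }) |>
    ungroup()

  out <- survey |>
    left_join(acti, by = "subject") |>
    left_join(dlmo |> select("subject", dlmo_status = "status", "dlmo"),
              by = "subject") |>
    mutate(
      n_nights_valid = tidyr::replace_na(.data$n_nights_valid, 0L),
      dlmo_status = tidyr::replace_na(.data$dlmo_status, "missing"),
      dlmo = ifelse(.data$dlmo_status == "ok", .data$dlmo, NA_real_),
      phase_angle = .data$mean_sleep_onset - .data$dlmo
    ) |>
    classify_groups() |>
    mutate(
      mean_onset_clock = noon_to_clock(.data$mean_sleep_onset),
      dlmo_clock = noon_to_clock(.data$dlmo)
    )
  out
}

#' Per-analysis sample sizes
#'
#' Counts subjects with a non-missing label for each of the four circadian
#' groupings — the Ns each group comparison can draw on before listwise
#' deletion on covariates.
#'
#' @param profiles Profiles tibble ([build_profiles()]).
#' @return Tibble `grouping`, `n`, and per-level counts.
#' @export
analysis_ns <- function(profiles) {
  purrr::map(c("phase_group", "alignment_group", "sjl_group", "chronotype_group"),
             function(g) {
    x <- profiles[[g]]
    tibble(grouping = g, n = sum(!is.na(x)),
           n_reference = sum(x == levels(x)[1], na.rm = TRUE),
           n_risk = sum(x == levels(x)[2], na.rm = TRUE))
  }) |> list_rbind()
}
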