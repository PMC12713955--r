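#' Run the full circadian sleep-health pipeline
#'
#' Orchestrates simulate (or load) -> nightly actigraphy scoring -> DLMO
#' estimation -> profile assembly -> group comparisons as one reproducible
#' run. All outputs are plain text with stable column order; the resolved
#' configuration (including the seed) is serialised next to them, so a rerun
#' from the written config regenerates the bundle identically.
#'
#' @param config A list with either a `simulate` element (a [cohort_config()])
#'   or an `inputs` element naming the four CSV paths (`epochs`, `diary`,
#'   `melatonin`, `survey`); optional elements `covariates`,
#'   `epoch_seconds`, `onset_run`, `wake_threshold`, `min_coverage`,
#'   `dlmo_threshold`, `interpolation`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Invisible list: `nightly`, `dlmo`, `profiles`, `comparisons`,
#'   `descriptives`, `ns`, `exclusions`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (!has_sim && !has_inputs) {
    abort("config needs either a 'simulate' block or an 'inputs' block",
          class = "circsleep_config_error")
  }
  covariates <- config$covariates %||% c("sex", "pds_total", "income_band")
  es <- config$epoch_seconds %||% 30

  if (has_sim) {
    cohort <- generate_cohort(config$simulate)
    epochs <- cohort$epochs
    diary <- cohort$diary
    melatonin <- cohort$melatonin
    survey <- cohort$survey
  } else {
    paths <- config$inputs
    need <- c("epochs", "diary", "melatonin", "survey")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      abort(paste0("missing input path(s): ", paste(miss, collapse = ", ")),
            class = "circsleep_config_error")
    }
    for (p in unlist(paths[need])) {
      if (!file.exists(p)) {
        abort(paste0("input file does not exist: ", p),
              class = "circsleep_config_error")
      }
    }
    epochs <- read_epoch_series(paths$epochs, epoch_seconds = es)
    diary <- readr::read_csv(
      paths$diary, progress = FALSE,
      col_types = readr::cols(subject = readr::col_character(),
                              night_date = readr::col_date(),
                              in_bed = readr::col_character(),
                              out_of_bed = readr::col_character()))
    melatonin <- read_melatonin_series(paths$melatonin)
    survey <- readr::read_csv(paths$survey, show_col_types = FALSE)
  }
  if (!"noon_min" %in% names(melatonin)) {
    melatonin$noon_min <- clock_to_noon(melatonin$sample_time)
  }

  nightly <- score_nights(
    epochs, diary,
    onset_run = config$onset_run %||% 10,
    wake_threshold = config$wake_threshold %||% 40,
    min_coverage = config$min_coverage %||% 0.8)
  dlmo <- estimate_dlmo_all(
    melatonin,
    threshold = config$dlmo_threshold %||% 4,
    interpolation = config$interpolation %||% "linear")
  profiles <- build_profiles(nightly, dlmo, survey)
  comparisons <- run_all_comparisons(profiles, covariates = covariates)
  ns <- analysis_ns(profiles)
  descriptives <- cohort_descriptives(profiles)
  exclusions <- tibble(
    stage = c("actigraphy", "dlmo"),
    n_subjects = rep(length(unique(survey$subject)), 2),
    n_valid = c(sum(profiles$n_nights_valid > 0),
                sum(profiles$dlmo_status == "ok")),
    detail = c(
      paste0(sum(nightly$status != "ok"), " night(s) excluded: ",
             paste(names(table(nightly$status[nightly$status != "ok"])),
                   table(nightly$status[nightly$status != "ok"]),
                   collapse = ", ")),
      paste(names(table(dlmo$status)), table(dlmo$status), collapse = ", ")
    ))

  # per-analysis reconciliation: comparison-row Ns never exceed label Ns
  for (g in ns$grouping) {
    rows <- comparisons[comparisons$grouping == g & !is.na(comparisons$F), ]
    if (nrow(rows) && any(rows$n1 + rows$n2 > ns$n[ns$grouping == g])) {
      abort("internal accounting error: model N exceeds labelled N")
    }
  }

  result <- list(nightly = nightly, dlmo = dlmo, profiles = profiles,
                 comparisons = comparisons, descriptives = descriptives,
                 ns = ns, exclusions = exclusions, config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

#' Cohort descriptive statistics
#'
#' Mean/SD table of the circadian measures and outcomes across the cohort
#' (durations reported in minutes, clock times as `"HH:MM"` means).
#'
#' @param profiles Profiles tibble.
#' @return Tibble `measure`, `n`, `mean`, `sd`, `mean_clock`.
#' @export
cohort_descriptives <- function(profiles) {
  num <- list(
    dlmo = profiles$dlmo,
    mean_sleep_onset = profiles$mean_sleep_onset,
    phase_angle = profiles$phase_angle,
    social_jetlag = profiles$sjl,
    meq_total = profiles$meq_total,
    pds_total = profiles$pds_total,
    depression = profiles$dass_depression,
    anxiety = profiles$dass_anxiety,
    stress = profiles$dass_stress,
    cognitive_reappraisal = profiles$erq_reappraisal,
    expressive_suppression = profiles$erq_suppression
  )
  clocky <- c("dlmo", "mean_sleep_onset")
  purrr::imap(num, function(v, nm) {
    tibble(measure = nm, n = sum(!is.na(v)),
           mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
           mean_clock = if (nm %in% clocky) noon_to_clock(mean(v, na.rm = TRUE))
                        else NA_character_)
  }) |> list_rbind()
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) readr::write_tsv(x, file.path(out_dir, f))
  tsv(result$nightly, "nightly.tsv")
  tsv(result$profiles, "profiles.tsv")
  tsv(as_tibble(result$comparisons), "results.tsv")
  tsv(result$descriptives, "table1.tsv")
  tsv(result$ns, "analysis_ns.tsv")
  tsv(result$exclusions, "exclusions.tsv")
  jsonlite::write_json(
    purrr::pmap(result$dlmo, function(subject, status, dlmo, dlmo_clock, threshold) {
      list(subject = subject, status = status,
           dlmo_time = if (is.na(dlmo_clock)) NULL else dlmo_clock,
           threshold = threshold)
    }),
    file.path(out_dir, "dlmo.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(
    list(comparisons = as_tibble(result$comparisons),
         n_tests = attr(result$comparisons, "n_tests")),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  cfg <- result$config
  if (!is.null(cfg$simulate)) {
    cfg$simulate <- unclass(cfg$simulate)
    cfg$simulate$start_date <- as.character(cfg$simulate$start_date)
  }
  jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
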