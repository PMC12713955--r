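#' Plan a salivary melatonin sampling session
#'
#' The session starts 5 h before and ends 1 h after the participant's typical
#' bedtime, sampled every 30 min. The inclusive 6-h grid has 13 nominal
#' points; protocols that count 12 samples simply stop one short of the final
#' grid point, and [read_melatonin_series()] accepts either.
#'
#' @param typical_bedtime Clock time (`"HH:MM"` or noon-axis minutes).
#' @return List with `start`, `end` (noon-axis minutes) and `sample_times`,
#'   the 13 nominal noon-axis sampling times.
#' @export
plan_session_window <- function(typical_bedtime) {
  bt <- clock_to_noon(typical_bedtime)
  start <- bt - 300
  end <- bt + 60
  list(start = start, end = end, sample_times = seq(start, end, by = 30))
}

#' Read salivary melatonin sample series
#'
#' Reads a CSV with columns `subject,sample_time,concentration_pg_ml`
#' (`sample_time` as `"HH:MM"` clock strings). Sample times must be strictly
#' increasing per subject at a nominal 30-min spacing (a tolerance of 5 min is
#' accepted with a warning); subjects with fewer than 8 samples are retained
#' but flagged so that [estimate_dlmo()] reports `insufficient_samples`.
#'
#' @param path CSV path.
#' @return Tibble `subject`, `sample_time` (clock string), `noon_min`,
#'   `concentration_pg_ml`.
#' @export
read_melatonin_series <- function(path) {
  df <- readr::read_csv(
    path, progress = FALSE,
    col_types = readr::cols(subject = readr::col_character(),
                            sample_time = readr::col_character(),
                            concentration_pg_ml = readr::col_double()))
  as_melatonin_series(df)
}

#' @rdname read_melatonin_series
#' @param df Data frame already holding the three columns.
#' @export
as_melatonin_series <- function(df) {
  need <- c("subject", "sample_time", "concentration_pg_ml")
  if (!all(need %in% names(df))) {
    abort(paste0("melatonin data must have columns ", paste(need, collapse = ", ")),
          class = "circsleep_malformed_input")
  }
  df <- as_tibble(df)
  if (anyNA(df$concentration_pg_ml) || any(df$concentration_pg_ml < 0)) {
    abort("melatonin concentrations must be non-negative",
          class = "circsleep_malformed_input")
  }
  df$noon_min <- clock_to_noon(df$sample_time)
  df <- arrange(df, .data$subject, .data$noon_min)
  off_grid <- df |>
    group_by(.data$subject) |>
    summarise(bad = any(diff(.data$noon_min) <= 0),
              irregular = any(abs(diff(.data$noon_min) - 30) > 5)) |>
    ungroup()
  if (any(off_grid$bad)) {
    abort(paste0("sample times not strictly increasing for subject ",
                 off_grid$subject[off_grid$bad][1]),
          class = "circsleep_malformed_input")
  }
  if (any(off_grid$irregular)) {
    warn(paste0("irregular (but tolerated) melatonin sample spacing for: ",
                paste(off_grid$subject[off_grid$irregular], collapse = ", ")))
  }
  df
}

#' Estimate dim-light melatonin onset by threshold crossing
#'
#' DLMO is the clock time at which the piecewise-linear interpolant of the
#' sampled melatonin concentrations first crosses `threshold` (default
#' 4 pg/mL) in a *sustained* rise: the crossing pair is the first consecutive
#' pair with `c[i] < threshold` and `c[i+1] >= threshold` whose next sample,
#' when one exists, is also at or above threshold — a guard against
#' single-sample contamination spikes (disable with `sustained = FALSE`).
#' With `interpolation = "linear"` the crossing time is interpolated within
#' the bracketing pair; `"step"` assigns the first supra-threshold sample time
#' (for sensitivity analysis).
#'
#' Status taxonomy: `ok` (crossing found), `never_above_threshold` (no
#' sustained rise to threshold), `never_below_threshold` (already at/above
#' threshold at the first sample), `insufficient_samples` (fewer than
#' `min_samples` retained samples).
#'
#' @param times Noon-axis sample times, or a melatonin tibble from
#'   [as_melatonin_series()] holding a single subject.
#' @param concentrations Concentrations (pg/mL) matching `times`.
#' @param threshold Threshold in pg/mL (default 4).
#' @param sustained Require the post-crossing sample to stay above threshold.
#' @param interpolation `"linear"` or `"step"`.
#' @param min_samples Minimum retained samples for a valid session (default 8).
#' @return List: `status`, `dlmo` (noon-axis minutes, `NA` unless `ok`),
#'   `dlmo_clock`, `threshold`.
#' @export
estimate_dlmo <- function(times, concentrations = NULL, threshold = 4,
                          sustained = TRUE, interpolation = c("linear", "step"),
                          min_samples = 8) {
  interpolation <- match.arg(interpolation)
  if (is.data.frame(times)) {
    concentrations <- times$concentration_pg_ml
    times <- times$noon_min
  }
  res <- function(status, dlmo = NA_real_) {
    list(status = status, dlmo = dlmo,
         dlmo_clock = noon_to_clock(dlmo), threshold = threshold)
  }
  n <- length(times)
  if (n < min_samples) return(res("insufficient_samples"))
  o <- order(times)
  t <- times[o]
  c_ <- concentrations[o]
  if (c_[1] >= threshold) return(res("never_below_threshold"))
  above <- c_ >= threshold
  if (!any(above)) return(res("never_above_threshold"))
  for (i in seq_len(n - 1)) {
    if (c_[i] < threshold && c_[i + 1] >= threshold) {
      ok <- !sustained || i + 2 > n || c_[i + 2] >= threshold
      if (ok) {
        dlmo <- if (interpolation == "linear") {
          t[i] + (threshold - c_[i]) / (c_[i + 1] - c_[i]) * (t[i + 1] - t[i])
        } else {
          t[i + 1]
        }
        return(res("ok", dlmo))
      }
    }
  }
  res("never_above_threshold")   # spikes only, no sustained rise
}

#' Estimate DLMO for every subject in a melatonin table
#'
#' @param melatonin Tibble from [read_melatonin_series()] (any number of
#'   subjects).
#' @inheritParams estimate_dlmo
#' @return Tibble: `subject`, `status`, `dlmo` (noon-axis minutes),
#'   `dlmo_clock`, `threshold`.
#' @export
estimate_dlmo_all <- function(melatonin, threshold = 4, sustained = TRUE,
                              interpolation = c("linear", "step"),
                              min_samples = 8) {
  interpolation <- match.arg(interpolation)
  melatonin |>
    group_by(.data$subject) |>
    group_modify(function(d, key) {
      e <- estimate_dlmo(d$noon_min, d$concentration_pg_ml,
                         threshold = threshold, sustained = sustained,
                         interpolation = interpolation,
                         min_samples = min_samples)
      tibble(status = e$status, dlmo = e$dlmo,
             dlmo_clock = e$dlmo_clock %||% NA_character_,
             threshold = e$threshold)
    }) |>
    ungroup()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
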