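# rolling sum of v over windows of length k, end-aligned: out[i] = sum(v[(i-k+1):i])
roll_sum <- function(v, k) {
  cs <- cumsum(v)
  cs - c(rep(0, k), head(cs, -k))
}

#' Sadeh sleep/wake scoring of one-minute activity counts
#'
#' Scores each minute of a one-minute-epoch activity series as sleep or wake
#' with the Sadeh linear discriminant
#' \deqn{PS = 7.601 - 0.065\,MW5 - 1.08\,NAT - 0.056\,SD6 - 0.703\,LG}
#' where, for the scored minute, `MW5` is the mean count over the 11-minute
#' window centred on it, `NAT` the number of minutes in that window with counts
#' in \[50, 100), `SD6` the population standard deviation of the scored minute
#' and the 5 preceding minutes, and `LG` the natural log of (count + 1). A
#' minute is scored *sleep* when `PS >= 0`. Windows extending past either end
#' of the series are padded with zero counts, so labels are deterministic at
#' the boundaries.
#'
#' @param counts Numeric vector of one-minute activity counts (non-negative),
#'   or an epoch tibble at 60-s resolution (a `label` column is then appended).
#' @param cap Optional ceiling applied to counts before scoring (some device
#'   software clips extreme counts); default `NULL` applies the bare formula.
#' @return For a vector: character vector of `"sleep"`/`"wake"`, one per
#'   minute. For a tibble: the tibble with `label` added (scored per subject
#'   and recording block).
#' @references Sadeh et al. (1994), activity-based sleep-wake identification.
#' @export
sadeh_scores <- function(counts, cap = NULL) {
  if (is.data.frame(counts)) {
    es <- epoch_seconds_of(counts, 60)
    if (es != 60) {
      abort("sadeh_scores needs 60-s epochs; call aggregate_to_minutes() first",
            class = "circsleep_unsupported_resolution")
    }
    if (!"block" %in% names(counts)) counts$block <- 0L
    counts <- counts |>
      group_by(.data$subject, .data$block) |>
      mutate(label = sadeh_scores(.data$count, cap = cap)) |>
      ungroup()
    return(counts)
  }
  n <- length(counts)
  if (n < 1) abort("empty activity series", class = "circsleep_empty_input")
  ifelse(sadeh_ps(counts, cap = cap) >= 0, "sleep", "wake")
}

#' @rdname sadeh_scores
#' @export
sadeh_ps <- function(counts, cap = NULL) {
  n <- length(counts)
  if (n < 1) abort("empty activity series", class = "circsleep_empty_input")
  x <- as.numeric(counts)
  if (!is.null(cap)) x <- pmin(x, cap)
  z <- c(rep(0, 5), x, rep(0, 5))          # zero padding at both boundaries
  # MW5 / NAT: 11-minute window centred on the scored minute
  s11 <- roll_sum(z, 11)[(5 + 1:n) + 5]    # window ends 5 after scored minute
  mw5 <- s11 / 11
  nat11 <- roll_sum(as.numeric(z >= 50 & z < 100), 11)[(5 + 1:n) + 5]
  # SD6: scored minute and the 5 preceding, population form
  s6 <- roll_sum(z, 6)[5 + 1:n]
  q6 <- roll_sum(z^2, 6)[5 + 1:n]
  sd6 <- sqrt(pmax(q6 / 6 - (s6 / 6)^2, 0))
  lg <- log(x + 1)
  7.601 - 0.065 * mw5 - 1.08 * nat11 - 0.056 * sd6 - 0.703 * lg
}

#' Detect the nightly sleep period from scored minutes
#'
#' Within the diary-defined in-bed window, sleep onset is the first minute of
#' the first run of at least `onset_run` consecutive sleep-scored minutes at or
#' after in-bed time; sleep offset is the minute after the last minute of the
#' last such run at or before out-of-bed time.
#'
#' @param labels Character (`"sleep"`/`"wake"`) or logical (sleep = `TRUE`)
#'   per-minute labels covering the in-bed window.
#' @param in_bed,out_of_bed In-bed and out-of-bed times on the noon axis
#'   (minutes; see [clock_to_noon()]). `times` defaults to consecutive minutes
#'   starting at `in_bed`.
#' @param times Optional noon-axis minute start times aligned with `labels`.
#' @param onset_run Minimum run length in minutes (default 10).
#' @return A list with `onset`, `offset` (noon-axis minutes) and `scored`, a
#'   tibble of minute times and labels.
#' @export
detect_sleep_period <- function(labels, in_bed, out_of_bed, times = NULL,
                                onset_run = 10) {
  if (is.character(labels)) labels <- labels == "sleep"
  if (is.null(times)) times <- in_bed + seq_along(labels) - 1
  keep <- times >= in_bed & times < out_of_bed
  labels <- labels[keep]
  times <- times[keep]
  n <- length(labels)
  if (n < onset_run) {
    abort("in-bed window shorter than the minimum sleep run",
          class = "circsleep_no_sleep")
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  qual <- which(r$values & r$lengths >= onset_run)
  if (!length(qual)) {
    abort("no run of sleep-scored minutes long enough to qualify as sleep",
          class = "circsleep_no_sleep")
  }
  onset_i <- starts[qual[1]]
  offset_i <- ends[qual[length(qual)]]
  list(
    onset = times[onset_i],
    offset = times[offset_i] + 1,   # first minute after the final sleep run
    scored = tibble(noon_min = times,
                    label = ifelse(labels, "sleep", "wake"))
  )
}
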