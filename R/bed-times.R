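#' Infer in-bed and out-of-bed times from the activity trace
#'
#' Fallback used when a diary entry is missing or visibly contradicts the
#' recorded activity. In-bed time is the start of the last maximal strictly
#' decreasing run of 10-minute (trailing) mean activity leading into the
#' longest low-activity block of the night; out-of-bed time is the first
#' minute after that block whose forward 30-minute rolling mean exceeds the
#' wake threshold (the first prolonged bout of activity after sleep).
#'
#' @param minutes Tibble of one-minute counts for one subject-night with
#'   columns `noon_min` and `count`.
#' @param window_hint Noon-axis interval searched (default 17:00 to 11:00 the
#'   next morning).
#' @param wake_threshold Counts/min below which a minute counts as
#'   low-activity (default 40).
#' @param min_block_min Minimum low-activity block length in minutes treated
#'   as candidate sleep (default 180).
#' @return List with `in_bed` and `out_of_bed` (noon-axis minutes).
#' @export
infer_bed_times <- function(minutes, window_hint = c(300, 1380),
                            wake_threshold = 40, min_block_min = 180) {
  d <- minutes |>
    filter(.data$noon_min >= window_hint[1], .data$noon_min < window_hint[2]) |>
    arrange(.data$noon_min)
  if (nrow(d) < min_block_min) {
    abort("too little activity data in the hint window to infer bed times",
          class = "circsleep_cannot_infer")
  }
  x <- d$count
  t <- d$noon_min
  # low-activity judged on a trailing 10-min mean so isolated movement
  # artefacts inside sleep do not fragment the block
  m10 <- roll_sum(c(rep(0, 9), x), 10)[9 + seq_along(x)] / 10
  low <- m10 < wake_threshold
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths >= min_block_min)
  if (!length(cand)) {
    abort("no low-activity block of at least 3 h in the hint window",
          class = "circsleep_cannot_infer")
  }
  main <- cand[which.max(r$lengths[cand])]
  b_start <- starts[main]
  b_end <- ends[main]

  # trailing 10-min mean; the wind-down shows as a strictly decreasing run
  r10 <- roll_sum(c(rep(0, 9), x), 10)[9 + seq_along(x)] / 10
  lim <- min(length(x) - 1, b_start + 9)
  dec <- diff(r10)[seq_len(lim)] < 0
  if (!any(dec)) {
    abort("no downward activity trend precedes the low-activity block",
          class = "circsleep_cannot_infer")
  }
  rr <- rle(dec)
  rends <- cumsum(rr$lengths)
  rstarts <- rends - rr$lengths + 1
  runs <- which(rr$values)
  ri <- runs[length(runs)]                 # run closest to the block
  in_bed_i <- rstarts[ri] + 1              # first minute where the mean falls
  if (t[in_bed_i] >= t[b_start]) in_bed_i <- max(1, b_start - 1)

  # forward 30-min mean after the block; first sustained activity = out of bed
  xz <- c(x, rep(0, 29))
  r30 <- roll_sum(xz, 30)[30:(length(x) + 29)] / 30  # r30[i] = mean x[i..i+29]
  after <- which(r30 > wake_threshold)
  after <- after[after > b_end]
  out_i <- if (length(after)) after[1] else length(x)
  list(in_bed = t[in_bed_i], out_of_bed = t[out_i])
}
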