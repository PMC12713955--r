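#' Classify a night as school or free
#'
#' A night is *free* when its morning (the day after `night_date`) falls on a
#' Saturday or Sunday — the mornings with no school-constrained wake time —
#' and *school* otherwise.
#'
#' @param night_date `Date` vector (the date of the evening).
#' @return Character vector `"school"`/`"free"`.
#' @export
night_class_of <- function(night_date) {
  wd <- as.POSIXlt(as.Date(night_date) + 1)$wday   # 0 = Sunday, 6 = Saturday
  ifelse(wd %in% c(0, 6), "free", "school")
}

#' Summarise a detected sleep period for one night
#'
#' Duration is offset minus onset in minutes; midsleep is the temporal
#' midpoint of onset and offset, so `midsleep - onset == offset - midsleep`
#' exactly on the noon axis.
#'
#' @param onset,offset Sleep onset/offset, noon-axis minutes (vectorised).
#' @param night_date `Date` of the evening.
#' @param night_class Optional `"school"`/`"free"` override; derived from the
#'   calendar via [night_class_of()] when `NULL`.
#' @return One-row-per-night tibble with times both in noon-axis minutes and
#'   `"HH:MM"` clock strings.
#' @export
summarize_night <- function(onset, offset, night_date, night_class = NULL) {
  stopifnot(all(offset > onset))
  if (is.null(night_class)) night_class <- night_class_of(night_date)
  duration <- offset - onset
  midsleep <- onset + duration / 2
  tibble(
    night_date = as.Date(night_date),
    night_class = night_class,
    onset = onset, offset = offset,
    duration_min = duration,
    midsleep = midsleep,
    onset_clock = noon_to_clock(onset),
    offset_clock = noon_to_clock(offset),
    midsleep_clock = noon_to_clock(midsleep)
  )
}

#' Score all diary nights of an actigraphy recording
#'
#' The per-night driver: pairs the epoch series with the sleep diary, checks
#' recording coverage, resolves in-bed/out-of-bed times (diary first, falling
#' back to [infer_bed_times()] when the diary is missing or contradicts the
#' trace), aggregates to one-minute epochs, applies Sadeh scoring and the
#' consecutive-run onset/offset rule, and summarises each night.
#'
#' Exclusion rules: nights with less than `min_coverage` of the expected
#' epochs in the in-bed window are excluded (`excluded_low_coverage`); nights
#' where bed times cannot be inferred are `excluded_cannot_infer`; nights with
#' no qualifying sleep run are `excluded_no_sleep`. Excluded nights stay in
#' the output with an explanatory `status`, never silently dropped.
#'
#' The diary-vs-trace discrepancy triggers are: mean activity in the 30 min
#' after diary in-bed above `wake_threshold`, or every minute in the 30 min
#' before diary out-of-bed below it.
#'
#' @param epochs Epoch tibble ([read_epoch_series()]).
#' @param diary Tibble with columns `subject`, `night_date`, `in_bed`,
#'   `out_of_bed` (`"HH:MM"`, possibly `NA`).
#' @param onset_run Minimum consecutive sleep-scored minutes defining
#'   onset/offset (default 10).
#' @param wake_threshold Counts/min separating rest from activity (default 40).
#' @param min_coverage Minimum fraction of expected epochs present in the
#'   in-bed window (default 0.8).
#' @param cap Optional count ceiling passed to [sadeh_scores()].
#' @param stabilization_nights Night indices (per subject, in diary order)
#'   spent on a fixed self-selected bedtime; marked so social-jetlag
#'   computations can exclude them (default nights 8-10).
#' @return Nightly tibble: one row per diary night with `status` (`"ok"` or an
#'   exclusion reason), night metadata, and the sleep summary columns of
#'   [summarize_night()] where scored.
#' @export
score_nights <- function(epochs, diary, onset_run = 10, wake_threshold = 40,
                         min_coverage = 0.8, cap = NULL,
                         stabilization_nights = 8:10) {
  es <- epoch_seconds_of(epochs, 30)
  diary <- as_tibble(diary)
  diary$night_date <- as.Date(diary$night_date)
  diary <- diary |>
    group_by(.data$subject) |>
    arrange(.data$night_date, .by_group = TRUE) |>
    mutate(night_index = row_number()) |>
    ungroup()

  minutes <- suppressWarnings(aggregate_to_minutes(epochs))
  mkey <- split(seq_len(nrow(minutes)),
                paste(minutes$subject, minutes$night_date))
  ekey <- split(seq_len(nrow(epochs)),
                paste(epochs$subject, epochs$night_date))
  m_noon <- minutes$noon_min
  m_count <- minutes$count
  e_noon <- epochs$noon_min

  nN <- nrow(diary)
  dkey <- paste(diary$subject, diary$night_date)
  d_in <- clock_to_noon(diary$in_bed)
  d_out <- clock_to_noon(diary$out_of_bed)
  status <- rep("ok", nN)
  in_bed_v <- out_ob_v <- onset_v <- offset_v <- rep(NA_real_, nN)

  for (i in seq_len(nN)) {
    midx <- mkey[[dkey[i]]]
    if (is.null(midx) || !length(midx)) {
      status[i] <- "excluded_low_coverage"
      next
    }
    nt <- m_noon[midx]
    nc <- m_count[midx]
    in_bed <- d_in[i]
    out_ob <- d_out[i]

    need_infer <- is.na(in_bed) || is.na(out_ob)
    if (!need_infer) {
      post <- nc[nt >= in_bed & nt < in_bed + 30]
      pre <- nc[nt >= out_ob - 30 & nt < out_ob]
      need_infer <- (length(post) > 0 && mean(post) > wake_threshold) ||
        (length(pre) > 0 && all(pre < wake_threshold))
    }
    if (need_infer) {
      bt <- tryCatch(
        infer_bed_times(tibble(noon_min = nt, count = nc),
                        wake_threshold = wake_threshold),
        circsleep_cannot_infer = function(e) NULL)
      if (is.null(bt)) {
        status[i] <- "excluded_cannot_infer"
        next
      }
      in_bed <- bt$in_bed
      out_ob <- bt$out_of_bed
    }
    in_bed_v[i] <- in_bed
    out_ob_v[i] <- out_ob

    ep_noon <- e_noon[ekey[[dkey[i]]]]
    present <- sum(ep_noon >= in_bed & ep_noon < out_ob)
    expected <- (out_ob - in_bed) * 60 / es
    if (expected <= 0 || present / expected < min_coverage) {
      status[i] <- "excluded_low_coverage"
      next
    }

    inwin <- nt >= in_bed & nt < out_ob
    labels <- sadeh_ps(nc[inwin], cap = cap) >= 0
    per <- tryCatch(
      detect_sleep_period(labels, in_bed, out_ob, times = nt[inwin],
                          onset_run = onset_run),
      circsleep_no_sleep = function(e) NULL
    )
    if (is.null(per)) {
      status[i] <- "excluded_no_sleep"
      next
    }
    onset_v[i] <- per$onset
    offset_v[i] <- per$offset
  }
  out <- tibble(
    subject = diary$subject,
    night_date = diary$night_date,
    night_index = diary$night_index,
    stabilization = diary$night_index %in% stabilization_nights,
    night_class = night_class_of(diary$night_date),
    status = status,
    in_bed = in_bed_v, out_of_bed = out_ob_v,
    onset = onset_v, offset = offset_v,
    duration_min = offset_v - onset_v,
    midsleep = onset_v + (offset_v - onset_v) / 2
  )
  out$onset_clock <- noon_to_clock(out$onset)
  out$offset_clock <- noon_to_clock(out$offset)
  out$midsleep_clock <- noon_to_clock(out$midsleep)
  out
}
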