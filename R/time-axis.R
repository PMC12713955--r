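#' The noon-to-noon clock axis
#'
#' Evening and night events (bedtimes, sleep onsets, DLMO) straddle midnight,
#' which makes naive clock arithmetic treacherous: 00:30 "follows" 23:00 but is
#' numerically smaller. All clock times in circsleep therefore live on a
#' *noon-to-noon axis*: minutes elapsed since 12:00 of the night's reference
#' date. On this axis 23:00 is 660, 00:30 is 750, and 07:00 the next morning is
#' 1140, so ordinary subtraction gives durations and means with no midnight
#' wrap-around.
#'
#' `clock_to_noon()` converts `"HH:MM"` (or `"HH:MM:SS"`) strings, placing
#' times from 12:00:00 to 23:59:59 on the evening of the reference date and
#' times before noon on the following morning. `noon_to_clock()` inverts the
#' mapping, rounding to the minute.
#'
#' @param x Character vector of clock times (`"HH:MM"` or `"HH:MM:SS"`), or a
#'   numeric vector of minutes for `noon_to_clock()`.
#' @return `clock_to_noon()`: numeric minutes since noon (0 to 1439).
#'   `noon_to_clock()`: character `"HH:MM"`.
#' @examples
#' clock_to_noon(c("23:00", "00:30", "07:00"))
#' noon_to_clock(c(660, 750, 1140))
#' @export
clock_to_noon <- function(x) {
  if (inherits(x, "hms")) {
    mins <- as.numeric(x) / 60          # hms stores seconds since midnight
    return(ifelse(mins >= 720, mins - 720, mins + 720))
  }
  if (inherits(x, "difftime")) {
    mins <- as.numeric(x, units = "mins")
    return(ifelse(mins >= 720, mins - 720, mins + 720))
  }
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & nzchar(x)
  if (any(ok)) {
    parts <- strsplit(x[ok], ":", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) < 2L, logical(1))
    if (any(bad)) {
      abort("clock times must be 'HH:MM' or 'HH:MM:SS'",
            class = "circsleep_malformed_input")
    }
    h <- vapply(parts, function(p) as.numeric(p[[1]]), numeric(1))
    m <- vapply(parts, function(p) as.numeric(p[[2]]), numeric(1))
    s <- vapply(parts, function(p) if (length(p) >= 3) as.numeric(p[[3]]) else 0, numeric(1))
    mins <- h * 60 + m + s / 60
    out[ok] <- ifelse(h >= 12, mins - 720, mins + 720)
  }
  out
}

#' @rdname clock_to_noon
#' @export
noon_to_clock <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  mins <- (round(x[ok]) + 720) %% 1440
  out[ok] <- sprintf("%02d:%02d", mins %/% 60, mins %% 60)
  out
}

#' Assign timestamps to nights and to the noon axis
#'
#' A timestamp at or after 12:00 belongs to the night of its own calendar date;
#' a timestamp before 12:00 belongs to the previous date's night. Used when
#' pairing raw epoch records with diary nights.
#'
#' @param ts A `POSIXct` vector (local clock).
#' @return `night_date_of()`: a `Date`; `timestamp_to_noon()`: minutes since
#'   noon of that night date.
#' @export
night_date_of <- function(ts) {
  lt <- as.POSIXlt(ts)
  as.Date(ifelse(lt$hour >= 12, as.character(as.Date(lt)),
                 as.character(as.Date(lt) - 1)))
}

#' @rdname night_date_of
#' @export
timestamp_to_noon <- function(ts) {
  lt <- as.POSIXlt(ts)
  mins <- lt$hour * 60 + lt$min + lt$sec / 60
  ifelse(lt$hour >= 12, mins - 720, mins + 720)
}

# Compose a POSIXct from a night date and noon-axis minutes (used by the
# synthetic generator when writing epoch timestamps).
noon_to_timestamp <- function(night_date, noon_min) {
  as.POSIXct(as.Date(night_date), tz = "UTC") + 12 * 3600 + round(noon_min * 60)
}
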