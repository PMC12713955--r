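#' Read and validate epoch-level activity counts
#'
#' Reads a wrist-actigraph export with columns `subject,timestamp,count`
#' (ISO-8601 local timestamps, one row per recording epoch) and validates it
#' into a tidy epoch series. Within each continuous recording block timestamps
#' must be uniformly spaced at `epoch_seconds`; gaps of at most two missing
#' epochs are filled with zero counts (with a warning), larger gaps within a
#' block are an error, and gaps of six hours or more are treated as boundaries
#' between recording blocks (e.g. the watch taken off between nights).
#'
#' @param path Path to the epoch CSV.
#' @param epoch_seconds Recording epoch length in seconds (default 30).
#' @return A tibble with columns `subject`, `timestamp`, `count`, `night_date`,
#'   `noon_min` (minutes since noon of `night_date`) and attribute
#'   `epoch_seconds`.
#' @seealso [as_epoch_series()] for data frames already in memory.
#' @export
read_epoch_series <- function(path, epoch_seconds = 30) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_epoch_series(df, epoch_seconds = epoch_seconds)
}

#' Validate an in-memory epoch data frame
#'
#' The data-frame-first twin of [read_epoch_series()]: applies the same
#' validation and gap-filling rules to a data frame with columns
#' `subject`, `timestamp`, `count`.
#'
#' @param df Data frame with columns `subject`, `timestamp` (POSIXct or
#'   ISO-8601 character) and `count`.
#' @inheritParams read_epoch_series
#' @return See [read_epoch_series()].
#' @export
as_epoch_series <- function(df, epoch_seconds = 30) {
  need <- c("subject", "timestamp", "count")
  if (!all(need %in% names(df))) {
    abort(paste0("epoch data must have columns ", paste(need, collapse = ", ")),
          class = "circsleep_malformed_input")
  }
  if (epoch_seconds <= 0 || epoch_seconds != round(epoch_seconds)) {
    abort("epoch_seconds must be a positive integer",
          class = "circsleep_malformed_input")
  }
  df <- as_tibble(df)
  if (is.character(df$timestamp)) {
    df$timestamp <- as.POSIXct(df$timestamp, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  }
  if (anyNA(df$timestamp)) {
    abort("unparseable timestamps in epoch data", class = "circsleep_malformed_input")
  }
  if (anyNA(df$count) || any(df$count < 0)) {
    abort("activity counts must be non-negative and non-missing",
          class = "circsleep_malformed_input")
  }

  df <- arrange(df, .data$subject, .data$timestamp)
  filled_total <- 0L
  out <- df |>
    group_by(.data$subject) |>
    group_modify(function(d, key) {
      dt <- as.numeric(diff(d$timestamp), units = "secs")
      if (any(dt <= 0)) {
        abort(paste0("timestamps not strictly increasing for subject ", key$subject),
              class = "circsleep_malformed_input")
      }
      if (any(dt %% epoch_seconds != 0)) {
        abort(paste0("non-uniform epoch spacing for subject ", key$subject,
                     " (not a multiple of ", epoch_seconds, " s)"),
              class = "circsleep_malformed_input")
      }
      k_missing <- dt / epoch_seconds - 1       # epochs missing in each gap
      block_break <- dt >= 6 * 3600
      bad <- k_missing > 2 & !block_break
      if (any(bad)) {
        abort(paste0("gap of ", k_missing[which(bad)[1]], " epochs for subject ",
                     key$subject, " exceeds the 2-epoch fill limit"),
              class = "circsleep_malformed_input")
      }
      fill_at <- which(k_missing >= 1 & !block_break)
      if (length(fill_at)) {
        filled_total <<- filled_total + sum(k_missing[fill_at])
        fills <- lapply(fill_at, function(i) {
          tibble(timestamp = d$timestamp[i] + epoch_seconds * seq_len(k_missing[i]),
                 count = 0)
        })
        d <- bind_rows(d, bind_rows(fills)) |> arrange(.data$timestamp)
      }
      blk <- cumsum(c(0, as.numeric(diff(d$timestamp), units = "secs") >= 6 * 3600))
      d$block <- blk
      d
    }) |>
    ungroup()
  if (filled_total > 0) {
    warn(paste0("zero-filled ", filled_total, " missing epoch(s)"))
  }
  out$night_date <- night_date_of(out$timestamp)
  out$noon_min <- timestamp_to_noon(out$timestamp)
  attr(out, "epoch_seconds") <- epoch_seconds
  out
}

epoch_seconds_of <- function(epochs, default = NULL) {
  es <- attr(epochs, "epoch_seconds")
  if (!is.null(es)) return(es)
  if (!is.null(default)) return(default)
  dt <- as.numeric(diff(epochs$timestamp), units = "secs")
  stats::median(dt[dt > 0])
}

#' Aggregate sub-minute epochs to one-minute epochs
#'
#' Sadeh scoring is defined on one-minute activity counts; recordings are
#' typically made at 30-s epochs. Counts are summed within each minute,
#' aligned to the start of each continuous recording block; a trailing partial
#' minute is dropped with a warning.
#'
#' @param epochs An epoch tibble from [read_epoch_series()] /
#'   [as_epoch_series()].
#' @param epoch_seconds Epoch length, taken from the attribute when absent.
#' @return The series at 60-s resolution (unchanged if already there).
#' @export
aggregate_to_minutes <- function(epochs, epoch_seconds = NULL) {
  es <- epoch_seconds_of(epochs, epoch_seconds)
  if (es > 60) {
    abort("cannot aggregate epochs longer than 60 s to minutes",
          class = "circsleep_unsupported_resolution")
  }
  if (60 %% es != 0) {
    abort("epoch_seconds must divide 60", class = "circsleep_unsupported_resolution")
  }
  if (es == 60) return(epochs)
  k <- 60L / es
  if (!"block" %in% names(epochs)) epochs$block <- 0L

  d <- epochs[order(epochs$subject, epochs$block, epochs$timestamp), ]
  gkey <- paste(d$subject, d$block)
  new_grp <- !duplicated(gkey)
  g <- cumsum(new_grp)
  first <- which(new_grp)
  n_rows <- nrow(d)
  base <- rep(first, diff(c(first, n_rows + 1L)))
  pos <- seq_len(n_rows) - base + 1L
  sz <- tabulate(g)
  n_min <- sz %/% k
  keep <- pos <= (n_min * k)[g]
  dropped <- n_rows - sum(keep)
  minute <- (pos - 1L) %/% k
  key <- g * 10000000 + minute          # increasing along rows
  sums <- rowsum(d$count[keep], key[keep], reorder = FALSE)
  starts <- keep & (pos %% k == 1L)
  out <- tibble(
    subject = d$subject[starts],
    block = d$block[starts],
    timestamp = d$timestamp[starts],
    count = as.numeric(sums[, 1])
  )
  if ("night_date" %in% names(d) && "noon_min" %in% names(d)) {
    out$night_date <- d$night_date[starts]
    out$noon_min <- d$noon_min[starts]
  } else {
    out$night_date <- night_date_of(out$timestamp)
    out$noon_min <- timestamp_to_noon(out$timestamp)
  }
  if (dropped > 0) warn(paste0("dropped ", dropped, " trailing sub-minute epoch(s)"))
  attr(out, "epoch_seconds") <- 60
  out
}
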