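#' Read an emergency-operation log
#'
#' CSV with columns `timestamp` (ISO 8601, `YYYY-MM-DDTHH:MM:SS`) and
#' `transfer_minutes` (alert-to-angiosuite-arrival time, `> 0`). Rows with
#' unparseable timestamps are dropped with a warning.
#'
#' @param path CSV file path.
#' @return Data frame with `timestamp` (POSIXct, UTC) and
#'   `transfer_minutes`.
#' @export
read_oplog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp", "transfer_minutes") %in% names(df))) {
    stop("oplog CSV must have columns timestamp, transfer_minutes",
         call. = FALSE)
  }
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- is.na(ts)
  if (any(bad)) {
    warning(sprintf("dropping %d row(s) with unparseable timestamps",
                    sum(bad)), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    ts <- ts[!bad]
  }
  if (any(df$transfer_minutes <= 0)) {
    stop("transfer_minutes must be > 0", call. = FALSE)
  }
  data.frame(timestamp = ts, transfer_minutes = df$transfer_minutes)
}

#' Write an emergency-operation log to CSV
#'
#' @param records Data frame with `timestamp` (POSIXct) and
#'   `transfer_minutes`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_oplog <- function(records, path) {
  out <- data.frame(
    timestamp = format(records$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    transfer_minutes = records$transfer_minutes)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.day_type <- function(timestamp) {
  # %u is locale-independent: Monday = 1 ... Sunday = 7
  ifelse(as.integer(format(timestamp, "%u")) <= 5, "weekday", "weekend")
}

#' Summarise an operation log
#'
#' Counts and integer percentages (of the full log, rounded half away
#' from zero) by day type (weekday = Monday--Friday) and by
#' day type x hour, with per-stratum median and mean transfer times.
#'
#' @param records Data frame with `timestamp` (POSIXct) and
#'   `transfer_minutes`.
#' @return List with `n_total`, `by_day_type` (data frame `day_type`, `n`,
#'   `percent`), `by_hour` (data frame `day_type`, `hour`, `n`, `percent`,
#'   `median_transfer`, `mean_transfer`), and overall
#'   `median_transfer` / `mean_transfer`.
#' @export
summarize_oplog <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("operation log is empty", call. = FALSE)
  }
  n_total <- nrow(records)
  dt <- .day_type(records$timestamp)
  hr <- as.integer(format(records$timestamp, "%H"))
  pct <- function(n) round_half_away(100 * n / n_total)

  by_dt <- data.frame(day_type = c("weekday", "weekend"))
  by_dt$n <- vapply(by_dt$day_type, function(d) sum(dt == d), numeric(1))
  by_dt$percent <- pct(by_dt$n)

  grid <- expand.grid(day_type = c("weekday", "weekend"), hour = 0:23,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$day_type, grid$hour), ]
  rownames(grid) <- NULL
  stats_row <- function(d, h) {
    sel <- dt == d & hr == h
    c(n = sum(sel),
      median_transfer = if (any(sel)) stats::median(
        records$transfer_minutes[sel]) else NA_real_,
      mean_transfer = if (any(sel)) mean(
        records$transfer_minutes[sel]) else NA_real_)
  }
  st <- t(mapply(stats_row, grid$day_type, grid$hour))
  by_hour <- cbind(grid, n = st[, "n"], percent = pct(st[, "n"]),
                   median_transfer = st[, "median_transfer"],
                   mean_transfer = st[, "mean_transfer"])
  rownames(by_hour) <- NULL

  list(n_total = n_total, by_day_type = by_dt, by_hour = by_hour,
       median_transfer = stats::median(records$transfer_minutes),
       mean_transfer = mean(records$transfer_minutes))
}

#' Count operations in a clock window
#'
#' Counts records whose hour lies in the half-open clock window
#' `[hour_start, hour_end)`; the window may wrap midnight
#' (`hour_start > hour_end`), and `hour_start == hour_end` is the empty
#' window. The percentage is taken against the full log.
#'
#' @param records Operation-log data frame.
#' @param hour_start,hour_end Hours in 0..23.
#' @param day_type Optional filter, `"weekday"` or `"weekend"`.
#' @return List with `n` and `percent`.
#' @export
window_count <- function(records, hour_start, hour_end, day_type = NULL) {
  .chk_num(hour_start, "hour_start", 0, 23)
  .chk_num(hour_end, "hour_end", 0, 23)
  n_total <- nrow(records)
  hr <- as.integer(format(records$timestamp, "%H"))
  sel <- if (hour_start <= hour_end) {
    hr >= hour_start & hr < hour_end
  } else {
    hr >= hour_start | hr < hour_end
  }
  if (hour_start == hour_end) sel <- rep(FALSE, length(hr))
  if (!is.null(day_type)) {
    sel <- sel & .day_type(records$timestamp) == day_type
  }
  list(n = sum(sel), percent = round_half_away(100 * sum(sel) / n_total))
}

#' Reference per-hour operation counts
#'
#' Deterministic per-(day type, hour) counts of the bundled
#' `"lueneburg-like"` preset: 128 operations in total, 106 on weekdays and
#' 22 on weekends; on weekdays 69 operations between 08:00 and 17:00, 8
#' between midnight and 07:00, none at 02:00--03:59, and a maximum of 15
#' at 10:00; on weekends none at 03:00--06:59, 14:00--15:59 or 20:00, and
#' a maximum of 3 at 17:00.
#'
#' @return Data frame with `day_type`, `hour`, `n`.
#' @export
lueneburg_like_counts <- function() {
  weekday <- c(2, 1, 0, 0, 1, 1, 3, 5, 9, 12, 15, 10,
               7, 5, 4, 3, 4, 6, 5, 4, 3, 2, 2, 2)
  weekend <- c(1, 1, 1, 0, 0, 0, 0, 1, 1, 2, 2, 2,
               2, 1, 0, 0, 2, 3, 1, 1, 0, 1, 0, 0)
  data.frame(
    day_type = rep(c("weekday", "weekend"), each = 24),
    hour = rep(0:23, 2),
    n = c(weekday, weekend))
}

#' Generate a synthetic operation log
#'
#' Seed-deterministic synthetic emergency-operation log. With
#' `preset = "lueneburg-like"` the per-(day type, hour) counts are exactly
#' [lueneburg_like_counts()] (counts are deterministic, only dates within
#' stratum and transfer times are sampled); otherwise `n` operations are
#' drawn with hour probabilities proportional to `hourly_weights` on
#' random dates. Transfer times are normal around `transfer_mean` with sd
#' `transfer_sd`, floored at 20 min and rounded to whole minutes.
#'
#' @param seed Integer seed.
#' @param n Number of operations (ignored with a preset).
#' @param hourly_weights Non-negative weights of length 24, not all zero
#'   (ignored with a preset).
#' @param transfer_mean,transfer_sd Transfer-time distribution (minutes).
#' @param preset Optional, `"lueneburg-like"`.
#' @return Operation-log data frame (`timestamp`, `transfer_minutes`).
#' @export
generate_oplog <- function(seed = 1L, n = 128,
                           hourly_weights = rep(1, 24),
                           transfer_mean = 82, transfer_sd = 18,
                           preset = NULL) {
  .with_seed(seed, {
    if (!is.null(preset)) {
      if (!identical(preset, "lueneburg-like")) {
        stop("unknown preset", call. = FALSE)
      }
      counts <- lueneburg_like_counts()
      # pools of study-period dates: Mon-Fri cycle / Sat-Sun cycle
      wk_dates <- seq(as.Date("2016-04-04"), by = 1, length.out = 1400)
      wk_dates <- wk_dates[as.integer(format(wk_dates, "%u")) <= 5]
      we_dates <- seq(as.Date("2016-04-02"), by = 1, length.out = 1400)
      we_dates <- we_dates[as.integer(format(we_dates, "%u")) >= 6]
      rows <- lapply(seq_len(nrow(counts)), function(i) {
        k <- counts$n[i]
        if (k == 0L) return(NULL)
        pool <- if (counts$day_type[i] == "weekday") wk_dates else we_dates
        data.frame(date = sample(pool, k), hour = counts$hour[i])
      })
      rows <- do.call(rbind, rows)
    } else {
      if (length(hourly_weights) != 24L || any(hourly_weights < 0) ||
          sum(hourly_weights) == 0) {
        stop("`hourly_weights` must be 24 non-negative weights, not all zero",
             call. = FALSE)
      }
      all_dates <- seq(as.Date("2016-04-01"), as.Date("2020-01-31"), by = 1)
      rows <- data.frame(
        date = sample(all_dates, n, replace = TRUE),
        hour = sample(0:23, n, replace = TRUE,
                      prob = hourly_weights / sum(hourly_weights)))
    }
    minute <- sample(0:59, nrow(rows), replace = TRUE)
    transfer <- pmax(20, round(stats::rnorm(nrow(rows), transfer_mean,
                                            transfer_sd)))
    ts <- as.POSIXct(sprintf("%s %02d:%02d:00", rows$date, rows$hour, minute),
                     tz = "UTC")
    ord <- order(ts)
    data.frame(timestamp = ts[ord], transfer_minutes = transfer[ord])
  })
}
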