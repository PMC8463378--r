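#' Hourly directional travel-time profile
#'
#' 24 hourly travel times (minutes) for one day type and one direction,
#' with deltas taken relative to a low-traffic baseline hour (3 a.m. by
#' default, simulating free flow and ambulance right of way).
#'
#' @param times Numeric vector of exactly 24 travel times, one per hour
#'   0--23, all `> 0`.
#' @param day_type `"weekday"` or `"weekend"`.
#' @param direction `"urban_to_suburban"` (CSC+ towards PSC, the
#'   drip-and-drive direction) or `"suburban_to_urban"` (patient towards
#'   the urban CSC, the mothership / drip-and-ship direction).
#' @param baseline_hour Baseline hour (0--23), default 3.
#' @return Object of class `traffic_profile`.
#' @export
traffic_profile <- function(times,
                            day_type = c("weekday", "weekend"),
                            direction = c("urban_to_suburban",
                                          "suburban_to_urban"),
                            baseline_hour = 3L) {
  day_type <- match.arg(day_type)
  direction <- match.arg(direction)
  if (!is.numeric(times) || length(times) != 24L || any(!is.finite(times))) {
    stop("`times` must be 24 finite hourly travel times", call. = FALSE)
  }
  if (any(times <= 0)) stop("travel times must be > 0", call. = FALSE)
  .chk_num(baseline_hour, "baseline_hour", 0, 23)
  structure(list(times = as.numeric(times), day_type = day_type,
                 direction = direction,
                 baseline_hour = as.integer(baseline_hour)),
            class = "traffic_profile")
}

#' @export
print.traffic_profile <- function(x, ...) {
  s <- summarize_profile(x)
  cat(sprintf("<traffic_profile %s %s: mean %.1f, max %g at %02d:00>\n",
              x$day_type, x$direction, s$mean, s$max, s$argmax_hour))
  invisible(x)
}

#' Baseline-relative traffic delta
#'
#' Difference between the travel time at `hour` and at the baseline hour
#' (signed minutes: positive = delay, negative = acceleration). With
#' `mode = "proportional"` the relative difference
#' `times[hour] / times[baseline] - 1` is returned instead; the default
#' absolute mode generalises the delta of the reference route to all
#' routes as a fixed number of minutes.
#'
#' @param profile A [traffic_profile()].
#' @param hour Hour of day, 0--23.
#' @param mode `"absolute"` (minutes, default) or `"proportional"`.
#' @return Signed delta (minutes, or unitless fraction).
#' @export
traffic_delta <- function(profile, hour, mode = c("absolute", "proportional")) {
  stopifnot(inherits(profile, "traffic_profile"))
  mode <- match.arg(mode)
  if (!is.numeric(hour) || any(hour != floor(hour)) ||
      any(hour < 0) || any(hour > 23)) {
    stop("`hour` must be an integer in 0..23", call. = FALSE)
  }
  at <- profile$times[hour + 1L]
  base <- profile$times[profile$baseline_hour + 1L]
  if (mode == "absolute") at - base else at / base - 1
}

# locate the profile for (day_type, direction) in a list of profiles
.find_profile <- function(profiles, day_type, direction) {
  for (p in profiles) {
    if (inherits(p, "traffic_profile") && p$day_type == day_type &&
        p$direction == direction) {
      return(p)
    }
  }
  stop(sprintf("no traffic profile for %s / %s", day_type, direction),
       call. = FALSE)
}

#' Per-paradigm traffic deltas for one hour
#'
#' Routes the directional deltas to the paradigms they delay: the
#' drip-and-drive interventionalist drives urban-to-suburban; the
#' drip-and-ship transfer and the mothership patient drive
#' suburban-to-urban (towards the urban CSC/CSC+). The mothership delta is
#' applied downstream to both CSC door times.
#'
#' @param profiles List of [traffic_profile()]s covering both directions
#'   for `day_type`.
#' @param day_type `"weekday"` or `"weekend"`.
#' @param hour Hour of day, 0--23.
#' @inheritParams traffic_delta
#' @return Named list `mothership`, `ds`, `dd` of signed deltas.
#' @export
paradigm_deltas <- function(profiles, day_type, hour,
                            mode = c("absolute", "proportional")) {
  mode <- match.arg(mode)
  us <- .find_profile(profiles, day_type, "urban_to_suburban")
  su <- .find_profile(profiles, day_type, "suburban_to_urban")
  d_su <- traffic_delta(su, hour, mode)
  list(mothership = d_su, ds = d_su, dd = traffic_delta(us, hour, mode))
}

#' Summary statistics of a traffic profile
#'
#' @param profile A [traffic_profile()].
#' @return List with `mean` (arithmetic mean over the 24 hours), `max`,
#'   `argmax_hour` (first hour attaining the maximum) and
#'   `hours_at_or_below_mean`.
#' @export
summarize_profile <- function(profile) {
  stopifnot(inherits(profile, "traffic_profile"))
  m <- mean(profile$times)
  mx <- max(profile$times)
  list(mean = m, max = mx,
       argmax_hour = which.max(profile$times) - 1L,
       hours_at_or_below_mean = which(profile$times <= m) - 1L)
}

#' Bundled reference traffic profiles
#'
#' Smooth piecewise-linear hourly profiles for the 68-km reference route
#' between the urban CSC+ and the suburban PSC, constructed to reproduce
#' the observed summaries: weekday urban-to-suburban mean 66 min with a
#' 93-min maximum at 16:00; weekday suburban-to-urban mean 65 min with
#' peaks of 90 min at 07:00 and 78 min at 16:00; weekend means of 57 min
#' in both directions with maxima of 65 and 60 min. Deltas are relative to
#' the 03:00 baseline.
#'
#' @return Named list of four [traffic_profile()]s
#'   (`weekday.urban_to_suburban`, `weekday.suburban_to_urban`,
#'   `weekend.urban_to_suburban`, `weekend.suburban_to_urban`).
#' @export
bundled_traffic_profiles <- function() {
  list(
    weekday.urban_to_suburban = traffic_profile(
      c(52, 51, 50, 50, 51, 54, 60, 64, 66, 65, 64, 66,
        74, 80, 86, 90, 93, 90, 84, 66, 62, 58, 55, 53),
      "weekday", "urban_to_suburban"),
    weekday.suburban_to_urban = traffic_profile(
      c(52, 51, 50, 50, 52, 58, 86, 90, 88, 76, 68, 66,
        66, 67, 72, 76, 78, 72, 64, 60, 57, 55, 54, 52),
      "weekday", "suburban_to_urban"),
    weekend.urban_to_suburban = traffic_profile(
      c(52, 49, 48, 48, 49, 52, 54, 56, 57, 57, 60, 64,
        65, 65, 65, 65, 64, 64, 62, 60, 56, 54, 52, 50),
      "weekend", "urban_to_suburban"),
    weekend.suburban_to_urban = traffic_profile(
      c(56, 55, 54, 53, 54, 55, 56, 56, 57, 57, 57, 60,
        60, 60, 60, 60, 60, 60, 60, 57, 56, 56, 55, 54),
      "weekend", "suburban_to_urban")
  )
}

#' Read traffic profiles from CSV
#'
#' Expects columns `day_type`, `direction`, `hour`, `minutes`; every
#' present (`day_type`, `direction`) pair must have exactly the 24 hours
#' 0--23.
#'
#' @param path CSV file path.
#' @param baseline_hour Baseline hour for all profiles.
#' @return Named list of [traffic_profile()]s.
#' @export
read_traffic_profiles <- function(path, baseline_hour = 3L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day_type", "direction", "hour", "minutes")
  if (!all(need %in% names(df))) {
    stop("traffic CSV must have columns day_type, direction, hour, minutes",
         call. = FALSE)
  }
  out <- list()
  for (dt in unique(df$day_type)) {
    for (dir in unique(df$direction[df$day_type == dt])) {
      sub <- df[df$day_type == dt & df$direction == dir, ]
      sub <- sub[order(sub$hour), ]
      if (nrow(sub) != 24L || !identical(as.integer(sub$hour), 0:23)) {
        stop(sprintf("profile %s/%s must have exactly hours 0..23", dt, dir),
             call. = FALSE)
      }
      out[[paste(dt, dir, sep = ".")]] <-
        traffic_profile(sub$minutes, dt, dir, baseline_hour)
    }
  }
  out
}

#' Write traffic profiles to CSV
#'
#' @param profiles Named list of [traffic_profile()]s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traffic_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(day_type = p$day_type, direction = p$direction,
               hour = 0:23, minutes = p$times)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
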