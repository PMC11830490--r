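#' Count valid GPS hours in one local day
#'
#' A "valid hour" is a distinct local clock hour (0-23) containing at least
#' one fix. This is the auditable reading of per-day GPS coverage used for
#' data-quality filtering.
#'
#' @param day_fixes Data frame of one local day's fixes as produced by
#'   [bucket_by_day] (column `local_hour`), or any data frame with a
#'   `timestamp` column if `timezone` is supplied.
#' @param timezone Timezone used to derive local hours when `local_hour` is
#'   absent.
#' @return Integer count in [0, 24].
#' @export
valid_hours <- function(day_fixes, timezone = NULL) {
  if (is.null(day_fixes) || nrow(day_fixes) == 0) return(0L)
  hrs <- day_fixes$local_hour
  if (is.null(hrs)) {
    if (is.null(timezone)) {
      stop("valid_hours: need `local_hour` column or a timezone")
    }
    hrs <- as.POSIXlt(day_fixes$timestamp, tz = timezone)$hour
  }
  length(unique(hrs))
}

#' Per-day validity table for a trace
#'
#' @param trace A [gps_trace].
#' @param min_valid_hours Hours-per-day threshold for a valid day (default 15,
#'   allowing for ~9 h of sleep during which no fixes may be transmitted).
#' @return Data frame with `participant_id`, `date`, `valid_hours`,
#'   `is_valid_day`, one row per local date present in the trace.
#' @export
day_validity <- function(trace, min_valid_hours = 15) {
  days <- bucket_by_day(trace)
  vh <- vapply(days, valid_hours, integer(1))
  data.frame(
    participant_id = trace$participant_id,
    date = as.Date(names(days)),
    valid_hours = as.integer(vh),
    is_valid_day = vh >= min_valid_hours,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Retain days meeting the valid-hours threshold
#'
#' @param days Data frame with a `valid_hours` column (e.g. daily features or
#'   a [day_validity] table).
#' @param min_valid_hours Threshold (inclusive); default 15 h/day.
#' @return The rows with `valid_hours >= min_valid_hours`, order preserved.
#' @export
filter_valid_days <- function(days, min_valid_hours = 15) {
  days[days$valid_hours >= min_valid_hours, , drop = FALSE]
}

#' Extrapolate a valid day's features to 24 hours
#'
#' Days that pass the valid-hours filter are linearly extrapolated to a full
#' 24-hour day: additive time/distance features (`total_distance_km`,
#' `time_home_min`, `transition_time_min`) are scaled by `24 / valid_hours`;
#' the significant-location count is a count, not an additive duration, and is
#' left unscaled. Scaled durations are capped at 1440 min.
#'
#' @param features Data frame of daily features (see [extract_daily_features]).
#' @param valid_hours Integer vector of valid hours per row; defaults to the
#'   `valid_hours` column.
#' @param scale_counts If TRUE, also scale `n_significant_locations`
#'   (off by default; provided as a config switch since the original
#'   protocol does not state which features were scaled).
#' @return `features` with scaled columns.
#' @export
extrapolate_to_24h <- function(features, valid_hours = features$valid_hours,
                               scale_counts = FALSE) {
  if (any(valid_hours < 1)) {
    stop("extrapolate_to_24h: valid_hours must be >= 1 (apply the day filter first)")
  }
  s <- 24 / valid_hours
  features$total_distance_km <- features$total_distance_km * s
  features$time_home_min <- pmin(features$time_home_min * s, 1440)
  features$transition_time_min <- pmin(features$transition_time_min * s, 1440)
  if (scale_counts) {
    features$n_significant_locations <- features$n_significant_locations * s
  }
  features
}

#' Monday-start week containing a date
#'
#' @param date A Date vector.
#' @return Date vector of the Monday starting each date's ISO week.
#' @export
iso_week_start <- function(date) {
  date - (as.POSIXlt(date)$wday + 6L) %% 7L
}

#' Retain weeks with enough valid days
#'
#' Applied after the day-level filter: calendar (Monday-start) weeks with
#' fewer than `min_valid_days` valid days are excluded entirely.
#'
#' @param daily Data frame of day-filtered daily rows with `participant_id`
#'   and `date` columns.
#' @param min_valid_days Minimum valid days per week (inclusive); default 3.
#' @return The rows belonging to retained participant-weeks, order preserved,
#'   with a `week_start` column added.
#' @export
filter_valid_weeks <- function(daily, min_valid_days = 3) {
  if (nrow(daily) == 0) {
    daily$week_start <- as.Date(character(0))
    return(daily)
  }
  daily$week_start <- iso_week_start(daily$date)
  key <- paste(daily$participant_id, daily$week_start)
  n_days <- table(key)
  daily[n_days[key] >= min_valid_days, , drop = FALSE]
}

#' Apply the full data-quality filter to daily features
#'
#' Day filter (valid hours), 24-h extrapolation, then week filter (valid days
#' per Monday-start week).
#'
#' @param daily Data frame of daily features with `valid_hours`.
#' @param min_valid_hours Valid-day threshold (default 15 h).
#' @param min_valid_days_per_week Valid-week threshold (default 3 days).
#' @param extrapolate Scale additive features to 24 h (default TRUE).
#' @return Filtered (and optionally extrapolated) daily feature rows with a
#'   `week_start` column.
#' @export
filter_quality <- function(daily, min_valid_hours = 15,
                           min_valid_days_per_week = 3, extrapolate = TRUE) {
  out <- filter_valid_days(daily, min_valid_hours)
  if (extrapolate && nrow(out) > 0) out <- extrapolate_to_24h(out)
  filter_valid_weeks(out, min_valid_days_per_week)
}
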