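FEATURE_COLS <- c("total_distance_km", "time_home_min",
                  "transition_time_min", "n_significant_locations")

#' Home disc radius in meters for a given home area
#'
#' The home is modelled as a circular area of `area_sqft` square feet around
#' the estimated house coordinates; the default 2000 sq ft gives a radius of
#' about 7.69 m. The disc is closed: a fix exactly at the radius is inside.
#'
#' @param area_sqft Home area in square feet.
#' @return Radius in meters.
#' @export
home_radius_m <- function(area_sqft = 2000) {
  sqrt(area_sqft * 0.09290304 / pi)
}

#' Consecutive-fix gap table for one day
#'
#' Internal workhorse: for each consecutive fix pair computes the time gap,
#' haversine distance and finite-difference speed. Gaps longer than
#' `max_gap_s` (default 300 s) or with zero duration are marked unusable and
#' contribute to no state or dwell accounting; each usable gap's duration is
#' attributed to the state/location of its starting fix.
#'
#' @param day_fixes Data frame of fixes sorted by time (columns `timestamp`,
#'   `latitude`, `longitude`, optionally `local_hour`).
#' @param max_gap_s Longest usable inter-fix gap, seconds.
#' @return Data frame with one row per gap: `dt_s`, `dist_m`, `speed_mps`,
#'   `usable`, `start_lat`, `start_lon`, `start_hour`.
#' @keywords internal
gap_table <- function(day_fixes, max_gap_s = 300) {
  n <- nrow(day_fixes)
  if (n < 2) {
    return(data.frame(dt_s = numeric(0), dist_m = numeric(0),
                      speed_mps = numeric(0), usable = logical(0),
                      start_lat = numeric(0), start_lon = numeric(0),
                      start_hour = integer(0)))
  }
  t <- as.numeric(day_fixes$timestamp)
  dt <- diff(t)
  d <- haversine_m(day_fixes$latitude[-n], day_fixes$longitude[-n],
                   day_fixes$latitude[-1], day_fixes$longitude[-1])
  usable <- dt > 0 & dt <= max_gap_s
  speed <- ifelse(dt > 0, d / dt, NA_real_)
  hrs <- day_fixes$local_hour
  data.frame(
    dt_s = dt, dist_m = d, speed_mps = speed, usable = usable,
    start_lat = day_fixes$latitude[-n], start_lon = day_fixes$longitude[-n],
    start_hour = if (is.null(hrs)) NA_integer_ else hrs[-n]
  )
}

#' Total distance travelled in one day
#'
#' Sum of haversine great-circle distances over consecutive fix pairs,
#' in kilometers. Fewer than two fixes give 0 km.
#'
#' @param day_fixes Sorted fixes for one local day.
#' @return Distance in km.
#' @export
total_distance_km <- function(day_fixes) {
  n <- nrow(day_fixes)
  if (n < 2) return(0)
  sum(haversine_m(day_fixes$latitude[-n], day_fixes$longitude[-n],
                  day_fixes$latitude[-1], day_fixes$longitude[-1])) / 1000
}

#' Finite-difference speeds between consecutive fixes
#'
#' The time derivative of position: for each consecutive pair, haversine
#' distance divided by the time gap. Gaps with zero duration are skipped
#' (NA speed); gaps longer than `max_gap_s` are flagged unusable and excluded
#' from state-time accounting downstream.
#'
#' @inheritParams gap_table
#' @return Data frame with `speed_mps` (m/s), `dt_s` and `usable` per gap.
#' @export
point_speeds <- function(day_fixes, max_gap_s = 300) {
  gap_table(day_fixes, max_gap_s)[, c("speed_mps", "dt_s", "usable")]
}

#' Daily transition time
#'
#' Time spent in the transitional state: the sum of usable gap durations whose
#' speed strictly exceeds the threshold (default 1 m/s). A gap at exactly the
#' threshold is stationary (movement must strictly exceed the threshold).
#'
#' @inheritParams gap_table
#' @param speed_threshold_mps Transitional/stationary cut, m/s.
#' @return Minutes of transition time.
#' @export
transition_time_min <- function(day_fixes, speed_threshold_mps = 1,
                                max_gap_s = 300) {
  g <- gap_table(day_fixes, max_gap_s)
  sum(g$dt_s[g$usable & g$speed_mps > speed_threshold_mps]) / 60
}

#' Daily time spent at home
#'
#' Total duration of usable gaps whose starting fix lies within the home disc
#' (closed; radius from [home_radius_m], default area 2000 sq ft, ~7.69 m).
#'
#' @inheritParams gap_table
#' @param home_center Numeric `c(lat, lon)` of the home cluster center, or
#'   NULL/NA when no home was identified (returns NA).
#' @param home_area_sqft Home disc area in square feet.
#' @return Minutes at home, or NA if no home is defined.
#' @export
time_at_home_min <- function(day_fixes, home_center, home_area_sqft = 2000,
                             max_gap_s = 300) {
  if (is.null(home_center) || anyNA(home_center)) return(NA_real_)
  g <- gap_table(day_fixes, max_gap_s)
  if (nrow(g) == 0) return(0)
  r <- home_radius_m(home_area_sqft)
  at_home <- haversine_m(g$start_lat, g$start_lon,
                         home_center[1], home_center[2]) <= r
  sum(g$dt_s[g$usable & at_home]) / 60
}

#' Number of significant locations visited in one day
#'
#' Counts the distinct participant-level clusters that receive at least one
#' stationary fix during the day. A fix is stationary when the usable gap it
#' starts has speed at or below the threshold. A day with only transitional
#' fixes visits 0 locations.
#'
#' @inheritParams gap_table
#' @param clusters A [location_clusters] object fitted on the participant's
#'   stationary points.
#' @param speed_threshold_mps Transitional/stationary cut, m/s.
#' @return Integer count of distinct clusters visited.
#' @export
n_significant_locations_day <- function(day_fixes, clusters,
                                        speed_threshold_mps = 1,
                                        max_gap_s = 300) {
  if (is.null(clusters) || clusters$k == 0) return(0L)
  g <- gap_table(day_fixes, max_gap_s)
  st <- g[g$usable & g$speed_mps <= speed_threshold_mps, , drop = FALSE]
  if (nrow(st) == 0) return(0L)
  idx <- assign_to_clusters(st$start_lat, st$start_lon, clusters)
  length(unique(idx))
}

#' Extract the four daily mobility features for one participant
#'
#' Runs the per-day feature extraction over all local days of a trace:
#' total distance (haversine sum), transition time (time at finite-difference
#' speed > 1 m/s), time at home (dwell within the 2000 sq ft home disc), and
#' number of significant locations visited (distinct fitted clusters with a
#' stationary fix). Clusters are fitted once per participant over all
#' stationary points of the study window (see [fit_significant_locations]);
#' per-day visit counts are then derived from the fitted model.
#'
#' @param trace A [gps_trace].
#' @param clusters Optional pre-fitted [location_clusters]; fitted from the
#'   trace when NULL.
#' @param k_max Maximum number of clusters for the elbow search.
#' @param speed_threshold_mps Transitional/stationary speed cut (m/s).
#' @param home_area_sqft Home disc area (sq ft).
#' @param max_gap_s Longest usable inter-fix gap (s).
#' @param seed Seed for the clustering initialisation.
#' @return Data frame with one row per local day: `participant_id`, `date`,
#'   the four features and `valid_hours`; the fitted cluster set is attached
#'   as attribute `"clusters"`.
#' @export
extract_daily_features <- function(trace, clusters = NULL, k_max = 10,
                                   speed_threshold_mps = 1,
                                   home_area_sqft = 2000, max_gap_s = 300,
                                   seed = 1L) {
  days <- bucket_by_day(trace)
  if (is.null(clusters)) {
    clusters <- fit_significant_locations(
      trace, k_max = k_max, speed_threshold_mps = speed_threshold_mps,
      max_gap_s = max_gap_s, seed = seed)
  }
  home <- if (!is.null(clusters$home_index) && !is.na(clusters$home_index)) {
    unlist(clusters$clusters[[clusters$home_index]][c("lat", "lon")])
  }
  rows <- lapply(days, function(df) {
    data.frame(
      participant_id = trace$participant_id,
      date = df$local_date[1],
      total_distance_km = total_distance_km(df),
      time_home_min = time_at_home_min(df, home, home_area_sqft, max_gap_s),
      transition_time_min = transition_time_min(df, speed_threshold_mps,
                                                max_gap_s),
      n_significant_locations = n_significant_locations_day(
        df, clusters, speed_threshold_mps, max_gap_s),
      valid_hours = valid_hours(df),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "clusters") <- clusters
  out
}

#' Weekly mean and SD of daily features
#'
#' Arithmetic mean and sample SD per feature over the (already validity
#' filtered) days of each participant's Monday-start week.
#'
#' @param daily Data frame of daily features (post quality filter).
#' @return Data frame with `participant_id`, `week_start`, `n_days` and
#'   `<feature>_mean` / `<feature>_sd` columns.
#' @export
weekly_mean_sd <- function(daily) {
  if (is.null(daily$week_start)) daily$week_start <- iso_week_start(daily$date)
  keys <- unique(daily[, c("participant_id", "week_start")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- daily[daily$participant_id == keys$participant_id[i] &
                   daily$week_start == keys$week_start[i], , drop = FALSE]
    row <- data.frame(participant_id = keys$participant_id[i],
                      week_start = keys$week_start[i], n_days = nrow(sub),
                      stringsAsFactors = FALSE)
    for (f in FEATURE_COLS) {
      row[[paste0(f, "_mean")]] <- mean(sub[[f]])
      row[[paste0(f, "_sd")]] <- stats::sd(sub[[f]])
    }
    row
  })
  out <- do.call(rbind, rows)
  out[order(out$participant_id, out$week_start), , drop = FALSE]
}
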