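#' Construct a GPS trace object
#'
#' A `gps_trace` holds the time-ordered GPS fixes of one participant together
#' with the IANA timezone used for local-day bucketing. Fixes are sorted
#' ascending by timestamp; duplicate timestamps are collapsed to the first
#' occurrence; rows with out-of-range or missing coordinates are dropped and
#' counted in the load report attached as attribute `"load_report"`.
#'
#' @param participant_id Participant identifier (opaque string; 8-character
#'   IDs as produced by passive-sensing platforms are typical but not
#'   enforced).
#' @param timestamp POSIXct vector (UTC) or numeric epoch milliseconds.
#' @param latitude,longitude Decimal degrees.
#' @param accuracy Optional reported accuracy in meters; carried through but
#'   not used by any feature (no accuracy gating is applied).
#' @param timezone IANA zone name used to bucket fixes into local calendar
#'   days.
#' @return An object of class `gps_trace`: a list with `participant_id`,
#'   `timezone` and a data frame `fixes` with columns `timestamp`, `latitude`,
#'   `longitude` and (if supplied) `accuracy`.
#' @export
gps_trace <- function(participant_id, timestamp, latitude, longitude,
                      accuracy = NULL, timezone = "UTC") {
  if (is.numeric(timestamp)) {
    timestamp <- as.POSIXct(timestamp / 1000, origin = "1970-01-01", tz = "UTC")
  }
  attr(timestamp, "tzone") <- "UTC"
  n_in <- length(timestamp)
  latitude <- as.numeric(latitude)
  longitude <- as.numeric(longitude)

  bad_ts <- is.na(timestamp)
  bad_coord <- is.na(latitude) | is.na(longitude) |
    latitude < -90 | latitude > 90 | longitude < -180 | longitude > 180
  keep <- !bad_ts & !bad_coord

  fixes <- data.frame(
    timestamp = timestamp[keep],
    latitude = latitude[keep],
    longitude = longitude[keep]
  )
  if (!is.null(accuracy)) fixes$accuracy <- as.numeric(accuracy)[keep]

  ord <- order(fixes$timestamp)
  fixes <- fixes[ord, , drop = FALSE]
  dup <- duplicated(fixes$timestamp)
  fixes <- fixes[!dup, , drop = FALSE]
  rownames(fixes) <- NULL

  trace <- structure(
    list(participant_id = as.character(participant_id),
         timezone = timezone, fixes = fixes),
    class = "gps_trace"
  )
  attr(trace, "load_report") <- list(
    rows_read = n_in,
    rows_kept = nrow(fixes),
    dropped = list(
      bad_timestamp = sum(bad_ts),
      bad_coordinates = sum(bad_coord & !bad_ts),
      duplicate_timestamp = sum(dup)
    )
  )
  trace
}

#' @export
print.gps_trace <- function(x, ...) {
  n <- nrow(x$fixes)
  cat("GPS trace for participant", x$participant_id, "\n")
  cat(sprintf("  %d fixes, timezone %s\n", n, x$timezone))
  if (n > 0) {
    cat(sprintf("  span: %s to %s (UTC)\n",
                format(min(x$fixes$timestamp)), format(max(x$fixes$timestamp))))
  }
  invisible(x)
}

parse_gps_timestamps <- function(x) {
  if (is.numeric(x)) {
    return(as.POSIXct(x / 1000, origin = "1970-01-01", tz = "UTC"))
  }
  x <- trimws(as.character(x))
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num[nzchar(x)])) {
    return(as.POSIXct(num / 1000, origin = "1970-01-01", tz = "UTC"))
  }
  iso <- sub("Z$", "", sub("T", " ", x))
  out <- as.POSIXct(iso, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

#' Read a GPS trace CSV
#'
#' Reads a long-format per-participant GPS export (comma-separated, header
#' required, UTF-8) with columns `timestamp` (epoch milliseconds or ISO-8601),
#' `latitude`, `longitude`, and optionally `accuracy`. Rows with unparseable
#' timestamps or out-of-range coordinates are dropped and counted in the load
#' report (attribute `"load_report"` of the result).
#'
#' @param path Path to the CSV file.
#' @param timezone IANA timezone for local-day bucketing.
#' @param participant_id Participant ID; defaults to a `participant_id` column
#'   if present, else the file name without extension.
#' @return A [gps_trace] object, sorted and de-duplicated.
#' @export
read_gps_csv <- function(path, timezone = "UTC", participant_id = NULL) {
  if (!file.exists(path)) stop("GPS file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("timestamp", "latitude", "longitude")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("GPS CSV ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) stop("GPS CSV ", path, " contains no fixes (empty trace)")
  if (is.null(participant_id)) {
    participant_id <- if ("participant_id" %in% names(df)) {
      as.character(df$participant_id[1])
    } else {
      sub("\\.[^.]*$", "", basename(path))
    }
  }
  ts <- parse_gps_timestamps(df$timestamp)
  gps_trace(participant_id, ts,
            suppressWarnings(as.numeric(df$latitude)),
            suppressWarnings(as.numeric(df$longitude)),
            accuracy = if ("accuracy" %in% names(df)) {
              suppressWarnings(as.numeric(df$accuracy))
            },
            timezone = timezone)
}

#' Write a GPS trace to CSV in the canonical dialect
#'
#' The canonical dialect is byte-stable under read/write round trips:
#' epoch-millisecond integer timestamps, coordinates with eight decimals
#' (~1 mm), comma-separated with a header.
#'
#' @param trace A [gps_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gps_csv <- function(trace, path) {
  stopifnot(inherits(trace, "gps_trace"))
  f <- trace$fixes
  out <- data.frame(
    participant_id = trace$participant_id,
    timestamp = sprintf("%.0f", as.numeric(f$timestamp) * 1000),
    latitude = sprintf("%.8f", f$latitude),
    longitude = sprintf("%.8f", f$longitude)
  )
  if (!is.null(f$accuracy)) out$accuracy <- sprintf("%.2f", f$accuracy)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a load report as JSON
#'
#' @param trace A [gps_trace] (its `"load_report"` attribute is serialised),
#'   or a list of traces.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_load_report <- function(trace, path) {
  reports <- if (inherits(trace, "gps_trace")) list(trace) else trace
  out <- lapply(reports, function(tr) attr(tr, "load_report"))
  names(out) <- vapply(reports, function(tr) tr$participant_id, character(1))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a quality-of-life assessment CSV
#'
#' Expects columns `participant_id`, `date` (ISO), `ph_t`, `mh_t`: the
#' physical-health and mental-health T-scores of a patient-reported global
#' health instrument (population mean 50, SD 10). Empty score cells become
#' missing values; scores outside the plausible T-score range [10, 90] raise
#' a warning, not an error. Instrument scoring itself is out of scope:
#' T-scores are consumed as given.
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `participant_id` (character), `date`
#'   (Date), `ph_t`, `mh_t` (numeric, possibly NA).
#' @export
read_qol_csv <- function(path) {
  if (!file.exists(path)) stop("QOL file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("participant_id", "date", "ph_t", "mh_t")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("QOL CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  parse_score <- function(x, col) {
    x <- trimws(x)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(nzchar(x) & is.na(out))
    if (length(bad) > 0) {
      stop("QOL CSV: non-numeric ", col, " in row(s) ",
           paste(bad, collapse = ", "))
    }
    out
  }
  res <- data.frame(
    participant_id = as.character(df$participant_id),
    date = as.Date(df$date),
    ph_t = parse_score(df$ph_t, "ph_t"),
    mh_t = parse_score(df$mh_t, "mh_t"),
    stringsAsFactors = FALSE
  )
  if (anyNA(res$date)) {
    stop("QOL CSV: unparseable date in row(s) ",
         paste(which(is.na(res$date)), collapse = ", "))
  }
  key <- paste(res$participant_id, res$date)
  if (anyDuplicated(key)) {
    stop("QOL CSV: duplicate (participant, date) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  scores <- c(res$ph_t, res$mh_t)
  if (any(!is.na(scores) & (scores < 10 | scores > 90))) {
    warning("QOL CSV: T-score(s) outside the plausible range [10, 90]")
  }
  res
}

#' Bucket a trace's fixes into local calendar days
#'
#' Each fix is assigned to exactly one local date under the trace's timezone,
#' using the half-open day convention [00:00, 24:00): a fix at exactly local
#' midnight belongs to the starting date of the new day.
#'
#' @param trace A [gps_trace] with at least one fix.
#' @return A named list of fix data frames, one per local date (names are ISO
#'   dates, ascending); each element also carries the local clock hour of its
#'   fixes in column `local_hour` and the local date in `local_date`.
#' @export
bucket_by_day <- function(trace) {
  stopifnot(inherits(trace, "gps_trace"))
  f <- trace$fixes
  if (nrow(f) == 0) stop("bucket_by_day: empty trace")
  lt <- as.POSIXlt(f$timestamp, tz = trace$timezone)
  f$local_date <- as.Date(lt)
  f$local_hour <- lt$hour
  split(f, format(f$local_date))
}

#' Flag low quality-of-life scores
#'
#' Applies the conventional low-score cut-offs for global health T-scores:
#' physical health below 42 and mental health below 40 indicate poor health.
#' Both inequalities are strict; a score exactly at the cut-off is not
#' flagged. Missing scores yield NA flags (tri-state).
#'
#' @param ph_t,mh_t Numeric T-score vectors (recycled).
#' @return A data frame with logical columns `low_ph` and `low_mh`.
#' @export
flag_low_qol <- function(ph_t, mh_t) {
  data.frame(low_ph = ph_t < 42, low_mh = mh_t < 40)
}
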