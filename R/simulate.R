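#' Synthetic-cohort configuration
#'
#' Default study conditions for the synthetic mobility cohort: 11 participants
#' observed for 16 weeks (GPS) with quality-of-life assessments at weeks 0, 6
#' and 12, home-anchored daily routines with trips to a small set of recurring
#' significant locations, hour-level missingness, and optional linear coupling
#' of QOL T-scores to true weekly mobility features at configurable week-lags.
#'
#' @param n_participants Number of participants (default 11).
#' @param n_weeks GPS observation length in weeks (default 16).
#' @param fixes_per_hour Regular sampling rate (default 12, one fix per 5 min;
#'   a fix is additionally emitted at every dwell/transit boundary).
#' @param n_locations Significant locations per participant including home
#'   (default 5).
#' @param trips_per_day_lambda Poisson mean of trips per day (default 2,
#'   capped at 3 so trips fit the 08:00-21:00 window).
#' @param trips_per_day_min Lower bound on scheduled trips per day (default 0;
#'   set to 1 to guarantee nonzero daily travel, e.g. for relative-error
#'   ground-truth comparisons that are ill-defined at zero distance).
#' @param trip_speed_mps Constant transit speed (default 13 m/s, ~47 km/h:
#'   car travel in a spread-out region).
#' @param dwell_min_mean,dwell_min_sd Out-of-home dwell duration per trip,
#'   minutes (default 90 +/- 30, floored at 20).
#' @param loc_dist_km Range of home-to-location distances (default 5-25 km,
#'   giving daily totals in the 10s-100s of km reported for car-dependent
#'   cohorts).
#' @param bias_sd_m Per-dwell GPS bias SD per axis (default 1.5 m).
#' @param noise_sd_m Per-fix GPS noise SD per axis (default 0.1 m; kept small
#'   because summed pairwise distance accumulates independent noise linearly
#'   in the number of fixes).
#' @param day_bad_prob Probability a day suffers heavy dropout (default 0.15).
#' @param hour_drop_prob Hour-dropout probability on ordinary days
#'   (default 0.08).
#' @param bad_hour_drop_prob Hour-dropout probability on heavy-dropout days
#'   (default 0.6, typically leaving fewer than 15 valid hours).
#' @param qol_weeks Assessment weeks relative to GPS start (default 0, 6, 12).
#' @param coupling NULL, or a data frame with columns `feature`, `qol_dim`,
#'   `lag_weeks`, `target_r` planting within-participant correlations.
#' @param intercept_sd Between-participant QOL intercept SD (default 5
#'   T-score points).
#' @param qol_noise_sd Within-participant QOL noise SD (default 5).
#' @param origin `c(lat, lon)` of the reference city grid
#'   (default 33.5 N, -86.8 W).
#' @param start_date First GPS day (default 2023-01-02, a Monday).
#' @param timezone Timezone of the simulated phones.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 11, n_weeks = 16,
                          fixes_per_hour = 12, n_locations = 5,
                          trips_per_day_lambda = 2, trips_per_day_min = 0,
                          trip_speed_mps = 13,
                          dwell_min_mean = 90, dwell_min_sd = 30,
                          loc_dist_km = c(5, 25), bias_sd_m = 1.5,
                          noise_sd_m = 0.1, day_bad_prob = 0.15,
                          hour_drop_prob = 0.08, bad_hour_drop_prob = 0.6,
                          qol_weeks = c(0, 6, 12), coupling = NULL,
                          intercept_sd = 5, qol_noise_sd = 5,
                          origin = c(33.5, -86.8),
                          start_date = as.Date("2023-01-02"),
                          timezone = "UTC") {
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# Build one participant's geography: home plus (n_locations - 1) recurring
# destinations at 5-25 km, random bearings, on the local planar grid.
make_geography <- function(cfg, participant_index) {
  home <- c(lat = cfg$origin[1] + 0.05 * ((participant_index - 1) %% 4),
            lon = cfg$origin[2] + 0.05 * ((participant_index - 1) %/% 4))
  n_other <- cfg$n_locations - 1
  d <- stats::runif(n_other, cfg$loc_dist_km[1], cfg$loc_dist_km[2]) * 1000
  th <- stats::runif(n_other, 0, 2 * pi)
  xy <- cbind(d * cos(th), d * sin(th))
  ll <- local_unproject(xy, home[1], home[2])
  list(home = home,
       locations = ll,
       dist_m = haversine_m(home[1], home[2], ll[, 1], ll[, 2]))
}

# One day's dwell/transit schedule. Segments partition [0, 86400) seconds.
# Trips are placed sequentially in the 08:00-21:00 window; trips that no
# longer fit are dropped (the realised count is what ground truth records).
make_day_schedule <- function(geo, cfg) {
  n_trips <- min(max(stats::rpois(1, cfg$trips_per_day_lambda),
                     cfg$trips_per_day_min), 3L)
  segs <- list()
  cursor <- 0
  dist_m <- 0
  transit_s <- 0
  visited <- integer(0)
  day_end <- 86400
  t_next <- 8 * 3600 + stats::runif(1, 0, 3600)
  n_other <- nrow(geo$locations)
  for (i in seq_len(n_trips)) {
    if (n_other == 0) break
    dest <- sample.int(n_other, 1)
    travel <- geo$dist_m[dest] / cfg$trip_speed_mps
    dwell <- max(20, stats::rnorm(1, cfg$dwell_min_mean, cfg$dwell_min_sd)) * 60
    if (t_next + 2 * travel + dwell > 21 * 3600) break
    segs[[length(segs) + 1]] <- list(type = "home", t0 = cursor, t1 = t_next)
    segs[[length(segs) + 1]] <- list(type = "transit", t0 = t_next,
                                     t1 = t_next + travel,
                                     from = "home", to = dest)
    segs[[length(segs) + 1]] <- list(type = "loc", t0 = t_next + travel,
                                     t1 = t_next + travel + dwell, loc = dest)
    segs[[length(segs) + 1]] <- list(type = "transit",
                                     t0 = t_next + travel + dwell,
                                     t1 = t_next + 2 * travel + dwell,
                                     from = dest, to = "home")
    cursor <- t_next + 2 * travel + dwell
    dist_m <- dist_m + 2 * geo$dist_m[dest]
    transit_s <- transit_s + 2 * travel
    visited <- union(visited, dest)
    t_next <- cursor + stats::runif(1, 30, 120) * 60
  }
  segs[[length(segs) + 1]] <- list(type = "home", t0 = cursor, t1 = day_end)
  away_s <- sum(vapply(segs, function(s) {
    if (s$type == "home") 0 else s$t1 - s$t0
  }, numeric(1)))
  list(segments = segs,
       truth = data.frame(
         total_distance_km = dist_m / 1000,
         time_home_min = (86400 - away_s) / 60,
         transition_time_min = transit_s / 60,
         n_locations_visited = 1L + length(visited)))
}

# Sample fixes from a schedule: the regular grid plus a fix at every segment
# boundary, so each inter-fix gap lies within one dwell or transit segment
# and the analytic ground truth is recoverable from the trace.
sample_day_fixes <- function(segs, geo, cfg, day_offset_s) {
  step <- 3600 / cfg$fixes_per_hour
  bounds <- unlist(lapply(segs, function(s) c(s$t0, s$t1)))
  times <- sort(unique(c(seq(0, 86400 - step, by = step), bounds)))
  times <- times[times < 86400]
  seg_idx <- findInterval(times, vapply(segs, `[[`, numeric(1), "t0"))
  lat <- numeric(length(times))
  lon <- numeric(length(times))
  loc_coord <- function(key) {
    if (identical(key, "home")) geo$home else geo$locations[key, ]
  }
  bias <- matrix(stats::rnorm(2 * length(segs), 0, cfg$bias_sd_m),
                 ncol = 2)
  for (j in unique(seg_idx)) {
    s <- segs[[j]]
    sel <- seg_idx == j
    if (s$type == "transit") {
      a <- loc_coord(s$from); b <- loc_coord(s$to)
      frac <- (times[sel] - s$t0) / (s$t1 - s$t0)
      lat[sel] <- a[1] + frac * (b[1] - a[1])
      lon[sel] <- a[2] + frac * (b[2] - a[2])
    } else {
      anchor <- if (s$type == "home") geo$home else geo$locations[s$loc, ]
      off <- local_unproject(matrix(bias[j, ], 1), anchor[1], anchor[2])
      lat[sel] <- off[1, 1]
      lon[sel] <- off[1, 2]
    }
  }
  noise <- matrix(stats::rnorm(2 * length(times), 0, cfg$noise_sd_m), ncol = 2)
  rad <- pi / 180; r_earth <- 6371008.8
  lat <- lat + noise[, 2] / (rad * r_earth)
  lon <- lon + noise[, 1] / (rad * r_earth * cos(geo$home[1] * rad))
  data.frame(t_s = day_offset_s + times, latitude = lat, longitude = lon)
}

#' Simulate one participant's GPS trace with analytic ground truth
#'
#' Each simulated day is a sequence of dwells at home and recurring
#' significant locations connected by constant-speed transits; fixes are
#' sampled on a regular grid plus the segment boundaries. Stationary scatter
#' is a per-dwell GPS bias (default 1.5 m/axis) plus per-fix noise
#' (default 0.5 m/axis), so the schedule-derived daily features are
#' recoverable from the trace. Ground truth is recorded analytically from the
#' schedule before any sampling or missingness.
#'
#' @param cfg A [cohort_config].
#' @param participant_index Index used for the participant's home placement
#'   and ID.
#' @param seed Integer seed; the trace is reproducible given (cfg, index,
#'   seed).
#' @return List with `trace` (a [gps_trace]), `truth` (data frame of true
#'   daily features) and `geography` (home and location coordinates).
#' @export
simulate_trace <- function(cfg, participant_index = 1, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_seed(old_seed))

  pid <- sprintf("sim%05d", participant_index)
  geo <- make_geography(cfg, participant_index)
  n_days <- cfg$n_weeks * 7
  dates <- cfg$start_date + seq_len(n_days) - 1
  truth <- vector("list", n_days)
  fixes <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    sched <- make_day_schedule(geo, cfg)
    truth[[d]] <- cbind(participant_id = pid,
                        data.frame(date = dates[d]), sched$truth)
    fixes[[d]] <- sample_day_fixes(sched$segments, geo, cfg,
                                   (d - 1) * 86400)
  }
  fx <- do.call(rbind, fixes)
  ts <- as.POSIXct(as.numeric(as.POSIXct(paste(cfg$start_date, "00:00:00"),
                                         tz = cfg$timezone)) + fx$t_s,
                   origin = "1970-01-01", tz = "UTC")
  trace <- gps_trace(pid, ts, fx$latitude, fx$longitude,
                     timezone = cfg$timezone)
  list(trace = trace, truth = do.call(rbind, truth), geography = geo)
}

#' Apply hour-level missingness to a trace
#'
#' Emulates phone-off / battery-depletion dropout: each day is either
#' ordinary (each clock hour independently dropped with `hour_drop_prob`) or
#' a heavy-dropout day (probability `day_bad_prob`, hours dropped with
#' `bad_hour_drop_prob`, typically leaving fewer than 15 valid hours). The
#' realised number of retained hours per day is attached as attribute
#' `"expected_validity"` so filter tests have known answers.
#'
#' @param trace A [gps_trace].
#' @param cfg A [cohort_config] holding the dropout probabilities.
#' @param seed Integer seed.
#' @return The censored [gps_trace].
#' @export
apply_missingness <- function(trace, cfg, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_seed(old_seed))

  lt <- as.POSIXlt(trace$fixes$timestamp, tz = trace$timezone)
  day <- format(as.Date(lt))
  hour <- lt$hour
  days <- sort(unique(day))
  keep <- rep(TRUE, nrow(trace$fixes))
  kept_hours <- integer(length(days))
  for (i in seq_along(days)) {
    p <- if (stats::runif(1) < cfg$day_bad_prob) cfg$bad_hour_drop_prob else
      cfg$hour_drop_prob
    drop_hour <- stats::runif(24) < p
    sel <- day == days[i]
    keep[sel] <- !drop_hour[hour[sel] + 1]
    kept_hours[i] <- length(unique(hour[sel][keep[sel]]))
  }
  out <- trace
  out$fixes <- trace$fixes[keep, , drop = FALSE]
  rownames(out$fixes) <- NULL
  attr(out, "load_report") <- attr(trace, "load_report")
  attr(out, "expected_validity") <- data.frame(
    participant_id = trace$participant_id,
    date = as.Date(days), valid_hours = kept_hours,
    stringsAsFactors = FALSE)
  out
}

#' Simulate QOL assessments coupled to true weekly mobility
#'
#' QOL T-scores are generated from a linear Gaussian model:
#' `qol = 50 + participant intercept + sum(beta * z) + noise`, where `z` is
#' the participant-standardised true weekly feature at the coupled lag week
#' and `beta = target_r / sqrt(1 - target_r^2) * noise_sd`, which induces the
#' target within-participant correlation asymptotically.
#'
#' @param truth True daily features as returned by [simulate_trace] (stacked
#'   over participants).
#' @param cfg A [cohort_config]; `cfg$coupling` is NULL or a data frame with
#'   `feature`, `qol_dim`, `lag_weeks`, `target_r`.
#' @param seed Integer seed.
#' @return Data frame `participant_id`, `date`, `ph_t`, `mh_t`, with the
#'   pre-noise latent values attached as attribute `"latent"`.
#' @export
simulate_qol <- function(truth, cfg, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_seed(old_seed))

  pids <- unique(truth$participant_id)
  qol_dates <- cfg$start_date + 7 * cfg$qol_weeks
  grid <- expand.grid(participant_id = pids, date = qol_dates,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$participant_id, grid$date), ]
  intercepts <- stats::rnorm(length(pids), 0, cfg$intercept_sd)
  names(intercepts) <- pids

  lagged_weekly_truth <- function(pid, qdate, feature, lag) {
    w0 <- qdate + 7 * lag
    sel <- truth$participant_id == pid & truth$date >= w0 &
      truth$date <= w0 + 6
    if (!any(sel)) {
      stop("simulate_qol: coupling references week lag ", lag,
           " outside the simulated window for ", pid)
    }
    mean(truth[[feature]][sel])
  }

  latent <- matrix(50, nrow(grid), 2, dimnames = list(NULL, c("ph", "mh")))
  latent <- latent + intercepts[grid$participant_id]
  cpl <- cfg$coupling
  if (!is.null(cpl) && nrow(cpl) > 0) {
    scale <- if (cfg$qol_noise_sd > 0) cfg$qol_noise_sd else 1
    for (j in seq_len(nrow(cpl))) {
      beta <- cpl$target_r[j] / sqrt(1 - cpl$target_r[j]^2) * scale
      # center each participant's coupled weekly values on their own mean,
      # but scale by the POOLED within-participant SD: a common slope across
      # participants is what makes the induced within-participant correlation
      # equal the target for the pooled repeated-measures estimator
      wc <- numeric(nrow(grid))
      for (pid in pids) {
        rows <- which(grid$participant_id == pid)
        w <- vapply(grid$date[rows], lagged_weekly_truth, numeric(1),
                    pid = pid, feature = cpl$feature[j],
                    lag = cpl$lag_weeks[j])
        wc[rows] <- w - mean(w)
      }
      pooled_sd <- sqrt(sum(wc^2) / max(1, nrow(grid) - length(pids)))
      z <- if (pooled_sd == 0) wc else wc / pooled_sd
      latent[, cpl$qol_dim[j]] <- latent[, cpl$qol_dim[j]] + beta * z
    }
  }
  noise <- matrix(stats::rnorm(2 * nrow(grid), 0, cfg$qol_noise_sd),
                  ncol = 2)
  out <- data.frame(
    participant_id = grid$participant_id, date = grid$date,
    ph_t = latent[, "ph"] + noise[, 1],
    mh_t = latent[, "mh"] + noise[, 2],
    stringsAsFactors = FALSE)
  attr(out, "latent") <- latent
  out
}

#' Simulate a full synthetic cohort
#'
#' Generates per-participant GPS traces (with missingness), true daily
#' features and coupled QOL assessments; optionally writes them to disk as
#' per-participant GPS CSVs, a QOL CSV and a ground-truth JSON.
#'
#' @param cfg A [cohort_config].
#' @param seed Master integer seed; all randomness derives from it.
#' @param dir Optional output directory; created if needed.
#' @param missingness Apply the hour-dropout model (default TRUE).
#' @return List with `traces` (list of [gps_trace]), `truth` (stacked daily
#'   ground truth), `qol` (assessment table) and, when written, `paths`.
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1L, dir = NULL,
                            missingness = TRUE) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  pseeds <- sample.int(2^30, cfg$n_participants * 2 + 1)
  restore_seed(old_seed)

  traces <- vector("list", cfg$n_participants)
  truths <- vector("list", cfg$n_participants)
  for (i in seq_len(cfg$n_participants)) {
    sim <- simulate_trace(cfg, i, seed = pseeds[2 * i - 1])
    tr <- sim$trace
    if (missingness) tr <- apply_missingness(tr, cfg, seed = pseeds[2 * i])
    traces[[i]] <- tr
    truths[[i]] <- sim$truth
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL
  qol <- simulate_qol(truth, cfg, seed = pseeds[length(pseeds)])

  out <- list(traces = traces, truth = truth, qol = qol)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gps_paths <- vapply(traces, function(tr) {
      p <- file.path(dir, paste0("gps_", tr$participant_id, ".csv"))
      write_gps_csv(tr, p)
      p
    }, character(1))
    qol_path <- file.path(dir, "qol.csv")
    utils::write.csv(qol, qol_path, row.names = FALSE, quote = FALSE)
    truth_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, truth_path, dataframe = "columns",
                         digits = NA)
    out$paths <- list(gps = gps_paths, qol = qol_path, truth = truth_path)
  }
  out
}

#' Simulate weekly features and coupled QOL directly (no GPS layer)
#'
#' Lightweight generator for correlation-level simulations: weekly feature
#' values are drawn i.i.d. across weeks around participant-specific means, and
#' QOL is coupled to the feature at a planted lag exactly as in
#' [simulate_qol]. Returned as a ready-made daily table (each week's value
#' repeated over its 7 days, all days valid) so it feeds [lag_rmcorr]
#' directly.
#'
#' @param n_participants,n_weeks Cohort size (defaults 11 participants,
#'   16 weeks).
#' @param qol_weeks Assessment weeks (default 0, 6, 12).
#' @param coupling NULL or data frame `feature`, `qol_dim`, `lag_weeks`,
#'   `target_r`.
#' @param intercept_sd,qol_noise_sd QOL model parameters (defaults 5, 5).
#' @param seed Integer seed.
#' @return List with `daily` (valid daily features), `assessments`, and
#'   `weekly` (the underlying weekly truth).
#' @export
simulate_weekly_features <- function(n_participants = 11, n_weeks = 16,
                                     qol_weeks = c(0, 6, 12), coupling = NULL,
                                     intercept_sd = 5, qol_noise_sd = 5,
                                     seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_seed(old_seed))

  start_date <- as.Date("2023-01-02")  # a Monday
  mu <- c(total_distance_km = 120, time_home_min = 500,
          transition_time_min = 100, n_significant_locations = 4.5)
  sig_b <- c(40, 120, 30, 0.8)  # between participants
  sig_w <- c(35, 100, 25, 0.7)  # week to week
  pids <- sprintf("sim%05d", seq_len(n_participants))
  weekly <- expand.grid(participant_id = pids,
                        week = seq_len(n_weeks) - 1L,
                        stringsAsFactors = FALSE)
  weekly <- weekly[order(weekly$participant_id, weekly$week), ]
  rownames(weekly) <- NULL
  for (i in seq_along(FEATURE_COLS)) {
    b <- stats::rnorm(n_participants, 0, sig_b[i])
    names(b) <- pids
    weekly[[FEATURE_COLS[i]]] <- pmax(
      0, mu[i] + b[weekly$participant_id] +
        stats::rnorm(nrow(weekly), 0, sig_w[i]))
  }
  weekly$week_start <- start_date + 7 * weekly$week

  daily <- weekly[rep(seq_len(nrow(weekly)), each = 7), ]
  daily$date <- daily$week_start + rep(0:6, nrow(weekly))
  daily$valid_hours <- 24L
  daily$week_start <- NULL
  daily$week <- NULL
  rownames(daily) <- NULL

  # truth table in the layout simulate_qol expects (daily rows)
  truth <- daily
  cfg <- cohort_config(n_participants = n_participants, n_weeks = n_weeks,
                       qol_weeks = qol_weeks, coupling = coupling,
                       intercept_sd = intercept_sd,
                       qol_noise_sd = qol_noise_sd, start_date = start_date)
  assessments <- simulate_qol(truth, cfg,
                              seed = (seed + 104729L) %% .Machine$integer.max)
  list(daily = daily, assessments = assessments, weekly = weekly)
}
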