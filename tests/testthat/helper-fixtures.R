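# Fixture builders and independent oracles shared across the suite.

# Trace from hour offsets (in hours since `day0` midnight UTC) and coordinates.
make_trace <- function(hours, lat, lon, pid = "p1", tz = "UTC",
                       day0 = as.Date("2023-01-02")) {
  t0 <- as.POSIXct(paste(day0, "00:00:00"), tz = tz)
  gps_trace(pid, as.numeric(t0) * 1000 + hours * 3600 * 1000,
            lat, lon, timezone = tz)
}

# Meters per degree of latitude on the reference sphere.
m_per_deg <- 6371008.8 * pi / 180

# Independent great-circle oracle: spherical law of cosines.
slc_distance_m <- function(lat1, lon1, lat2, lon2, radius_m = 6371008.8) {
  rad <- pi / 180
  ca <- sin(lat1 * rad) * sin(lat2 * rad) +
    cos(lat1 * rad) * cos(lat2 * rad) * cos((lon2 - lon1) * rad)
  radius_m * acos(pmin(1, pmax(-1, ca)))
}

# Independent repeated-measures correlation oracle: ANCOVA with participant
# dummies; r recovered from the slope t statistic, signed by the slope.
ancova_rmcorr <- function(x, y, id) {
  fit <- stats::lm(y ~ x + factor(id))
  s <- summary(fit)$coefficients
  tv <- s["x", "t value"]
  unname(sign(stats::coef(fit)["x"]) * sqrt(tv^2 / (tv^2 + fit$df.residual)))
}

# Planted Gaussian clusters on the local plane around a reference point,
# returned as lat/lon. Centers drawn uniformly with a minimum separation.
planted_clusters <- function(k, n_per = 200, sigma_m = 30, min_sep_m = 2000,
                             box_m = 8000) {
  repeat {
    ctr <- cbind(stats::runif(k, -box_m, box_m),
                 stats::runif(k, -box_m, box_m))
    if (k == 1 || min(stats::dist(ctr)) >= min_sep_m) break
  }
  xy <- do.call(rbind, lapply(seq_len(k), function(j) {
    cbind(stats::rnorm(n_per, ctr[j, 1], sigma_m),
          stats::rnorm(n_per, ctr[j, 2], sigma_m))
  }))
  ll <- gpsmobility:::local_unproject(xy, 33.5, -86.8)
  list(lat = ll[, 1], lon = ll[, 2],
       label = rep(seq_len(k), each = n_per), centers_xy = ctr)
}

# Daily-features data frame builder for filter tests.
make_daily <- function(pid, dates, valid_hours,
                       dist = 10, home = 600, tt = 60, nloc = 3) {
  data.frame(participant_id = pid, date = as.Date(dates),
             total_distance_km = dist, time_home_min = home,
             transition_time_min = tt, n_significant_locations = nloc,
             valid_hours = valid_hours, stringsAsFactors = FALSE)
}
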