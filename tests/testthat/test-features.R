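test_that("haversine_m matches independent great-circle oracles", {
  # one degree of longitude at the equator, against the law-of-cosines oracle
  expect_equal(haversine_m(0, 0, 0, 1), slc_distance_m(0, 0, 0, 1),
               tolerance = 1e-9)
  expect_equal(haversine_m(0, 0, 0, 1) / 1000, 111.195, tolerance = 1e-4)
  expect_equal(haversine_m(10, 10, 10, 10), 0)

  set.seed(1)
  lat1 <- runif(500, -80, 80); lon1 <- runif(500, -180, 180)
  lat2 <- runif(500, -80, 80); lon2 <- runif(500, -180, 180)
  h <- haversine_m(lat1, lon1, lat2, lon2)
  o <- slc_distance_m(lat1, lon1, lat2, lon2)
  expect_lt(max(abs(h - o) / pmax(o, 1)), 1e-6)
  expect_equal(h, haversine_m(lat2, lon2, lat1, lon1))  # symmetry

  g <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                r = 6371008.8)
  expect_equal(h, g, tolerance = 1e-9)
})

test_that("total_distance_km sums consecutive haversine legs", {
  expect_equal(total_distance_km(data.frame(timestamp = 1, latitude = 33,
                                            longitude = -86)), 0)
  # collinear equator fixes: additivity along a great circle
  tr <- make_trace(c(0, 1, 2), c(0, 0, 0), c(0, 0.5, 1))
  day <- bucket_by_day(tr)[[1]]
  expect_equal(total_distance_km(day), haversine_m(0, 0, 0, 1) / 1000,
               tolerance = 1e-12)
})

test_that("point_speeds computes finite-difference speeds and flags long gaps", {
  # two fixes 30 m apart (N-S), 10 s apart -> 3 m/s
  dlat <- 30 / m_per_deg
  tr <- make_trace(c(0, 10 / 3600), c(33.5, 33.5 + dlat), c(-86.8, -86.8))
  sp <- point_speeds(bucket_by_day(tr)[[1]])
  expect_equal(sp$speed_mps, 3, tolerance = 1e-6)
  expect_true(sp$usable)

  # identical consecutive positions -> 0 m/s; 400 s gap -> unusable
  tr2 <- make_trace(c(0, 100 / 3600, 500 / 3600), rep(33.5, 3), rep(-86.8, 3))
  sp2 <- point_speeds(bucket_by_day(tr2)[[1]])
  expect_equal(sp2$speed_mps, c(0, 0))
  expect_equal(sp2$usable, c(TRUE, FALSE))
})

test_that("transition time uses strict speed > 1 m/s on usable gaps only", {
  # 60 min of 3 m/s gaps
  n <- 13
  dlat3 <- 3 * 300 / m_per_deg  # 3 m/s over 300 s
  tr <- make_trace(seq(0, 1, length.out = n), 33.5 + dlat3 * (0:(n - 1)),
                   rep(-86.8, n))
  expect_equal(transition_time_min(bucket_by_day(tr)[[1]]), 60,
               tolerance = 1e-6)

  # all stationary
  tr0 <- make_trace(seq(0, 1, length.out = n), rep(33.5, n), rep(-86.8, n))
  expect_equal(transition_time_min(bucket_by_day(tr0)[[1]]), 0)

  # the speed comparison is strict: a gap exactly at the threshold is
  # stationary, a hair below the threshold makes the same gap transit
  dlat1 <- 600 / m_per_deg  # ~1 m/s over 10 min
  tr1 <- make_trace(c(0, 1 / 6), c(33.5, 33.5 + dlat1), c(-86.8, -86.8),
                    day0 = as.Date("2023-01-02"))
  g <- gpsmobility:::gap_table(bucket_by_day(tr1)[[1]], max_gap_s = 601)
  expect_equal(g$speed_mps, 1, tolerance = 1e-9)
  expect_equal(transition_time_min(bucket_by_day(tr1)[[1]],
                                   speed_threshold_mps = g$speed_mps,
                                   max_gap_s = 601), 0)
  expect_equal(transition_time_min(bucket_by_day(tr1)[[1]],
                                   speed_threshold_mps = g$speed_mps - 1e-9,
                                   max_gap_s = 601), 10)
})

test_that("transition + stationary time conserve total usable gap time", {
  sim <- simulate_trace(cohort_config(n_weeks = 1), 2, seed = 21)
  for (day in bucket_by_day(sim$trace)[1:3]) {
    g <- gpsmobility:::gap_table(day)
    tot <- sum(g$dt_s[g$usable]) / 60
    tt <- transition_time_min(day)
    stat <- sum(g$dt_s[g$usable & g$speed_mps <= 1]) / 60
    expect_equal(tt + stat, tot, tolerance = 1e-9)
  }
})

test_that("time_at_home_min uses a closed 2000 sq ft disc", {
  expect_equal(home_radius_m(2000), sqrt(2000 * 0.09290304 / pi))
  r <- home_radius_m(2000)
  expect_equal(r, 7.69, tolerance = 1e-2)

  home <- c(33.5, -86.8)
  # every 5-min gap of the day starts at home; the last fix is 23:55, so
  # 1435 gap minutes lie within the local day
  hrs <- seq(0, 24, by = 1 / 12)
  tr <- make_trace(hrs, rep(home[1], length(hrs)), rep(home[2], length(hrs)))
  day <- bucket_by_day(tr)[[1]]
  expect_equal(time_at_home_min(day, home), 1435)

  # all fixes 100 m away -> 0 min
  far <- 100 / m_per_deg
  tr2 <- make_trace(hrs, rep(home[1] + far, length(hrs)),
                    rep(home[2], length(hrs)))
  expect_equal(time_at_home_min(bucket_by_day(tr2)[[1]], home), 0)

  # the boundary sits at the disc radius: a fix 1 micrometer inside counts,
  # 1 micrometer outside does not
  just_in <- (r - 1e-6) / m_per_deg
  tr3 <- make_trace(c(0, 1 / 12), rep(home[1] + just_in, 2), rep(home[2], 2))
  expect_equal(time_at_home_min(bucket_by_day(tr3)[[1]], home), 5)
  just_out <- (r + 1e-6) / m_per_deg
  tr4 <- make_trace(c(0, 1 / 12), rep(home[1] + just_out, 2), rep(home[2], 2))
  expect_equal(time_at_home_min(bucket_by_day(tr4)[[1]], home), 0)
  expect_true(is.na(time_at_home_min(day, NULL)))
})

test_that("weekly_mean_sd averages valid days per participant-week", {
  mon <- as.Date("2023-01-02")
  d <- make_daily("p1", mon + 0:1, 24, dist = c(100, 200))
  w <- weekly_mean_sd(d)
  expect_equal(w$total_distance_km_mean, 150)
  expect_equal(w$total_distance_km_sd, sd(c(100, 200)))

  d2 <- make_daily("p1", mon + 0:2, 24, dist = 5)
  expect_equal(weekly_mean_sd(d2)$total_distance_km_sd, 0)
})
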