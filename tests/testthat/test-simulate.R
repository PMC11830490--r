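test_that("simulate_trace ground truth matches the schedule bookkeeping", {
  cfg <- cohort_config(n_weeks = 1)
  sim <- simulate_trace(cfg, 1, seed = 4)
  tr <- sim$truth
  expect_equal(nrow(tr), 7)
  expect_true(all(tr$total_distance_km >= 0))
  expect_true(all(tr$time_home_min + tr$transition_time_min <= 1440 + 1e-9))
  expect_true(all(tr$n_locations_visited >= 1 &
                    tr$n_locations_visited <= cfg$n_locations))
  # a day with zero trips stays home all day with zero distance
  z <- tr$total_distance_km == 0
  if (any(z)) {
    expect_true(all(tr$time_home_min[z] == 1440))
    expect_true(all(tr$n_locations_visited[z] == 1))
  }
  # distance and transit time are consistent through the constant trip speed
  expect_equal(tr$total_distance_km * 1000,
               tr$transition_time_min * 60 * cfg$trip_speed_mps,
               tolerance = 1e-9)
  # reproducibility
  sim2 <- simulate_trace(cfg, 1, seed = 4)
  expect_identical(sim$trace$fixes, sim2$trace$fixes)
  expect_identical(sim$truth, sim2$truth)
})

test_that("extracted features recover the analytic ground truth on dense days", {
  cfg <- cohort_config(n_weeks = 2, fixes_per_hour = 60, day_bad_prob = 0,
                       trips_per_day_min = 1)
  sim <- simulate_trace(cfg, 3, seed = 8)
  feats <- extract_daily_features(sim$trace, seed = 8)
  m <- merge(feats, sim$truth, by = c("participant_id", "date"))
  expect_equal(nrow(m), 14)
  expect_lt(max(abs(m$total_distance_km.x - m$total_distance_km.y) /
                  m$total_distance_km.y), 0.05)
  expect_lt(max(abs(m$time_home_min.x - m$time_home_min.y) /
                  m$time_home_min.y), 0.05)
  expect_lt(max(abs(m$transition_time_min.x - m$transition_time_min.y) /
                  m$transition_time_min.y), 0.05)
  expect_true(all(m$n_significant_locations == m$n_locations_visited))
})

test_that("apply_missingness censors whole clock hours reproducibly", {
  cfg <- cohort_config(n_weeks = 1)
  sim <- simulate_trace(cfg, 1, seed = 6)
  cens1 <- apply_missingness(sim$trace, cfg, seed = 2)
  cens2 <- apply_missingness(sim$trace, cfg, seed = 2)
  expect_identical(cens1$fixes, cens2$fixes)
  expect_lte(nrow(cens1$fixes), nrow(sim$trace$fixes))

  # no dropout leaves the trace untouched
  cfg0 <- cohort_config(day_bad_prob = 0, hour_drop_prob = 0)
  cens0 <- apply_missingness(sim$trace, cfg0, seed = 2)
  expect_identical(cens0$fixes, sim$trace$fixes)
  expect_true(all(attr(cens0, "expected_validity")$valid_hours == 24))

  # a dropped hour removes every fix in that hour, never part of one
  ev <- attr(cens1, "expected_validity")
  dv <- day_validity(cens1)
  expect_equal(dv$valid_hours, ev$valid_hours)
})

test_that("simulate_qol follows the linear model exactly when noise is off", {
  cfg <- cohort_config(n_weeks = 2, qol_weeks = c(0, 1), qol_noise_sd = 0,
                       coupling = NULL)
  sim <- simulate_trace(cfg, 1, seed = 3)
  qol <- simulate_qol(sim$truth, cfg, seed = 9)
  # no coupling, no noise: scores are 50 + the participant intercept
  expect_equal(length(unique(round(qol$ph_t, 10))), 1)
  expect_equal(qol$ph_t, qol$mh_t)

  # coupling a week outside the simulated window is an error, not silence
  cfg_bad <- cohort_config(n_weeks = 2, qol_weeks = 0, coupling = data.frame(
    feature = "total_distance_km", qol_dim = "ph", lag_weeks = -3L,
    target_r = 0.5))
  expect_error(simulate_qol(sim$truth, cfg_bad, seed = 9), "outside")
})

test_that("planted coupling induces the target correlation, sign included", {
  run <- function(target_r, seed) {
    coupling <- data.frame(feature = "total_distance_km", qol_dim = "ph",
                           lag_weeks = -1L, target_r = target_r,
                           stringsAsFactors = FALSE)
    sim <- simulate_weekly_features(
      n_participants = 120, n_weeks = 12, qol_weeks = c(2, 4, 6, 8, 10),
      coupling = coupling, seed = seed)
    obs <- assemble_lagged(sim$daily, sim$assessments, "total_distance_km",
                           "ph")
    sub <- obs[obs$lag_weeks == -1, ]
    as.numeric(rm_correlation(sub$feature_value, sub$qol_value,
                              sub$participant_id))
  }
  r_pos <- run(0.5, 13)
  r_neg <- run(-0.5, 13)
  expect_lt(abs(r_pos - 0.5), 0.08)
  expect_lt(abs(r_neg + 0.5), 0.08)

  # near-deterministic coupling saturates the correlation
  expect_gt(run(0.99, 21), 0.95)
})

test_that("simulate_cohort is seed-deterministic and writes readable files", {
  cfg <- cohort_config(n_participants = 2, n_weeks = 1)
  a <- simulate_cohort(cfg, seed = 31)
  b <- simulate_cohort(cfg, seed = 31)
  expect_identical(a$truth, b$truth)
  expect_identical(a$qol, b$qol)
  expect_identical(a$traces[[1]]$fixes, b$traces[[1]]$fixes)
  c <- simulate_cohort(cfg, seed = 32)
  expect_false(identical(a$qol$ph_t, c$qol$ph_t))

  dir <- withr::local_tempdir()
  w <- simulate_cohort(cfg, seed = 31, dir = dir)
  expect_identical(w$truth, a$truth)
  tr <- read_gps_csv(w$paths$gps[1], timezone = cfg$timezone)
  expect_equal(nrow(tr$fixes), nrow(w$traces[[1]]$fixes))
  qol <- read_qol_csv(w$paths$qol)
  expect_equal(qol$ph_t, w$qol$ph_t, tolerance = 1e-12)
})
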