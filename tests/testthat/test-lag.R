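test_that("lag_weeks is the signed floor of the day difference over 7", {
  q <- as.Date("2023-02-13")
  expect_equal(lag_weeks(q, q), 0L)
  expect_equal(lag_weeks(q + 6, q), 0L)
  expect_equal(lag_weeks(q + 7, q), 1L)
  expect_equal(lag_weeks(q - 1, q), -1L)
  expect_equal(lag_weeks(q - 7, q), -1L)
  expect_equal(lag_weeks(q - 8, q), -2L)
  # 15-21 days before the assessment is lag -3
  expect_equal(lag_weeks(q - c(15, 21), q), c(-3L, -3L))
  expect_equal(lag_weeks(q - c(14, 22), q), c(-2L, -4L))
})

test_that("assemble_lagged builds one observation per participant-assessment-lag", {
  mon <- as.Date("2023-01-02")
  daily <- rbind(make_daily("a", mon + 0:13, 24, dist = c(1:7, 8:14)),
                 make_daily("b", mon + 0:13, 24, dist = 21:34))
  qol <- data.frame(participant_id = c("a", "b"), date = mon + 7,
                    ph_t = c(55, 45), mh_t = c(NA, 50),
                    stringsAsFactors = FALSE)
  obs <- assemble_lagged(daily, qol, "total_distance_km", "ph")
  expect_equal(nrow(obs), 4)  # 2 participants x lags {-1, 0}
  expect_equal(sort(unique(obs$lag_weeks)), c(-1L, 0L))
  a_m1 <- obs[obs$participant_id == "a" & obs$lag_weeks == -1, ]
  expect_equal(a_m1$feature_value, mean(1:7))
  expect_equal(a_m1$qol_value, 55)
  a_0 <- obs[obs$participant_id == "a" & obs$lag_weeks == 0, ]
  expect_equal(a_0$feature_value, mean(8:14))

  # an NA QOL value contributes no observations for that dimension
  obs_mh <- assemble_lagged(daily, qol, "total_distance_km", "mh")
  expect_equal(unique(obs_mh$participant_id), "b")

  # 12 participants x 3 assessments, full overlap -> 36 observations per lag
  pids <- sprintf("p%02d", 1:12)
  big_daily <- do.call(rbind, lapply(pids, function(p) {
    make_daily(p, mon + 0:27, 24)
  }))
  big_qol <- expand.grid(participant_id = pids, date = mon + c(7, 14, 21),
                         stringsAsFactors = FALSE)
  big_qol$ph_t <- 50; big_qol$mh_t <- 50
  big <- assemble_lagged(big_daily, big_qol, "total_distance_km", "ph")
  expect_equal(sum(big$lag_weeks == 0), 36)
  expect_equal(nrow(assemble_lagged(daily[0, ], qol, "total_distance_km",
                                    "ph")), 0)
})

test_that("filter_lags drops lags at exactly min_obs and keeps min_obs + 1", {
  obs <- data.frame(participant_id = "x",
                    qol_date = as.Date("2023-01-02"),
                    lag_weeks = rep(c(-1L, 0L, 1L), c(10, 11, 3)),
                    feature_value = 1, qol_value = 1)
  kept <- filter_lags(obs, min_obs = 10)
  expect_equal(attr(kept, "retained_lags"), 0L)   # 11 > 10 retained
  expect_equal(unique(kept$lag_weeks), 0L)        # 10 and 3 dropped
  expect_equal(nrow(filter_lags(obs, min_obs = 0)), 24)
})

test_that("lag_rmcorr recovers a planted medium correlation at the right lag", {
  coupling <- data.frame(feature = "total_distance_km", qol_dim = "ph",
                         lag_weeks = -3L, target_r = 0.5,
                         stringsAsFactors = FALSE)
  sim <- simulate_weekly_features(
    n_participants = 30, n_weeks = 30, qol_weeks = c(3, 9, 15, 21, 27),
    coupling = coupling, seed = 42)
  fit <- lag_rmcorr(sim$daily, sim$assessments, "ph",
                    features = "total_distance_km", n_boot = 0,
                    lag_range = c(-3, 3))
  tab <- fit$table
  planted <- tab$r[tab$lag_weeks == -3]
  expect_gt(planted, 0.3)
  expect_equal(tab$lag_weeks[which.max(abs(tab$r))], -3L)
  # all rows well-populated
  expect_true(all(tab$n_obs > 10))
  expect_true(all(tab$n_participants == 30))
})

test_that("lag_rmcorr methods expose the fit coherently", {
  coupling <- data.frame(feature = "time_home_min", qol_dim = "mh",
                         lag_weeks = 0L, target_r = -0.5,
                         stringsAsFactors = FALSE)
  sim <- simulate_weekly_features(n_participants = 12, n_weeks = 10,
                                  qol_weeks = c(2, 5, 8),
                                  coupling = coupling, seed = 5)
  fit <- lag_rmcorr(sim$daily, sim$assessments, "mh", n_boot = 200,
                    seed = 11, lag_range = c(-2, 1))
  tab <- fit$table
  expect_s3_class(fit, "lag_rmcorr")
  expect_identical(as.data.frame(fit), tab)
  expect_false(is.unsorted(tab$lag_weeks))
  # CI brackets r wherever both are defined
  ok <- !is.na(tab$r) & !is.na(tab$ci_low)
  expect_true(all(tab$ci_low[ok] <= tab$r[ok] & tab$r[ok] <= tab$ci_high[ok]))
  expect_equal(tab$effect_label, label_effect(tab$r))

  cm <- coef(fit)
  expect_equal(colnames(cm), FEATURE_COLS)
  expect_equal(cm["0", "time_home_min"],
               tab$r[tab$lag_weeks == 0 & tab$feature == "time_home_min"])

  expect_output(print(fit), "MH T-score")
  expect_output(summary(fit), "peak r")

  # identical seeds give identical tables; lag_table is the same table
  fit2 <- lag_rmcorr(sim$daily, sim$assessments, "mh", n_boot = 200,
                     seed = 11, lag_range = c(-2, 1))
  expect_identical(tab, fit2$table)
  expect_identical(lag_table(sim$daily, sim$assessments, "mh", n_boot = 0,
                             lag_range = c(-2, 1))$r,
                   lag_rmcorr(sim$daily, sim$assessments, "mh", n_boot = 0,
                              lag_range = c(-2, 1))$table$r)

  p <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(p)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(p))
})

test_that("lag_rmcorr returns an empty, well-formed table when nothing passes", {
  sim <- simulate_weekly_features(n_participants = 3, n_weeks = 4,
                                  qol_weeks = 1, seed = 2)
  fit <- lag_rmcorr(sim$daily, sim$assessments, "ph",
                    min_obs_per_lag = 1e6, n_boot = 0)
  expect_equal(nrow(fit$table), 0)
  expect_output(print(fit), "no lag met")
  expect_output(summary(fit), "no retained lags")
})
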