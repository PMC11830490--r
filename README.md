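# gpsmobility

Digital-phenotyping analysis of passively collected smartphone GPS traces:
daily mobility feature extraction, data-quality filtering, and time-lagged
repeated-measures correlation against sparse patient-reported quality-of-life
(QOL) scores — with a synthetic cohort generator whose ground truth is known
analytically, so the whole pipeline can be validated without access to any
real location data.

## The scientific problem

In cohorts with a high symptom burden (the motivating setting is advanced
cancer patients and their family caregivers), passively sensed mobility may
track self-reported quality of life, possibly at a temporal offset: mobility
this week may correlate with a PROMIS Global-10 physical-health (PH) or
mental-health (MH) T-score reported weeks later or earlier. The package
estimates, per mobility feature and per signed week-lag, the common
within-participant association between weekly mobility and the T-score.

Four daily features are extracted from raw GPS fixes:

| feature | definition |
|---|---|
| total distance (km) | sum of haversine great-circle distances between consecutive fixes |
| transition time (min) | usable inter-fix gaps (≤ 5 min) with speed strictly > 1 m/s |
| time at home (min) | usable gaps starting inside the closed 2000 sq ft home disc (radius ≈ 7.69 m) |
| significant locations | distinct fitted location clusters receiving ≥ 1 stationary fix that day |

Significant locations come from k-means (k-means++ seeding, 10 restarts)
on the trace's stationary points, with k chosen by the elbow (kneedle chord)
criterion on the log-WSS curve; the home cluster is the night-dominant
(00:00–06:00 dwell) cluster among the top 3 by total dwell. Days need ≥ 15
valid hours (a valid hour contains ≥ 1 fix) and are extrapolated to 24 h by
`24 / valid_hours` scaling (durations capped at 1440 min, counts unscaled);
weeks need ≥ 3 valid days.

The estimator is the repeated-measures correlation: centre the
assessment-anchored weekly feature mean and the T-score on each
participant's means, take the Pearson correlation of the centred values
(df = n_obs − n_participants − 1), for every lag with strictly more than 10
observations. Confidence intervals are percentile cluster bootstrap
(participants resampled with replacement, 1000 resamples by default). A
correlation with zero within-participant variance is reported as missing,
never as 0.

## Worked example

Simulate a small cohort, extract and filter features, and fit the
lag-correlation model:

```r
library(gpsmobility)

cfg <- cohort_config(n_participants = 6, n_weeks = 12, qol_weeks = c(0, 4, 8))
cohort <- simulate_cohort(cfg, seed = 42)
print(cohort$traces[[1]])
#> GPS trace for participant sim00001
#>   20688 fixes, timezone UTC
#>   span: 2023-01-02 to 2023-03-26 23:55:00 (UTC)

daily <- do.call(rbind, lapply(cohort$traces, extract_daily_features,
                               seed = 42))
filtered <- filter_quality(daily)

fit <- lag_rmcorr(filtered, cohort$qol, qol_dim = "ph", n_boot = 500,
                  lag_range = c(-4, 3), seed = 42)
summary(fit)
#> Repeated-measures lag correlations, PH T-score
#>   lags -4 to 3; n_obs 12-18; participants up to 6
#>   total_distance_km        peak r = +0.38 (medium) at lag -4 [-0.54, 0.96]; 0/8 lag CI(s) exclude 0
#>   time_home_min            peak r = +0.25 (small) at lag -1 [-0.51, 0.68]; 0/8 lag CI(s) exclude 0
#>   transition_time_min      peak r = -0.41 (medium) at lag +0 [-0.75, 0.06]; 1/8 lag CI(s) exclude 0
#>   n_significant_locations  peak r = -0.31 (medium) at lag -2 [-0.85, 0.42]; 0/8 lag CI(s) exclude 0

round(coef(fit)[1:4, 1:2], 2)
#>    total_distance_km time_home_min
#> -4              0.38         -0.22
#> -3             -0.11         -0.02
#> -2             -0.04         -0.19
#> -1             -0.34          0.25
```

(With 6 synthetic participants and no planted effect these correlations are
noise, as the intervals show; `plot(fit)` draws the per-feature lag curves
with CI ribbons.)

The one-call pipeline ingests real CSVs (`gps_files`, `qol_csv`) or
simulates, and writes all tables, plots and a reproducibility manifest:

```r
res <- run_pipeline(pipeline_config(output_dir = "out", seed = 1))
```

Reruns with the same configuration and seed are byte-identical.

Reading real data: `read_gps_csv()` expects columns `timestamp` (epoch ms or
ISO-8601), `latitude`, `longitude`, optional `accuracy`; `read_qol_csv()`
expects `participant_id`, `date`, `ph_t`, `mh_t`.

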