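#' Default pipeline configuration
#'
#' A single configuration list governs all stages of [run_pipeline]. It can be
#' written to / read from YAML for reproducible reruns; the run manifest
#' written alongside the outputs contains the full configuration, the package
#' version and the seed, and suffices to reproduce the run exactly.
#'
#' @param gps_files Character vector of GPS CSV paths (one per participant);
#'   NULL when `simulate = TRUE`.
#' @param qol_csv Path to the QOL CSV; NULL when simulating.
#' @param timezone IANA timezone for day bucketing.
#' @param output_dir Where outputs are written.
#' @param simulate Generate the default synthetic cohort instead of reading
#'   inputs.
#' @param min_valid_hours,min_valid_days_per_week,extrapolate Quality-filter
#'   settings.
#' @param k_max,speed_threshold_mps,home_area_sqft,max_gap_s Feature-extraction
#'   settings.
#' @param min_obs_per_lag,n_boot,ci_level,lag_range Lag-correlation settings.
#' @param cohort A [cohort_config] used when `simulate = TRUE` (default: the
#'   standard synthetic cohort).
#' @param seed Master seed for simulation, clustering and bootstrap.
#' @return A configuration list.
#' @export
pipeline_config <- function(gps_files = NULL, qol_csv = NULL,
                            timezone = "UTC", output_dir = "gpsmobility_out",
                            simulate = is.null(gps_files), cohort = NULL,
                            min_valid_hours = 15,
                            min_valid_days_per_week = 3, extrapolate = TRUE,
                            k_max = 10, speed_threshold_mps = 1,
                            home_area_sqft = 2000, max_gap_s = 300,
                            min_obs_per_lag = 10, n_boot = 1000,
                            ci_level = 0.95, lag_range = NULL, seed = 1L) {
  as.list(environment())
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file take the [pipeline_config] defaults.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  cfg[names(user)] <- user
  if (!is.null(cfg$lag_range)) cfg$lag_range <- as.numeric(cfg$lag_range)
  if (!is.null(cfg$cohort) && !inherits(cfg$cohort, "cohort_config")) {
    cfg$cohort <- do.call(cohort_config, cfg$cohort)
  }
  cfg
}

open_plot_device <- function(path_base, width = 9, height = 7) {
  png_path <- paste0(path_base, ".png")
  ok <- tryCatch({
    grDevices::png(png_path, width = width, height = height, units = "in",
                   res = 120)
    TRUE
  }, error = function(e) FALSE)
  if (ok) return(png_path)
  pdf_path <- paste0(path_base, ".pdf")
  grDevices::pdf(pdf_path, width = width, height = height)
  pdf_path
}

#' Run the full pipeline
#'
#' Ingest (or simulate) GPS traces and QOL assessments, apply the data-quality
#' filter, extract daily mobility features, aggregate, and estimate lagged
#' repeated-measures correlations for both QOL dimensions. Writes to
#' `config$output_dir`: `daily_features.csv`, `validity_report.csv`,
#' `cluster_report.csv`, `lag_table_ph.csv`, `lag_table_mh.csv`,
#' `weekly_summary.txt`, lag-correlation plots, `load_report.json` and
#' `manifest.json`. Reruns with the same configuration and seed produce
#' byte-identical tables.
#'
#' @param config A list from [pipeline_config] or [read_pipeline_config].
#' @return Invisibly, a list with the daily features, filtered daily table,
#'   both [lag_rmcorr] fits, the weekly summary and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", what, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (isTRUE(config$simulate)) {
    ccfg <- if (is.null(config$cohort)) cohort_config() else config$cohort
    sim <- stage("simulate", simulate_cohort(ccfg, seed = config$seed))
    traces <- sim$traces
    assessments <- sim$qol
  } else {
    traces <- stage("ingest", lapply(config$gps_files, read_gps_csv,
                                     timezone = config$timezone))
    assessments <- stage("ingest", read_qol_csv(config$qol_csv))
  }

  validity <- stage("quality", do.call(rbind, lapply(
    traces, day_validity, min_valid_hours = config$min_valid_hours)))

  daily_list <- vector("list", length(traces))
  clusters <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    pid <- traces[[i]]$participant_id
    daily_list[[i]] <- stage(
      paste0("features/", pid),
      extract_daily_features(
        traces[[i]], k_max = config$k_max,
        speed_threshold_mps = config$speed_threshold_mps,
        home_area_sqft = config$home_area_sqft,
        max_gap_s = config$max_gap_s, seed = config$seed + i))
    clusters[[i]] <- cluster_report(attr(daily_list[[i]], "clusters"), pid)
  }
  daily <- do.call(rbind, daily_list)
  rownames(daily) <- NULL

  filtered <- stage("quality", filter_quality(
    daily, min_valid_hours = config$min_valid_hours,
    min_valid_days_per_week = config$min_valid_days_per_week,
    extrapolate = config$extrapolate))
  message(sprintf(
    "quality filter: %d/%d days valid, %d day(s) in retained weeks",
    sum(daily$valid_hours >= config$min_valid_hours), nrow(daily),
    nrow(filtered)))

  fits <- lapply(c(ph = "ph", mh = "mh"), function(dim) {
    stage(paste0("correlate/", dim), lag_rmcorr(
      filtered, assessments, qol_dim = dim,
      min_obs_per_lag = config$min_obs_per_lag, n_boot = config$n_boot,
      ci_level = config$ci_level, seed = config$seed,
      lag_range = config$lag_range))
  })

  summary_txt <- stage("report", summarize_features(filtered))

  out_dir <- config$output_dir
  num <- function(df) {
    for (cl in names(df)) if (is.numeric(df[[cl]])) {
      df[[cl]] <- format(df[[cl]], digits = 12, trim = TRUE,
                         scientific = FALSE)
    }
    df
  }
  paths <- list(
    daily_features = file.path(out_dir, "daily_features.csv"),
    validity_report = file.path(out_dir, "validity_report.csv"),
    cluster_report = file.path(out_dir, "cluster_report.csv"),
    lag_table_ph = file.path(out_dir, "lag_table_ph.csv"),
    lag_table_mh = file.path(out_dir, "lag_table_mh.csv"),
    weekly_summary = file.path(out_dir, "weekly_summary.txt"),
    load_report = file.path(out_dir, "load_report.json"),
    manifest = file.path(out_dir, "manifest.json"))
  utils::write.csv(num(daily), paths$daily_features, row.names = FALSE)
  utils::write.csv(num(validity), paths$validity_report, row.names = FALSE)
  utils::write.csv(num(do.call(rbind, clusters)), paths$cluster_report,
                   row.names = FALSE)
  utils::write.csv(num(fits$ph$table), paths$lag_table_ph, row.names = FALSE)
  utils::write.csv(num(fits$mh$table), paths$lag_table_mh, row.names = FALSE)
  writeLines(summary_txt$text, paths$weekly_summary)
  write_load_report(traces, paths$load_report)

  for (dim in c("ph", "mh")) {
    if (nrow(fits[[dim]]$table) > 0) {
      p <- open_plot_device(file.path(out_dir, paste0("lag_correlation_",
                                                      dim)))
      plot(fits[[dim]])
      grDevices::dev.off()
      paths[[paste0("plot_", dim)]] <- p
    }
  }

  cfg_out <- config[!vapply(config, is.null, logical(1))]
  if (!is.null(cfg_out$cohort)) {
    cfg_out$cohort <- lapply(unclass(cfg_out$cohort), function(v) {
      if (inherits(v, "Date")) format(v) else v
    })
  }
  manifest <- list(
    package = "gpsmobility",
    version = as.character(utils::packageVersion("gpsmobility")),
    seed = config$seed,
    ci_method = "percentile",
    config = cfg_out)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(daily = daily, filtered = filtered, validity = validity,
                 fits = fits, summary = summary_txt, paths = paths))
}

#' Weekly feature summary across participants
#'
#' For each Monday-start study week, daily feature values are pooled across
#' participants and summarised as mean (SD); the report then gives each
#' feature's minimum and maximum weekly mean over the study, the format used
#' to describe cohort-level weekly averages.
#'
#' @param daily Quality-filtered daily features.
#' @return List with `weekly` (per-week mean/SD data frame) and `text`
#'   (formatted summary lines).
#' @export
summarize_features <- function(daily) {
  if (nrow(daily) == 0) stop("summarize_features: no valid days")
  if (is.null(daily$week_start)) daily$week_start <- iso_week_start(daily$date)
  weeks <- sort(unique(daily$week_start))
  rows <- lapply(weeks, function(w) {
    sub <- daily[daily$week_start == w, , drop = FALSE]
    row <- data.frame(week_start = w, n_days = nrow(sub))
    for (f in FEATURE_COLS) {
      row[[paste0(f, "_mean")]] <- mean(sub[[f]], na.rm = TRUE)
      row[[paste0(f, "_sd")]] <- stats::sd(sub[[f]])
    }
    row
  })
  weekly <- do.call(rbind, rows)
  unit <- c(total_distance_km = "km", time_home_min = "min",
            transition_time_min = "min", n_significant_locations = "")
  text <- vapply(FEATURE_COLS, function(f) {
    m <- weekly[[paste0(f, "_mean")]]
    s <- weekly[[paste0(f, "_sd")]]
    lo <- which.min(m); hi <- which.max(m)
    sprintf(
      "%s: weekly mean ranged from a minimum of %.1f (SD %.1f) to a maximum of %.1f (SD %.1f) %s",
      f, m[lo], s[lo], m[hi], s[hi], unit[f])
  }, character(1))
  list(weekly = weekly, text = unname(text))
}
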