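#' Signed week-lag between a GPS day and a QOL assessment date
#'
#' `floor((gps_date - qol_date in days) / 7)`: a GPS day on the assessment
#' date or up to 6 days after is lag 0; 1-7 days before is lag -1; lag -3
#' means GPS data collected 15-21 days before the assessment. Negative lags
#' are GPS data before the assessment.
#'
#' @param gps_date,qol_date Date vectors (recycled).
#' @return Integer vector of signed week lags.
#' @export
lag_weeks <- function(gps_date, qol_date) {
  as.integer(floor(as.numeric(gps_date - qol_date) / 7))
}

#' Assemble lag-indexed observations of one feature against one QOL dimension
#'
#' Every assessment is paired with the participant's valid GPS days, bucketed
#' into assessment-anchored weeks by [lag_weeks]; the feature value of an
#' observation is the mean of the daily values in that lag week. One
#' observation per (participant, assessment, lag).
#'
#' @param daily Quality-filtered daily features (see [filter_quality]).
#' @param assessments QOL table as from [read_qol_csv].
#' @param feature One of the daily feature column names.
#' @param qol_dim `"ph"` or `"mh"`.
#' @return Data frame with `participant_id`, `qol_date`, `lag_weeks`,
#'   `feature_value`, `qol_value`.
#' @export
assemble_lagged <- function(daily, assessments, feature = FEATURE_COLS,
                            qol_dim = c("ph", "mh")) {
  feature <- match.arg(feature)
  qol_dim <- match.arg(qol_dim)
  qcol <- paste0(qol_dim, "_t")
  out <- vector("list", nrow(assessments))
  for (i in seq_len(nrow(assessments))) {
    pid <- assessments$participant_id[i]
    qval <- assessments[[qcol]][i]
    if (is.na(qval)) next  # missing dimension contributes no observations
    sub <- daily[daily$participant_id == pid & !is.na(daily[[feature]]), ,
                 drop = FALSE]
    if (nrow(sub) == 0) next
    lag <- lag_weeks(sub$date, assessments$date[i])
    fv <- tapply(sub[[feature]], lag, mean)
    out[[i]] <- data.frame(
      participant_id = pid,
      qol_date = assessments$date[i],
      lag_weeks = as.integer(names(fv)),
      feature_value = as.numeric(fv),
      qol_value = qval,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(participant_id = character(0),
                      qol_date = as.Date(character(0)),
                      lag_weeks = integer(0), feature_value = numeric(0),
                      qol_value = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Retain lags with more than `min_obs` observations
#'
#' The observation filter is strict: a lag with exactly `min_obs` observations
#' is dropped; `min_obs + 1` is retained.
#'
#' @param observations Lagged observations from [assemble_lagged].
#' @param min_obs Strict lower bound on observations per lag (default 10).
#' @return The observations at retained lags; the retained lag values are
#'   attached as attribute `"retained_lags"`.
#' @export
filter_lags <- function(observations, min_obs = 10) {
  counts <- table(observations$lag_weeks)
  keep <- as.integer(names(counts))[counts > min_obs]
  out <- observations[observations$lag_weeks %in% keep, , drop = FALSE]
  attr(out, "retained_lags") <- sort(keep)
  out
}

#' Fit lag-indexed repeated-measures correlations with cluster-bootstrap CIs
#'
#' The core estimator: for each mobility feature and each retained signed
#' week-lag, the repeated-measures correlation between the assessment-anchored
#' weekly feature mean and the QOL T-score is estimated over all
#' (participant, assessment, lag) observations, with a participant-level
#' (cluster) bootstrap percentile confidence interval.
#'
#' @param daily Quality-filtered daily features ([filter_quality]).
#' @param assessments QOL assessment table ([read_qol_csv]).
#' @param qol_dim `"ph"` (physical health) or `"mh"` (mental health).
#' @param features Feature columns to analyse (default all four).
#' @param min_obs_per_lag Strict observation filter per lag (default 10).
#' @param n_boot Bootstrap resamples (default 1000); 0 skips the intervals
#'   and reports point estimates only.
#' @param ci_level Confidence level (default 0.95).
#' @param seed Integer seed controlling all bootstrap randomness.
#' @param lag_range Optional `c(min, max)` window of lags to keep after the
#'   observation filter (e.g. `c(-6, 13)`).
#' @return An object of class `lag_rmcorr` with the result `table` (columns
#'   `lag_weeks`, `n_obs`, `n_participants`, `feature`, `r`, `ci_low`,
#'   `ci_high`, `effect_label`, sorted by lag) and the fit settings. Methods:
#'   `print`, `summary`, `coef` (lag-by-feature matrix of r), `plot`,
#'   `as.data.frame`.
#' @seealso [rm_correlation], [cluster_bootstrap_ci], [lag_table]
#' @export
lag_rmcorr <- function(daily, assessments, qol_dim = c("ph", "mh"),
                       features = FEATURE_COLS, min_obs_per_lag = 10,
                       n_boot = 1000, ci_level = 0.95, seed = 1L,
                       lag_range = NULL) {
  qol_dim <- match.arg(qol_dim)
  rows <- list()
  cell <- 0L
  for (f in features) {
    obs <- assemble_lagged(daily, assessments, f, qol_dim)
    obs <- filter_lags(obs, min_obs_per_lag)
    lags <- attr(obs, "retained_lags")
    if (!is.null(lag_range)) {
      lags <- lags[lags >= lag_range[1] & lags <= lag_range[2]]
    }
    for (lg in lags) {
      cell <- cell + 1L
      sub <- obs[obs$lag_weeks == lg, , drop = FALSE]
      r <- rm_correlation(sub$feature_value, sub$qol_value,
                          sub$participant_id)
      ci <- if (is.na(r) || n_boot < 1) c(NA_real_, NA_real_) else {
        cluster_bootstrap_ci(sub$feature_value, sub$qol_value,
                             sub$participant_id, n_boot = n_boot,
                             level = ci_level,
                             seed = (seed + 7919L * cell) %% .Machine$integer.max)
      }
      rows[[cell]] <- data.frame(
        lag_weeks = lg, n_obs = nrow(sub),
        n_participants = length(unique(sub$participant_id)),
        feature = f, r = as.numeric(r), ci_low = ci[1], ci_high = ci[2],
        effect_label = label_effect(as.numeric(r)),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(lag_weeks = integer(0), n_obs = integer(0),
                      n_participants = integer(0), feature = character(0),
                      r = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), effect_label = character(0))
  } else {
    tab <- tab[order(tab$lag_weeks, match(tab$feature, features)), ,
               drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(
    list(table = tab, qol_dim = qol_dim, features = features,
         min_obs_per_lag = min_obs_per_lag, n_boot = n_boot,
         ci_level = ci_level, seed = seed, ci_method = "percentile",
         call = match.call()),
    class = "lag_rmcorr"
  )
}

#' Lag-correlation table
#'
#' Convenience wrapper returning only the result table of [lag_rmcorr]
#' (one row per retained lag and feature).
#'
#' @inheritParams lag_rmcorr
#' @param ... Passed to [lag_rmcorr].
#' @return Data frame, see [lag_rmcorr].
#' @export
lag_table <- function(daily, assessments, qol_dim = c("ph", "mh"), ...) {
  lag_rmcorr(daily, assessments, qol_dim = qol_dim, ...)$table
}

#' @export
print.lag_rmcorr <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Lag-indexed repeated-measures correlations (%s T-score)\n",
    toupper(x$qol_dim)))
  cat(sprintf("  %d retained lag(s), %d feature(s); %d%% cluster-bootstrap CIs (%d resamples)\n\n",
              length(unique(x$table$lag_weeks)), length(x$features),
              round(100 * x$ci_level), x$n_boot))
  if (nrow(x$table) == 0) {
    cat("  <no lag met the observation filter>\n")
    return(invisible(x))
  }
  tab <- x$table
  tab$r <- round(tab$r, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.lag_rmcorr <- function(object, ...) {
  tab <- object$table
  cat(sprintf("Repeated-measures lag correlations, %s T-score\n",
              toupper(object$qol_dim)))
  if (nrow(tab) == 0) {
    cat("  no retained lags\n")
    return(invisible(object))
  }
  cat(sprintf("  lags %d to %d; n_obs %d-%d; participants up to %d\n",
              min(tab$lag_weeks), max(tab$lag_weeks), min(tab$n_obs),
              max(tab$n_obs), max(tab$n_participants)))
  for (f in object$features) {
    sub <- tab[tab$feature == f & !is.na(tab$r), , drop = FALSE]
    if (nrow(sub) == 0) {
      cat(sprintf("  %-24s all correlations undefined\n", f))
      next
    }
    best <- sub[which.max(abs(sub$r)), ]
    excl0 <- sub$ci_low > 0 | sub$ci_high < 0
    cat(sprintf(
      "  %-24s peak r = %+.2f (%s) at lag %+d [%.2f, %.2f]; %d/%d lag CI(s) exclude 0\n",
      f, best$r, best$effect_label, best$lag_weeks, best$ci_low, best$ci_high,
      sum(excl0, na.rm = TRUE), nrow(sub)))
  }
  invisible(object)
}

#' @export
coef.lag_rmcorr <- function(object, ...) {
  tab <- object$table
  lags <- sort(unique(tab$lag_weeks))
  m <- matrix(NA_real_, length(lags), length(object$features),
              dimnames = list(lags, object$features))
  for (i in seq_len(nrow(tab))) {
    m[as.character(tab$lag_weeks[i]), tab$feature[i]] <- tab$r[i]
  }
  m
}

#' @export
as.data.frame.lag_rmcorr <- function(x, ...) x$table

#' Plot lag correlations with confidence ribbons
#'
#' One panel per feature: point estimate r against signed week-lag with the
#' cluster-bootstrap CI as a shaded ribbon and reference lines at r = 0 and
#' the +/-0.3 medium-effect convention.
#'
#' @param x A [lag_rmcorr] fit.
#' @param features Subset of features to plot.
#' @param ... Unused.
#' @export
plot.lag_rmcorr <- function(x, features = x$features, ...) {
  tab <- x$table
  if (nrow(tab) == 0) {
    warning("nothing to plot: no retained lags")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(ceiling(length(features) / 2),
                                 min(2, length(features))),
                       mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(old))
  for (f in features) {
    sub <- tab[tab$feature == f, , drop = FALSE]
    sub <- sub[order(sub$lag_weeks), ]
    ylim <- range(c(-0.4, 0.4, sub$ci_low, sub$ci_high, sub$r), na.rm = TRUE)
    graphics::plot(sub$lag_weeks, sub$r, type = "n", ylim = ylim,
                   xlab = "lag (weeks from QOL assessment)",
                   ylab = "repeated-measures r",
                   main = sprintf("%s vs %s", f, toupper(x$qol_dim)))
    ok <- !is.na(sub$ci_low)
    if (any(ok)) {
      graphics::polygon(c(sub$lag_weeks[ok], rev(sub$lag_weeks[ok])),
                        c(sub$ci_low[ok], rev(sub$ci_high[ok])),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
    }
    graphics::abline(h = 0, lty = 1, col = "grey40")
    graphics::abline(h = c(-0.3, 0.3), lty = 3, col = "grey60")
    graphics::lines(sub$lag_weeks, sub$r, col = "steelblue4")
    graphics::points(sub$lag_weeks, sub$r, pch = 16, col = "steelblue4")
  }
  invisible(x)
}
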