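#' Repeated-measures correlation
#'
#' The common within-participant linear association between two repeatedly
#' measured variables: both variables are centered on their participant means
#' and the Pearson correlation of the centered values is returned. This
#' removes stable between-participant differences, so the estimate reflects
#' only the shared within-participant covariation, with error degrees of
#' freedom `n_obs - n_participants - 1`.
#'
#' Undefined cases (fewer than 3 complete observations, or zero
#' within-participant variance in either variable) return NA rather than 0:
#' absence of within-participant variation carries no information about the
#' association.
#'
#' @param x,y Numeric vectors of paired measurements.
#' @param id Participant (cluster) identifier vector, same length.
#' @return The correlation in [-1, 1], with attributes `n_obs`,
#'   `n_participants` and `df`; NA if undefined.
#' @export
rm_correlation <- function(x, y, id) {
  ok <- !(is.na(x) | is.na(y) | is.na(id))
  x <- x[ok]; y <- y[ok]; id <- as.character(id[ok])
  n <- length(x)
  k <- length(unique(id))
  if (n < 3) return(structure(NA_real_, n_obs = n, n_participants = k,
                              df = NA_integer_))
  xc <- x - stats::ave(x, id)
  yc <- y - stats::ave(y, id)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  r <- if (sxx == 0 || syy == 0) NA_real_ else sum(xc * yc) / sqrt(sxx * syy)
  structure(r, n_obs = n, n_participants = k, df = as.integer(n - k - 1L))
}

# Per-participant sufficient statistics for the within-centered correlation.
# Because centering is per cluster, the correlation of any concatenation of
# (possibly repeated) clusters is sum(sxy) / sqrt(sum(sxx) * sum(syy)),
# which makes the cluster bootstrap cheap.
rm_suffstats <- function(x, y, id) {
  ok <- !(is.na(x) | is.na(y) | is.na(id))
  x <- x[ok]; y <- y[ok]; id <- as.character(id[ok])
  split_idx <- split(seq_along(x), id)
  t(vapply(split_idx, function(i) {
    xc <- x[i] - mean(x[i]); yc <- y[i] - mean(y[i])
    c(sxy = sum(xc * yc), sxx = sum(xc^2), syy = sum(yc^2))
  }, numeric(3)))
}

#' Cluster-bootstrap confidence interval for the repeated-measures correlation
#'
#' Participants (clusters) are resampled with replacement, each sampled
#' participant bringing their full set of observations; the repeated-measures
#' correlation is recomputed per resample and a percentile interval is taken.
#' Resampling at the participant level keeps the interval valid under
#' within-participant dependence. Degenerate resamples (zero within-cluster
#' variance in either variable) are discarded and redrawn, up to
#' `10 * n_boot` attempts; if fewer than half of `n_boot` usable resamples
#' are obtained the interval is undefined and a diagnostic is attached.
#'
#' @inheritParams rm_correlation
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; the same seed reproduces the interval exactly.
#' @return Numeric `c(ci_low, ci_high)` with attributes `n_usable` and
#'   `method = "percentile"`; both NA (with attribute `diagnostic`) when
#'   undefined.
#' @export
cluster_bootstrap_ci <- function(x, y, id, n_boot = 1000, level = 0.95,
                                 seed = 1L) {
  ss <- rm_suffstats(x, y, id)
  k <- nrow(ss)
  if (is.null(k) || k < 2) {
    return(structure(c(NA_real_, NA_real_),
                     diagnostic = "fewer than 2 participants"))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_seed(old_seed))

  rs <- numeric(n_boot)
  got <- 0L
  attempts <- 0L
  max_attempts <- 10L * n_boot
  while (got < n_boot && attempts < max_attempts) {
    take <- min(n_boot - got, n_boot)
    draw <- matrix(sample.int(k, take * k, replace = TRUE), nrow = take)
    sxy <- rowSums(matrix(ss[draw, "sxy"], nrow = take))
    sxx <- rowSums(matrix(ss[draw, "sxx"], nrow = take))
    syy <- rowSums(matrix(ss[draw, "syy"], nrow = take))
    ok <- sxx > 0 & syy > 0
    n_ok <- sum(ok)
    if (n_ok > 0) {
      rs[got + seq_len(n_ok)] <- sxy[ok] / sqrt(sxx[ok] * syy[ok])
      got <- got + n_ok
    }
    attempts <- attempts + take
  }
  if (got < n_boot / 2) {
    return(structure(c(NA_real_, NA_real_),
                     diagnostic = sprintf(
                       "only %d usable resamples of %d requested", got, n_boot)))
  }
  rs <- rs[seq_len(got)]
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(rs, c(alpha, 1 - alpha)))
  structure(ci, n_usable = got, method = "percentile")
}

#' Conventional effect-size label for a correlation
#'
#' Labels follow the convention small at |r| = 0.1, medium at |r| = 0.3 and
#' large at |r| >= 0.5; below 0.1 is negligible.
#'
#' @param r Correlation value(s).
#' @return Character vector of labels ("negligible", "small", "medium",
#'   "large"), NA where `r` is NA.
#' @export
label_effect <- function(r) {
  a <- abs(r)
  out <- ifelse(a >= 0.5, "large",
                ifelse(a >= 0.3, "medium",
                       ifelse(a >= 0.1, "small", "negligible")))
  out[is.na(r)] <- NA_character_
  out
}
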