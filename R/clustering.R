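#' Adaptive k-means clustering of stationary GPS points
#'
#' Finds a participant's significant locations: points are projected to a
#' local planar frame (meters), k-means is fitted for k = 1..k_max with
#' k-means++ seeding and 10 restarts per k (lowest within-cluster sum of
#' squares kept), and the number of clusters is chosen by the elbow criterion:
#' the k whose point on the axis-normalised WSS-vs-k curve lies furthest below
#' the chord from the first to the last k (ties broken by the lowest k).
#' Deterministic given `seed`.
#'
#' @param lat,lon Stationary point coordinates, decimal degrees.
#' @param k_max Largest k considered; the effective upper bound is
#'   `min(k_max, number of distinct points)`.
#' @param seed Integer seed for the k-means++ initialisation.
#' @param n_restarts Restarts per k (default 10).
#' @param fit_max At most this many points are used to fit the model (seeded
#'   subsample); all points are still assigned afterwards.
#' @return A `location_clusters` object: list with `k`, `clusters` (per
#'   cluster: `lat`, `lon`, `member_count`, `visit_minutes_total`,
#'   `visit_minutes_night`), planar `centers_xy`, projection reference,
#'   `assignment` (cluster index per input point), `wss` (per candidate k)
#'   and `home_index` (NA until visit statistics are filled in).
#' @export
adaptive_kmeans <- function(lat, lon, k_max = 10, seed = 1L, n_restarts = 10,
                            fit_max = 20000) {
  n <- length(lat)
  if (n == 0) {
    return(structure(list(k = 0L, clusters = list(), centers_xy = NULL,
                          ref_lat = NA_real_, ref_lon = NA_real_,
                          assignment = integer(0), wss = numeric(0),
                          home_index = NA_integer_),
                     class = "location_clusters"))
  }
  proj <- local_project(lat, lon)
  pts <- proj$xy
  fit_pts <- pts
  if (n > fit_max) {
    idx <- sample_with_seed(seed, n, fit_max)
    fit_pts <- pts[idx, , drop = FALSE]
  }
  n_distinct <- nrow(unique(fit_pts))
  ks <- seq_len(min(k_max, n_distinct))

  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_seed(old_seed))

  fits <- vector("list", length(ks))
  wss <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    best <- NULL
    if (k == nrow(fit_pts)) {
      # exact solution (stats::kmeans rejects k == n): one point per center
      best <- list(centers = fit_pts, tot.withinss = 0)
    } else {
      for (r in seq_len(n_restarts)) {
        init <- kmeanspp_init(fit_pts, k)
        fit <- suppressWarnings(
          stats::kmeans(fit_pts, centers = init, iter.max = 100))
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
        if (k == 1) break  # single cluster has a closed form
      }
    }
    fits[[i]] <- best
    wss[i] <- best$tot.withinss
  }
  k_star <- ks[elbow_index(ks, wss)]
  centers <- fits[[match(k_star, ks)]]$centers

  assignment <- nearest_center(pts, centers)
  member_count <- tabulate(assignment, nbins = k_star)
  ll <- local_unproject(centers, proj$ref_lat, proj$ref_lon)
  clusters <- lapply(seq_len(k_star), function(j) {
    list(lat = unname(ll[j, 1]), lon = unname(ll[j, 2]),
         member_count = member_count[j],
         visit_minutes_total = 0, visit_minutes_night = 0)
  })
  structure(list(k = k_star, clusters = clusters, centers_xy = centers,
                 ref_lat = proj$ref_lat, ref_lon = proj$ref_lon,
                 assignment = assignment, wss = stats::setNames(wss, ks),
                 home_index = NA_integer_),
            class = "location_clusters")
}

#' @export
print.location_clusters <- function(x, ...) {
  cat(sprintf("Significant-location model: k = %d cluster(s)\n", x$k))
  for (j in seq_len(x$k)) {
    cl <- x$clusters[[j]]
    cat(sprintf(
      "  [%d]%s (%.5f, %.5f)  members %d  dwell %.0f min (night %.0f)\n",
      j, if (identical(j, x$home_index)) " home" else "",
      cl$lat, cl$lon, cl$member_count,
      cl$visit_minutes_total, cl$visit_minutes_night))
  }
  invisible(x)
}

# k-means++ seeding: first center uniform, later centers drawn with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(NA_real_, k, ncol(pts))
  centers[1, ] <- pts[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- rowSums((pts - rep(centers[1, ], each = n))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        centers[j, ] <- pts[sample.int(n, 1), ]
      } else {
        centers[j, ] <- pts[sample.int(n, 1, prob = d2), ]
      }
      d2 <- pmin(d2, rowSums((pts - rep(centers[j, ], each = n))^2))
    }
  }
  # collapse accidental duplicate centers by tiny deterministic perturbation
  dup <- duplicated(centers)
  if (any(dup)) centers[dup, ] <- centers[dup, , drop = FALSE] + 1e-6
  centers
}

nearest_center <- function(pts, centers) {
  k <- nrow(centers)
  d2 <- vapply(seq_len(k), function(j) {
    (pts[, 1] - centers[j, 1])^2 + (pts[, 2] - centers[j, 2])^2
  }, numeric(nrow(pts)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  max.col(-d2, ties.method = "first")
}

# Kneedle chord rule on the log-WSS curve: the candidate k furthest below
# the chord joining the first and last points of the normalised
# log(WSS)-vs-k curve. The log scale makes the rule scale-free: cluster
# separations (km) and within-cluster scatter (m) differ by orders of
# magnitude, and on the raw scale every k past the first big drop collapses
# onto the chord, so the raw-WSS chord systematically under-estimates k when
# cluster sizes or separations are uneven. Ties break to the lowest k.
elbow_index <- function(ks, wss) {
  m <- length(ks)
  if (m == 1) return(1L)
  eps <- max(wss) * 1e-12 + .Machine$double.xmin
  ly <- log(wss + eps)
  rng <- max(ly) - min(ly)
  if (rng == 0) return(1L)
  x <- (ks - ks[1]) / (ks[m] - ks[1])
  y <- (ly - min(ly)) / rng
  d <- (y[1] + x * (y[m] - y[1])) - y  # vertical drop below the chord
  which.max(d)
}

#' Assign points to fitted location clusters
#'
#' @param lat,lon Coordinates in decimal degrees.
#' @param clusters A [location_clusters] object.
#' @return Integer vector of cluster indices (nearest planar center).
#' @export
assign_to_clusters <- function(lat, lon, clusters) {
  stopifnot(inherits(clusters, "location_clusters"), clusters$k > 0)
  pts <- local_project(lat, lon, clusters$ref_lat, clusters$ref_lon)$xy
  nearest_center(pts, clusters$centers_xy)
}

#' Identify the home cluster
#'
#' Two heuristics, applied jointly: the home must be (1) among the 3 clusters
#' with the greatest total dwell time and (2) the one among those with the
#' greatest dwell time between 00:00 and 06:00 local. Undefined (NA) when the
#' cluster set is empty or no cluster has any night dwell time.
#'
#' @param clusters A [location_clusters] object with visit statistics filled
#'   in (see [fit_significant_locations]).
#' @return Integer index of the home cluster, or NA.
#' @export
identify_home <- function(clusters) {
  if (clusters$k == 0) return(NA_integer_)
  total <- vapply(clusters$clusters, `[[`, numeric(1), "visit_minutes_total")
  night <- vapply(clusters$clusters, `[[`, numeric(1), "visit_minutes_night")
  top3 <- order(-total)[seq_len(min(3, clusters$k))]
  if (all(night[top3] == 0)) return(NA_integer_)
  top3[which.max(night[top3])]
}

#' Fit a participant's significant-location model with visit statistics
#'
#' Collects the stationary points of the whole trace (starting fixes of usable
#' gaps at or below the speed threshold, computed within local days so gaps
#' never span midnight), fits [adaptive_kmeans], accumulates per-cluster dwell
#' minutes (total and 00:00-06:00 local) by attributing each usable stationary
#' gap to the cluster of its starting fix, and identifies the home cluster.
#'
#' @inheritParams extract_daily_features
#' @return A [location_clusters] object with visit statistics and
#'   `home_index` set.
#' @export
fit_significant_locations <- function(trace, k_max = 10,
                                      speed_threshold_mps = 1,
                                      max_gap_s = 300, seed = 1L) {
  days <- bucket_by_day(trace)
  gaps <- do.call(rbind, lapply(days, gap_table, max_gap_s = max_gap_s))
  st <- gaps[gaps$usable & gaps$speed_mps <= speed_threshold_mps, ,
             drop = FALSE]
  if (nrow(st) == 0) {
    return(adaptive_kmeans(numeric(0), numeric(0), k_max = k_max, seed = seed))
  }
  cl <- adaptive_kmeans(st$start_lat, st$start_lon, k_max = k_max, seed = seed)
  idx <- cl$assignment
  night <- st$start_hour >= 0 & st$start_hour < 6
  tot_min <- tapply(st$dt_s, factor(idx, levels = seq_len(cl$k)), sum,
                    default = 0) / 60
  night_min <- tapply(st$dt_s * night, factor(idx, levels = seq_len(cl$k)),
                      sum, default = 0) / 60
  for (j in seq_len(cl$k)) {
    cl$clusters[[j]]$visit_minutes_total <- unname(tot_min[j])
    cl$clusters[[j]]$visit_minutes_night <- unname(night_min[j])
  }
  cl$home_index <- identify_home(cl)
  cl
}

#' Cluster report table
#'
#' One row per fitted cluster, mirroring the cluster report written by
#' [run_pipeline].
#'
#' @param clusters A fitted [location_clusters].
#' @param participant_id Participant identifier for the report rows.
#' @return Data frame with center coordinates, member counts, dwell minutes
#'   and the home flag.
#' @export
cluster_report <- function(clusters, participant_id = NA_character_) {
  if (clusters$k == 0) {
    return(data.frame(participant_id = character(0), cluster = integer(0),
                      center_lat = numeric(0), center_lon = numeric(0),
                      member_count = integer(0),
                      visit_minutes_total = numeric(0),
                      visit_minutes_night = numeric(0), is_home = logical(0)))
  }
  data.frame(
    participant_id = participant_id,
    cluster = seq_len(clusters$k),
    center_lat = vapply(clusters$clusters, `[[`, numeric(1), "lat"),
    center_lon = vapply(clusters$clusters, `[[`, numeric(1), "lon"),
    member_count = vapply(clusters$clusters, `[[`, numeric(1), "member_count"),
    visit_minutes_total = vapply(clusters$clusters, `[[`, numeric(1),
                                 "visit_minutes_total"),
    visit_minutes_night = vapply(clusters$clusters, `[[`, numeric(1),
                                 "visit_minutes_night"),
    is_home = seq_len(clusters$k) == (clusters$home_index %||% NA_integer_),
    stringsAsFactors = FALSE
  )
}
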