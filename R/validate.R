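# Maximum pairwise Euclidean distance of 2D points; uses the convex hull
# so long trajectories do not need an O(T^2) distance matrix.
max_pairwise_distance_2d <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) > 3) {
    hull <- grDevices::chull(pts[, 1], pts[, 2])
    pts <- pts[hull, , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Collect observed transition vectors around a query point
#'
#' From a (projected, 2D) trajectory, all timepoints passing within
#' `capture_fraction` of the trajectory's maximum pairwise distance of the
#' query point become start points; the observed vector of a start point t
#' is `coords[t + lag, ] - coords[t, ]`. Starts whose end index overruns
#' the trajectory are dropped.
#'
#' @param traj_coords2d time x 2 matrix of projected trajectory states.
#' @param query length-2 query point.
#' @param lag time delay in recorded steps (>= 0).
#' @param capture_fraction capture distance as a fraction of the maximum
#'   pairwise trajectory distance (default 0.02).
#' @return list of class `observed_vectors`: `starts` (indices), `vectors`
#'   (n x 2), `angles` (radians in (-pi, pi]), `query`, `lag`,
#'   `capture_distance`. Empty (with a warning) when no timepoint passes
#'   near the query.
#' @export
collect_observed_vectors <- function(traj_coords2d, query, lag,
                                     capture_fraction = 0.02) {
  traj_coords2d <- as.matrix(traj_coords2d)
  stopifnot(ncol(traj_coords2d) == 2, length(query) == 2, lag >= 0,
            capture_fraction > 0)
  cap <- capture_fraction * max_pairwise_distance_2d(traj_coords2d)
  d <- sqrt((traj_coords2d[, 1] - query[1])^2 +
            (traj_coords2d[, 2] - query[2])^2)
  starts <- which(d <= cap)
  starts <- starts[starts + lag <= nrow(traj_coords2d)]
  if (length(starts) == 0) {
    warning("no trajectory points within the capture distance of the query")
    vecs <- matrix(numeric(0), 0, 2)
  } else {
    vecs <- traj_coords2d[starts + lag, , drop = FALSE] -
      traj_coords2d[starts, , drop = FALSE]
  }
  structure(list(starts = starts, vectors = vecs,
                 angles = atan2(vecs[, 2], vecs[, 1]),
                 query = query, lag = lag, capture_distance = cap),
            class = "observed_vectors")
}

#' Select the trajectory lag matching a target displacement
#'
#' Scans lags 1..`max_lag` and returns the lag whose root mean squared
#' distance (RMSD) between start points and the points `lag` steps later is
#' closest to `target_rmsd`; ties go to the smaller lag. The target is
#' chosen per dataset so observed vectors are long enough to rise above
#' noise yet still local.
#'
#' @param traj_coords2d time x 2 projected trajectory.
#' @param starts start indices (e.g., from [collect_observed_vectors()]).
#' @param target_rmsd target RMSD, > 0.
#' @param max_lag largest lag scanned (default 200).
#' @return Integer lag, with attribute `rmsd` (the RMSD profile over lags).
#' @export
select_lag <- function(traj_coords2d, starts, target_rmsd, max_lag = 200) {
  traj_coords2d <- as.matrix(traj_coords2d)
  if (length(starts) == 0) stop("no start points supplied")
  stopifnot(target_rmsd > 0, max_lag >= 1)
  rmsd <- rep(NA_real_, max_lag)
  for (lag in seq_len(max_lag)) {
    ok <- starts[starts + lag <= nrow(traj_coords2d)]
    if (length(ok) == 0) break
    dd <- traj_coords2d[ok + lag, , drop = FALSE] -
      traj_coords2d[ok, , drop = FALSE]
    rmsd[lag] <- sqrt(mean(rowSums(dd^2)))
  }
  if (all(is.na(rmsd))) stop("all lags overrun the trajectory")
  best <- which.min(abs(rmsd - target_rmsd))  # which.min takes first tie
  structure(as.integer(best), rmsd = rmsd)
}

#' Peak angles of a circular distribution (von Mises kernel density)
#'
#' The density at angle theta is the mean over samples of
#' `exp(kappa * cos(theta - angle_s))`, evaluated on a 360-point grid.
#' Peaks are circular local maxima (wrap-around handled, so a cluster
#' straddling +/-pi yields one peak) at or above `floor_frac` of the
#' density maximum.
#'
#' @param angles sample angles in radians (>= 5).
#' @param kappa von Mises concentration (default 8).
#' @param grid_n grid resolution (default 360, i.e., 1 degree).
#' @param floor_frac discard peaks below this fraction of the maximum.
#' @return Numeric vector of peak angles in (-pi, pi], ordered by
#'   decreasing density, with attribute `density` (grid density) and
#'   `grid` (grid angles).
#' @export
angle_peaks <- function(angles, kappa = 8, grid_n = 360, floor_frac = 0.2) {
  if (length(angles) < 5) stop("need at least 5 angles")
  grid <- seq(-pi, pi, length.out = grid_n + 1)[-(grid_n + 1)]
  dens <- vapply(grid, function(th) mean(exp(kappa * cos(th - angles))),
                 numeric(1))
  up <- c(dens[-1], dens[1])
  down <- c(dens[grid_n], dens[-grid_n])
  is_peak <- dens > down & dens >= up & dens >= floor_frac * max(dens)
  if (!any(is_peak)) is_peak[which.max(dens)] <- TRUE
  peaks <- grid[is_peak]
  ord <- order(dens[is_peak], decreasing = TRUE)
  structure(peaks[ord], density = dens, grid = grid)
}

#' Cosine similarity between a predicted vector and the nearest peak angle
#'
#' `max` over peaks of `cos(angle(predicted) - peak)`: 1 when aligned with
#' any peak, so heterogeneous (multi-route) trajectories are not penalized.
#' Invariant to positive rescaling of the vector.
#'
#' @param predicted non-zero 2D vector.
#' @param peaks peak angles (radians), e.g., from [angle_peaks()].
#' @return score in [-1, 1]; NA (with a warning) for a zero vector.
#' @export
cosine_score <- function(predicted, peaks) {
  stopifnot(length(predicted) == 2, length(peaks) >= 1)
  if (all(predicted == 0)) {
    warning("zero predicted vector: cosine score undefined")
    return(NA_real_)
  }
  theta <- atan2(predicted[2], predicted[1])
  max(cos(theta - peaks))
}

#' Nearest-peak cosine scores for both ends of a reversibility vector
#'
#' Reversibility has no preferred sign, so both ends (+v and -v) are scored
#' independently against the nearest observed peak.
#'
#' @param reversibility non-zero 2D reversibility vector.
#' @param peaks peak angles (radians).
#' @return named numeric pair c(plus = ..., minus = ...).
#' @export
reversibility_score <- function(reversibility, peaks) {
  c(plus = cosine_score(reversibility, peaks),
    minus = cosine_score(-reversibility, peaks))
}

#' Validate predicted vectors against an observed trajectory
#'
#' End-to-end harness: for each query point, collects observed vectors
#' from the trajectory (selecting the lag from `target_rmsd` when given),
#' finds their circular density peaks, and scores the prediction at the
#' query (nearest valid cell's vector from `fit`) by nearest-peak cosine
#' similarity. Net flow is scored directly; reversibility at both ends.
#'
#' @param fit a [sticc()] fit whose space is the trajectory's projection.
#' @param traj_coords2d time x 2 projected trajectory (same space as
#'   `fit`).
#' @param queries q x 2 matrix of query points.
#' @param component "net" or "rev".
#' @param lag fixed lag, or NULL to select per query via `target_rmsd`.
#' @param target_rmsd RMSD target for [select_lag()] (required when
#'   `lag` is NULL).
#' @param capture_fraction see [collect_observed_vectors()].
#' @param kappa von Mises concentration for [angle_peaks()].
#' @param max_lag see [select_lag()].
#' @return data.frame, one row per query: query coordinates, n_starts,
#'   lag, n_peaks, predicted angle, score (best score for reversibility),
#'   score_minus (reversibility only).
#' @export
validate_against_trajectory <- function(fit, traj_coords2d, queries,
                                        component = c("net", "rev"),
                                        lag = NULL, target_rmsd = NULL,
                                        capture_fraction = 0.02, kappa = 8,
                                        max_lag = 200) {
  component <- match.arg(component)
  queries <- matrix(as.matrix(queries), ncol = 2)
  V <- field_component(fit, component)[, 1:2, drop = FALSE]
  co <- fit$space$coords[, 1:2, drop = FALSE]
  rows <- lapply(seq_len(nrow(queries)), function(qi) {
    q <- queries[qi, ]
    base <- data.frame(qx = q[1], qy = q[2], n_starts = 0L, lag = NA_integer_,
                       n_peaks = NA_integer_, predicted_angle = NA_real_,
                       score = NA_real_, score_minus = NA_real_)
    obs0 <- suppressWarnings(
      collect_observed_vectors(traj_coords2d, q, lag = 0,
                               capture_fraction = capture_fraction))
    if (length(obs0$starts) == 0) return(base)
    use_lag <- lag
    if (is.null(use_lag)) {
      if (is.null(target_rmsd))
        stop("supply either a fixed lag or a target_rmsd")
      use_lag <- select_lag(traj_coords2d, obs0$starts, target_rmsd, max_lag)
    }
    obs <- collect_observed_vectors(traj_coords2d, q, lag = use_lag,
                                    capture_fraction = capture_fraction)
    if (length(obs$starts) < 5) return(base)
    peaks <- angle_peaks(obs$angles, kappa = kappa)
    dq <- sqrt((co[, 1] - q[1])^2 + (co[, 2] - q[2])^2)
    dq[!fit$valid] <- Inf
    ci <- which.min(dq)
    v <- V[ci, ]
    base$n_starts <- length(obs$starts)
    base$lag <- as.integer(use_lag)
    base$n_peaks <- length(peaks)
    if (all(v == 0) || anyNA(v)) return(base)
    base$predicted_angle <- atan2(v[2], v[1])
    if (component == "rev") {
      sc <- reversibility_score(v, peaks)
      base$score <- max(sc)
      base$score_minus <- min(sc)
    } else {
      base$score <- cosine_score(v, peaks)
    }
    base
  })
  do.call(rbind, rows)
}
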