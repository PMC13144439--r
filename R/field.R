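#' Principal component projection of an expression matrix
#'
#' Centered (not scaled) PCA with a deterministic sign convention: in each
#' component the loading with the largest absolute value is made positive,
#' so repeated runs and machine-to-machine differences cannot flip axes.
#'
#' @param expression cells x genes matrix.
#' @param n_components number of components to keep
#'   (<= min(cells - 1, genes)).
#' @return list with `model` (loadings genes x k, per-gene `center`,
#'   `explained_variance` fractions) and `coords` (cells x k scores).
#' @export
pca_project <- function(expression, n_components = 2) {
  n_max <- min(nrow(expression) - 1L, ncol(expression))
  if (n_components > n_max)
    stop("n_components must be <= min(cells - 1, genes) = ", n_max)
  pr <- stats::prcomp(expression, center = TRUE, scale. = FALSE)
  k <- n_components
  load <- pr$rotation[, 1:k, drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  coords <- sweep(pr$x[, 1:k, drop = FALSE], 2, flip, `*`)
  ev <- pr$sdev^2 / sum(pr$sdev^2)
  list(model = list(loadings = load, center = pr$center,
                    explained_variance = ev[1:k]),
       coords = coords)
}

#' Project new data with an existing PCA model
#'
#' @param model the `model` element returned by [pca_project()].
#' @param expression cells x genes matrix over the same genes.
#' @return cells x k coordinate matrix.
#' @export
pca_transform <- function(model, expression) {
  sweep(expression[, names(model$center), drop = FALSE], 2, model$center) %*%
    model$loadings
}

#' Inverse-distance-weighted smoothing of a vector field on a grid
#'
#' Lays a uniform `grid_size` x `grid_size` lattice over the bounding box
#' of the 2D coordinates; each node's vector is the inverse-distance
#' weighted mean, with weights `1 / (d + 1e-9)^power`, of the vectors of
#' all cells within `influence_radius` of the node. Nodes with no cell in
#' range are masked.
#'
#' @param coords2d cells x 2 coordinates.
#' @param vectors cells x 2 vectors.
#' @param grid_size nodes per axis (>= 2).
#' @param power inverse-distance exponent.
#' @param influence_radius absolute radius around each node.
#' @return list of class `smoothed_field`: `grid` (nodes x 2), `vectors`
#'   (nodes x 2, NA where masked), `occupied` (logical),
#'   `n_contributors` (integer per node).
#' @export
grid_smooth <- function(coords2d, vectors, grid_size = 20, power = 2,
                        influence_radius) {
  coords2d <- as.matrix(coords2d)
  vectors <- as.matrix(vectors)
  stopifnot(ncol(coords2d) == 2, ncol(vectors) == 2, grid_size >= 2,
            nrow(coords2d) == nrow(vectors),
            all(is.finite(coords2d)), all(is.finite(vectors)),
            influence_radius > 0)
  gx <- seq(min(coords2d[, 1]), max(coords2d[, 1]), length.out = grid_size)
  gy <- seq(min(coords2d[, 2]), max(coords2d[, 2]), length.out = grid_size)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  nn <- nrow(grid)
  out_v <- matrix(NA_real_, nn, 2)
  n_contrib <- integer(nn)
  delta <- 1e-9
  for (g in seq_len(nn)) {
    d <- sqrt((coords2d[, 1] - grid[g, 1])^2 +
              (coords2d[, 2] - grid[g, 2])^2)
    inr <- which(d <= influence_radius)
    n_contrib[g] <- length(inr)
    if (length(inr)) {
      w <- 1 / (d[inr] + delta)^power
      out_v[g, ] <- colSums(vectors[inr, , drop = FALSE] * w) / sum(w)
    }
  }
  structure(list(grid = grid, vectors = out_v, occupied = n_contrib > 0L,
                 n_contributors = n_contrib),
            class = "smoothed_field")
}

#' Estimate basin positions from a 2D point density
#'
#' Gaussian kernel density (Scott bandwidth) on a 100 x 100 grid; basin
#' centers are the local density maxima over an 8-cell neighborhood, with
#' maxima below 10% of the global peak discarded as spurious.
#'
#' @param coords2d points x 2 matrix (>= 50 points).
#' @param grid_n density grid resolution per axis.
#' @param min_density_frac discard peaks below this fraction of the global
#'   maximum.
#' @return matrix of basin centers (k x 2) with a `density` attribute of
#'   peak heights, ordered by decreasing density.
#' @export
estimate_basins <- function(coords2d, grid_n = 100, min_density_frac = 0.1) {
  coords2d <- as.matrix(coords2d)
  stopifnot(ncol(coords2d) == 2)
  if (nrow(coords2d) < 50) stop("basin estimation needs at least 50 points")
  sds <- apply(coords2d, 2, stats::sd)
  if (any(sds == 0) || abs(stats::cor(coords2d[, 1], coords2d[, 2])) > 0.9999)
    stop("degenerate (collinear) coordinates; density has no 2D structure")
  n <- nrow(coords2d)
  # Scott bandwidth sigma * n^(-1/6); kde2d's h is ~4x the kernel SD
  h <- 4 * sds * n^(-1 / 6)
  dens <- MASS::kde2d(coords2d[, 1], coords2d[, 2], h = h, n = grid_n)
  z <- dens$z
  peak <- matrix(FALSE, grid_n, grid_n)
  for (i in 2:(grid_n - 1)) {
    for (j in 2:(grid_n - 1)) {
      nbhd <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
      peak[i, j] <- z[i, j] == max(nbhd) && sum(nbhd == z[i, j]) == 1L
    }
  }
  peak[z < min_density_frac * max(z)] <- FALSE
  idx <- which(peak, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    # fall back to the single global maximum (possibly on the border)
    gi <- which(z == max(z), arr.ind = TRUE)[1, ]
    idx <- matrix(gi, 1, 2)
  }
  centers <- cbind(dens$x[idx[, 1]], dens$y[idx[, 2]])
  colnames(centers) <- colnames(coords2d) %||% c("x", "y")
  ord <- order(z[idx], decreasing = TRUE)
  centers <- centers[ord, , drop = FALSE]
  attr(centers, "density") <- z[idx][ord]
  centers
}

# Per-cell vector matrix of a chosen component.
field_component <- function(fit, component = c("net", "rev", "v1", "v2")) {
  component <- match.arg(component)
  switch(component, net = fit$net_flow, rev = fit$reversibility,
         v1 = fit$v1, v2 = fit$v2)
}

#' Compare two vector fields cell by cell
#'
#' For each cell present and valid in both fits, reports the Euclidean
#' norm of the vector difference (`dmag`, the primary sensitivity metric),
#' the absolute difference of magnitudes (`dmag_abs`, the alternative
#' reading), and the absolute angle in [0, pi] between the two vectors'
#' first-two-coordinate projections (`dangle`; NA when either projection is
#' a zero vector).
#'
#' @param a,b [sticc()] fits on the same cells and space.
#' @param component one of "net", "rev", "v1", "v2".
#' @return data.frame with columns cell, valid, dmag, dmag_abs, dangle.
#' @export
compare_fields <- function(a, b, component = c("net", "rev", "v1", "v2")) {
  component <- match.arg(component)
  if (length(a$valid) != length(b$valid))
    stop("fields describe different cell sets")
  va <- field_component(a, component)
  vb <- field_component(b, component)
  if (ncol(va) != ncol(vb)) stop("fields live in different spaces")
  ok <- a$valid & b$valid
  dmag <- sqrt(rowSums((vb - va)^2))
  dmag_abs <- abs(sqrt(rowSums(vb^2)) - sqrt(rowSums(va^2)))
  pa <- va[, 1:2, drop = FALSE]
  pb <- vb[, 1:2, drop = FALSE]
  na_ <- sqrt(rowSums(pa^2))
  nb_ <- sqrt(rowSums(pb^2))
  # atan2 of |cross| over dot: exact 0 for parallel, pi for anti-parallel
  dangle <- atan2(abs(pa[, 1] * pb[, 2] - pa[, 2] * pb[, 1]),
                  rowSums(pa * pb))
  dangle[na_ == 0 | nb_ == 0] <- NA_real_
  dmag[!ok] <- dmag_abs[!ok] <- dangle[!ok] <- NA_real_
  data.frame(cell = rownames(va) %||% as.character(seq_along(ok)),
             valid = ok, dmag = dmag, dmag_abs = dmag_abs, dangle = dangle,
             stringsAsFactors = FALSE)
}

#' Null distribution of angle changes from shuffled cell pairs
#'
#' Builds the reference distribution against which dropout- or
#' perturbation-induced angle changes are judged: for every valid cell, the
#' angle between its vector and the vector of a uniformly drawn *different*
#' valid cell.
#'
#' @param fit a [sticc()] fit.
#' @param component vector component to use.
#' @param seed integer seed.
#' @return numeric vector of angles in [0, pi].
#' @export
shuffled_null <- function(fit, component = c("net", "rev", "v1", "v2"),
                          seed = NULL) {
  component <- match.arg(component)
  if (!is.null(seed)) set.seed(seed)
  V <- field_component(fit, component)[, 1:2, drop = FALSE]
  idx <- which(fit$valid & sqrt(rowSums(V^2)) > 0)
  if (length(idx) < 2) stop("need at least 2 valid cells with nonzero vectors")
  partner <- vapply(seq_along(idx), function(ii) {
    others <- idx[-ii]
    others[sample.int(length(others), 1L)]
  }, integer(1))
  a <- V[idx, , drop = FALSE]
  b <- V[partner, , drop = FALSE]
  atan2(abs(a[, 1] * b[, 2] - a[, 2] * b[, 1]), rowSums(a * b))
}

#' Edge-sensitivity analysis of a vector field
#'
#' Re-runs the vector inference with parts of the network removed
#' (simulating incomplete or incorrect prior knowledge) and quantifies the
#' impact of each perturbation as the median per-cell change (Euclidean
#' norm of the vector difference) in net flow and in reversibility against
#' the baseline fit. Output rows are sorted by the combined change, and the
#' top 15% are flagged.
#'
#' @param topology the baseline [grn_topology()].
#' @param expression,space,radius,min_neighbors as in [sticc()]; must match
#'   the baseline fit.
#' @param perturbations named list; each element is a list of arguments for
#'   [perturb_topology()] (`edges`, `node`, `direction`). An empty list is
#'   the identity perturbation.
#' @param baseline a [sticc()] fit of the unperturbed topology, or NULL to
#'   compute it.
#' @param top_frac fraction of perturbations flagged as most influential.
#' @return data.frame of class `sticc_sensitivity` with columns
#'   perturbation, d_net, d_rev, combined, degenerate, top_flag; per-cell
#'   change tables retained in attribute `details`.
#' @export
edge_sensitivity <- function(topology, expression, space = NULL,
                             perturbations, baseline = NULL, radius = 0.15,
                             min_neighbors = 15, top_frac = 0.15) {
  if (is.null(baseline))
    baseline <- sticc(topology, expression, space = space, radius = radius,
                      min_neighbors = min_neighbors)
  space <- baseline$space
  nm <- names(perturbations) %||% paste0("perturbation_", seq_along(perturbations))
  details <- list()
  rows <- lapply(seq_along(perturbations), function(p) {
    pt <- do.call(perturb_topology, c(list(topology = topology),
                                      perturbations[[p]]))
    if (pt$degenerate)
      return(data.frame(perturbation = nm[p], d_net = NA_real_,
                        d_rev = NA_real_, combined = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    fit <- sticc(pt, expression, space = space, radius = radius,
                 min_neighbors = min_neighbors)
    cn <- compare_fields(baseline, fit, "net")
    cr <- compare_fields(baseline, fit, "rev")
    details[[nm[p]]] <<- list(net = cn, rev = cr)
    data.frame(perturbation = nm[p],
               d_net = stats::median(cn$dmag, na.rm = TRUE),
               d_rev = stats::median(cr$dmag, na.rm = TRUE),
               combined = NA_real_, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$combined <- out$d_net + out$d_rev
  out <- out[order(-out$combined, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  n_real <- sum(!out$degenerate)
  n_top <- ceiling(top_frac * n_real)
  out$top_flag <- !out$degenerate & seq_len(nrow(out)) <= n_top
  attr(out, "details") <- details
  class(out) <- c("sticc_sensitivity", class(out))
  out
}

#' Enumerate per-node perturbations for [edge_sensitivity()]
#'
#' One perturbation per gene, removing its outgoing, incoming, or both
#' edge sets.
#'
#' @param topology a [grn_topology()].
#' @param direction passed to [perturb_topology()].
#' @return named list of perturbation specs.
#' @export
node_perturbations <- function(topology, direction = "outgoing") {
  out <- lapply(topology$genes,
                function(g) list(node = g, direction = direction))
  names(out) <- paste0(topology$genes, "_", direction)
  out
}
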