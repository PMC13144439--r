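#' Cross-cell correlation context
#'
#' Binds a topology to an expression matrix and precomputes the full
#' cells x cells cross-cell correlation (CCC) matrix. The CCC from cell i
#' to cell j is the Pearson correlation between the sign-adjusted regulator
#' expression of cell i and the target expression of cell j, taken over the
#' network's edges:
#' `rho_{i->j} = corr(e_R_i * s, e_T_j)`,
#' where the k-th component of `e_R_i` is cell i's expression of edge k's
#' source gene, `e_T_j` likewise for edge k's target gene, and `s` is the
#' edge sign (+1 activation, -1 inhibition). A high CCC marks cell j as a
#' plausible future state of cell i under the network. Cells whose
#' regulator or target vector has zero variance have undefined (NA)
#' correlations.
#'
#' @param topology a [grn_topology()] with >= 2 edges.
#' @param expression cells x genes matrix (log or z-scored upstream; used
#'   as supplied) whose columns cover the network genes.
#' @return An object of class `ccc_context` with elements `ccc` (n x n
#'   matrix, `ccc[i, j]` = rho_{i->j}), `topology`, `expression` (restricted
#'   to network genes) and the edge index vectors.
#' @export
ccc_context <- function(topology, expression) {
  stopifnot(inherits(topology, "grn_topology"))
  if (nrow(topology$edges) < 2)
    stop("cross-cell correlation needs at least 2 edges")
  if (!all(topology$genes %in% colnames(expression)))
    stop("network genes missing from expression matrix: ",
         paste(setdiff(topology$genes, colnames(expression)), collapse = ", "))
  expression <- expression[, topology$genes, drop = FALSE]
  idx <- topology_indices(topology, colnames(expression))
  R <- expression[, idx$regulator, drop = FALSE] *
    matrix(idx$sign, nrow(expression), length(idx$sign), byrow = TRUE)
  T_ <- expression[, idx$target, drop = FALSE]
  std_rows <- function(M) {
    Mc <- M - rowMeans(M)
    ss <- sqrt(rowSums(Mc^2))
    bad <- ss == 0 | !is.finite(ss)
    ss[bad] <- 1
    out <- Mc / ss
    out[bad, ] <- NA_real_
    out
  }
  Rs <- std_rows(R)
  Ts <- std_rows(T_)
  ccc <- Rs %*% t(Ts)
  ccc[ccc > 1] <- 1
  ccc[ccc < -1] <- -1
  dimnames(ccc) <- list(rownames(expression), rownames(expression))
  structure(list(ccc = ccc, topology = topology, expression = expression,
                 regulator = idx$regulator, target = idx$target,
                 sign = idx$sign),
            class = "ccc_context")
}

#' Cross-cell correlation between two cells
#'
#' Scalar convenience wrapper around [ccc_context()]; see there for the
#' definition.
#'
#' @inheritParams ccc_context
#' @param i,j cell indices (i = regulator side, j = target side).
#' @return rho_{i->j} in [-1, 1], or NA when either edge vector has zero
#'   variance.
#' @export
compute_ccc <- function(topology, expression, i, j) {
  if (nrow(topology$edges) < 2)
    stop("cross-cell correlation needs at least 2 edges")
  idx <- topology_indices(topology, colnames(expression))
  r <- expression[i, idx$regulator] * idx$sign
  t_ <- expression[j, idx$target]
  if (stats::sd(r) == 0 || stats::sd(t_) == 0) return(NA_real_)
  stats::cor(r, t_)
}

#' Embedding space for vector inference
#'
#' The coordinates in which neighborhoods are found and transition vectors
#' expressed: network-gene expression, principal components, or any other
#' user-supplied per-cell coordinates.
#'
#' @param coords cells x m matrix (m >= 2), finite.
#' @param tag label for the space (e.g., "genes", "pca").
#' @return A list of class `embedding_space` with `coords`,
#'   `max_pairwise_distance`, the full distance matrix `dist`, and `tag`.
#' @export
embedding_space <- function(coords, tag = "genes") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) >= 2, all(is.finite(coords)))
  D <- as.matrix(stats::dist(coords))
  mx <- max(D)
  if (mx <= 0) stop("all cells coincide; embedding is degenerate")
  structure(list(coords = coords, dist = D, max_pairwise_distance = mx,
                 tag = tag),
            class = "embedding_space")
}

#' Find the radius neighborhood of a cell
#'
#' Neighbors are all other cells within `radius_fraction` times the
#' maximum pairwise distance of the embedding, in increasing index order.
#'
#' @param space an [embedding_space()].
#' @param i center cell index.
#' @param radius_fraction radius as a fraction of the maximum pairwise
#'   distance, in (0, 1].
#' @return Integer vector of neighbor indices (excluding i).
#' @export
find_neighbors <- function(space, i, radius_fraction) {
  stopifnot(inherits(space, "embedding_space"),
            radius_fraction > 0, radius_fraction <= 1)
  r <- radius_fraction * space$max_pairwise_distance
  nb <- which(unname(space$dist[i, ]) <= r)
  nb[nb != i]
}

# Minimum-norm least squares; returns list(coef, rank_deficient).
lsq_solve <- function(X, y) {
  q <- qr(X)
  if (q$rank == ncol(X)) {
    list(coef = qr.coef(q, y), rank_deficient = FALSE)
  } else {
    sv <- svd(X)
    tol <- max(dim(X)) * max(sv$d) * .Machine$double.eps
    dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
    list(coef = drop(sv$v %*% (dinv * crossprod(sv$u, y))),
         rank_deficient = TRUE)
  }
}

# Shared regression core for outgoing/incoming fits. ccc may be a
# ccc_context or a plain n x n CCC matrix. Returns a "sticc_fit" list or
# NULL with a reason when the cell is invalid.
fit_vector <- function(ccc, space, i, neighbors, direction,
                       min_neighbors = 15) {
  C <- if (inherits(ccc, "ccc_context")) ccc$ccc else ccc
  self <- C[i, i]
  if (is.na(self))
    return(structure(list(reason = "degenerate center"), class = "sticc_skip"))
  y_raw <- if (direction == "outgoing") C[i, neighbors] else C[neighbors, i]
  ok <- !is.na(y_raw)
  neighbors <- neighbors[ok]
  y <- y_raw[ok] - self
  if (length(neighbors) < min_neighbors)
    return(structure(list(reason = "insufficient neighborhood",
                          n_used = length(neighbors)),
                     class = "sticc_skip"))
  X <- space$coords[neighbors, , drop = FALSE] -
    matrix(space$coords[i, ], length(neighbors), ncol(space$coords),
           byrow = TRUE)
  sol <- lsq_solve(X, y)
  v <- sol$coef
  if (direction == "incoming") v <- -v
  fitted <- drop(X %*% sol$coef)
  resid <- y - fitted
  big <- abs(y) >= 1e-9
  mape <- if (any(big)) stats::median(abs(resid[big] / y[big])) * 100 else NA_real_
  structure(list(v = unname(v), X = X, y = unname(y), fitted = fitted,
                 residuals = resid, mape = mape, n_used = length(neighbors),
                 rank_deficient = sol$rank_deficient),
            class = "sticc_fit")
}

#' Infer the outgoing transition vector of one cell
#'
#' Fits the local linear model `y1 = X v1 + eps`, where row j of `X` is the
#' relative position `x_j - x_i` of neighbor j and `y1_j = rho_{i->j} -
#' rho_{i->i}` is the relative outgoing CCC, and returns the least-squares
#' estimate `v1 = (X'X)^{-1} X' y1` (minimum-norm pseudo-inverse solution,
#' flagged, when X is rank-deficient). `v1` points along the steepest
#' increase of outgoing CCC: the likely future state.
#'
#' @param ccc a [ccc_context()] or a plain cells x cells CCC matrix.
#' @param space an [embedding_space()].
#' @param i center cell index.
#' @param neighbors indices from [find_neighbors()].
#' @param min_neighbors minimum usable neighbors for a valid fit.
#' @return A `sticc_fit` list (v, X, y, fitted, residuals, mape, n_used,
#'   rank_deficient), or a `sticc_skip` carrying the reason the cell is
#'   invalid.
#' @export
infer_outgoing <- function(ccc, space, i, neighbors, min_neighbors = 15) {
  fit_vector(ccc, space, i, neighbors, "outgoing", min_neighbors)
}

#' Infer the incoming transition vector of one cell
#'
#' As [infer_outgoing()] but with `y2_j = rho_{j->i} - rho_{i->i}` and the
#' estimator negated (`v2 = -(X'X)^{-1} X' y2`), so that `v2` also points
#' away from likely precursor states, in the same orientation as `v1`.
#'
#' @inheritParams infer_outgoing
#' @export
infer_incoming <- function(ccc, space, i, neighbors, min_neighbors = 15) {
  fit_vector(ccc, space, i, neighbors, "incoming", min_neighbors)
}

#' Decompose outgoing/incoming vectors into net flow and reversibility
#'
#' Net flow `(v1 + v2) / 2` is the irreversible component of the local
#' state transition; reversibility `(v1 - v2) / 2` is the bidirectional
#' (sign-free) component. The identities `net + rev = v1` and
#' `net - rev = v2` hold exactly.
#'
#' @param v1,v2 numeric vectors of equal length (or matrices of equal
#'   shape).
#' @return list(net_flow, reversibility).
#' @export
decompose_vectors <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("v1 and v2 must have the same dimension")
  list(net_flow = (v1 + v2) / 2, reversibility = (v1 - v2) / 2)
}

#' Infer per-cell state transition vectors from expression and a GRN
#'
#' The main fitting function. For every cell it computes the outgoing and
#' incoming transition vectors by local least-squares regression of
#' relative cross-cell correlations on relative position (see
#' [infer_outgoing()] / [infer_incoming()]), then decomposes them into net
#' flow and reversibility. CCCs are always computed on the network-gene
#' expression; the regression (and the returned vectors) live in `space`,
#' which defaults to the network-gene expression itself but may be a PCA
#' or any user-supplied embedding.
#'
#' @param topology a [grn_topology()] with >= 2 edges.
#' @param expression cells x genes matrix covering the network genes,
#'   already log-normalized or z-scored as appropriate (used as supplied).
#' @param space optional [embedding_space()] or cells x m coordinate
#'   matrix; "pca" computes a PCA of the network-gene expression and uses
#'   the first `n_pcs` components.
#' @param radius sampling radius as a fraction of the maximum pairwise
#'   distance in `space` (default 0.15).
#' @param min_neighbors minimum usable neighbors for a valid cell
#'   (default 15).
#' @param n_pcs number of components when `space = "pca"`.
#' @param verbose print a one-line summary.
#' @return An object of class `sticc`: per-cell matrices `v1`, `v2`,
#'   `net_flow`, `reversibility` (cells x m, NA rows for invalid cells),
#'   logical `valid`, character `reason`, integer `n_neighbors` (cells in
#'   radius) and `n_used` (neighbors entering the fit), per-cell `mape`
#'   (percent), the `space`, `radius`, `min_neighbors`, `topology` and
#'   `call`.
#' @examples
#' \donttest{
#' top <- builtin_circuit("REP")
#' snap <- simulate_steady_states(top, 300, sim_config(seed = 1))
#' fit <- sticc(top, normalize_log(snap), space = "pca", radius = 0.2)
#' summary(fit)
#' }
#' @export
sticc <- function(topology, expression, space = NULL, radius = 0.15,
                  min_neighbors = 15, n_pcs = 2, verbose = FALSE) {
  cl <- match.call()
  ctx <- ccc_context(topology, expression)
  n <- nrow(ctx$expression)
  if (n < min_neighbors + 1)
    stop("only ", n, " cells: no cell can reach min_neighbors = ",
         min_neighbors)
  if (is.null(space)) {
    space <- embedding_space(ctx$expression, tag = "genes")
  } else if (identical(space, "pca")) {
    pr <- pca_project(expression, n_components = n_pcs)
    space <- embedding_space(pr$coords, tag = sprintf("pca:%d", n_pcs))
  } else if (!inherits(space, "embedding_space")) {
    space <- embedding_space(as.matrix(space), tag = "coords")
  }
  if (nrow(space$coords) != n)
    stop("expression and space describe different numbers of cells")
  m <- ncol(space$coords)
  v1 <- v2 <- matrix(NA_real_, n, m,
                     dimnames = list(rownames(ctx$expression),
                                     colnames(space$coords)))
  valid <- rep(FALSE, n)
  reason <- rep("", n)
  n_nb <- n_used <- integer(n)
  mape <- rep(NA_real_, n)
  rankdef <- rep(FALSE, n)
  for (i in seq_len(n)) {
    nb <- find_neighbors(space, i, radius)
    n_nb[i] <- length(nb)
    f1 <- infer_outgoing(ctx, space, i, nb, min_neighbors)
    if (inherits(f1, "sticc_skip")) {
      reason[i] <- f1$reason
      n_used[i] <- f1$n_used %||% 0L
      next
    }
    f2 <- infer_incoming(ctx, space, i, nb, min_neighbors)
    v1[i, ] <- f1$v
    v2[i, ] <- f2$v
    valid[i] <- TRUE
    n_used[i] <- f1$n_used
    mape[i] <- f1$mape
    rankdef[i] <- f1$rank_deficient || f2$rank_deficient
  }
  if (!any(valid))
    stop("no valid cells: radius too small for min_neighbors = ",
         min_neighbors, ", or the network/expression is degenerate")
  dec <- decompose_vectors(v1, v2)
  out <- structure(list(v1 = v1, v2 = v2, net_flow = dec$net_flow,
                        reversibility = dec$reversibility, valid = valid,
                        reason = reason, n_neighbors = n_nb, n_used = n_used,
                        mape = mape, rank_deficient = rankdef, space = space,
                        radius = radius, min_neighbors = min_neighbors,
                        topology = topology, call = cl),
                   class = "sticc")
  if (verbose) {
    nf <- sqrt(rowSums(out$net_flow^2))
    rv <- sqrt(rowSums(out$reversibility^2))
    message(sprintf(
      "sticc: %d/%d valid cells (radius %.3g, space %s); median |net| %.3g, median |rev| %.3g",
      sum(valid), n, radius, space$tag,
      stats::median(nf[valid]), stats::median(rv[valid])))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimize the sampling radius by coverage / MAPE
#'
#' Grid search over candidate radii (default: 11 evenly spaced values on
#' [0.05, 0.30]). For each radius it computes coverage, the fraction of
#' cells whose neighborhood holds at least `min_neighbors` usable cells,
#' and MAPE, the median over valid cells of the per-cell median absolute
#' percentage error of the outgoing-CCC regression (components with
#' |y| < 1e-9 excluded). The selected radius maximizes coverage / MAPE;
#' ties go to the smaller radius.
#'
#' @inheritParams sticc
#' @param radii candidate radii (fractions of the maximum pairwise
#'   distance).
#' @return list(radius, table) where `table` has columns radius, coverage,
#'   mape and score.
#' @export
optimize_radius <- function(topology, expression, space = NULL,
                            radii = seq(0.05, 0.30, by = 0.025),
                            min_neighbors = 15, n_pcs = 2) {
  ctx <- ccc_context(topology, expression)
  n <- nrow(ctx$expression)
  if (n < min_neighbors + 1)
    stop("need at least min_neighbors + 1 cells")
  if (is.null(space)) {
    space <- embedding_space(ctx$expression, tag = "genes")
  } else if (identical(space, "pca")) {
    pr <- pca_project(expression, n_components = n_pcs)
    space <- embedding_space(pr$coords, tag = sprintf("pca:%d", n_pcs))
  } else if (!inherits(space, "embedding_space")) {
    space <- embedding_space(as.matrix(space), tag = "coords")
  }
  rows <- lapply(radii, function(r) {
    mapes <- rep(NA_real_, n)
    covered <- logical(n)
    for (i in seq_len(n)) {
      nb <- find_neighbors(space, i, r)
      f <- infer_outgoing(ctx, space, i, nb, min_neighbors)
      if (!inherits(f, "sticc_skip")) {
        covered[i] <- TRUE
        mapes[i] <- f$mape
      }
    }
    data.frame(radius = r, coverage = mean(covered),
               mape = stats::median(mapes[covered], na.rm = TRUE))
  })
  tab <- do.call(rbind, rows)
  if (all(tab$coverage == 0))
    stop("zero coverage at every candidate radius; try a larger grid")
  tab$score <- ifelse(tab$coverage > 0, tab$coverage / tab$mape, -Inf)
  best <- which(tab$score == max(tab$score, na.rm = TRUE))[1]
  list(radius = tab$radius[best], table = tab)
}
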