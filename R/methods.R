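#' @export
print.sticc <- function(x, ...) {
  cat("State transition vectors (cross-cell correlation inference)\n")
  cat(sprintf("  cells: %d (%d valid), space: %s (%d dims), radius: %g\n",
              length(x$valid), sum(x$valid), x$space$tag,
              ncol(x$space$coords), x$radius))
  invisible(x)
}

#' @export
summary.sticc <- function(object, ...) {
  v <- object$valid
  mag <- function(M) sqrt(rowSums(M^2))
  out <- list(
    n_cells = length(v),
    n_valid = sum(v),
    invalid_reasons = table(object$reason[!v & nzchar(object$reason)]),
    radius = object$radius,
    space = object$space$tag,
    median_net_flow = stats::median(mag(object$net_flow)[v]),
    median_reversibility = stats::median(mag(object$reversibility)[v]),
    median_v1 = stats::median(mag(object$v1)[v]),
    median_v2 = stats::median(mag(object$v2)[v]),
    median_neighbors = stats::median(object$n_used[v]),
    mape = stats::median(object$mape[v], na.rm = TRUE))
  class(out) <- "summary.sticc"
  out
}

#' @export
print.summary.sticc <- function(x, ...) {
  cat("State transition vector field\n")
  cat(sprintf("  cells             : %d (%d valid)\n", x$n_cells, x$n_valid))
  cat(sprintf("  space / radius    : %s / %g\n", x$space, x$radius))
  cat(sprintf("  median |v1|, |v2| : %.4g, %.4g\n", x$median_v1, x$median_v2))
  cat(sprintf("  median |net flow| : %.4g\n", x$median_net_flow))
  cat(sprintf("  median |revers.|  : %.4g\n", x$median_reversibility))
  cat(sprintf("  median neighbors  : %g\n", x$median_neighbors))
  cat(sprintf("  regression MAPE   : %.4g%%\n", x$mape))
  if (length(x$invalid_reasons)) {
    cat("  invalid cells     :",
        paste(sprintf("%s (%d)", names(x$invalid_reasons),
                      as.integer(x$invalid_reasons)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-cell vector table
#'
#' Flattens a fitted `sticc` object into the canonical per-cell table:
#' cell id, space tag, coordinates, v1/v2/net/rev components, neighborhood
#' size, validity and reason.
#'
#' @param x a [sticc()] fit.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame, one row per cell.
#' @export
as.data.frame.sticc <- function(x, row.names = NULL, optional = FALSE, ...) {
  m <- ncol(x$space$coords)
  dims <- seq_len(m)
  cmp <- function(M, pre) {
    out <- as.data.frame(M)
    names(out) <- paste0(pre, dims)
    out
  }
  cbind(data.frame(cell_id = rownames(x$v1) %||% as.character(seq_along(x$valid)),
                   space = x$space$tag, stringsAsFactors = FALSE),
        cmp(x$space$coords, "x"), cmp(x$v1, "v1_"), cmp(x$v2, "v2_"),
        cmp(x$net_flow, "net_"), cmp(x$reversibility, "rev_"),
        data.frame(n_neighbors = x$n_neighbors, n_used = x$n_used,
                   valid = x$valid, reason = x$reason))
}

#' Plot a transition vector field
#'
#' Draws the cells in the first two dimensions of the embedding with
#' arrows for the chosen vector component, optionally grid-smoothed for
#' readability.
#'
#' @param x a [sticc()] fit.
#' @param component one of "net", "rev", "v1", "v2".
#' @param smooth if TRUE (default), arrows show the inverse-distance
#'   grid-smoothed field ([grid_smooth()]); otherwise per-cell vectors.
#' @param grid_size smoothing grid resolution.
#' @param scale arrow length multiplier (auto-chosen if NULL).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sticc <- function(x, component = c("net", "rev", "v1", "v2"),
                       smooth = TRUE, grid_size = 20, scale = NULL, ...) {
  component <- match.arg(component)
  V <- switch(component, net = x$net_flow, rev = x$reversibility,
              v1 = x$v1, v2 = x$v2)
  co <- x$space$coords[, 1:2, drop = FALSE]
  vv <- V[, 1:2, drop = FALSE]
  keep <- x$valid
  graphics::plot(co, col = ifelse(x$valid, "grey60", "grey90"), pch = 16,
                 cex = 0.5, xlab = colnames(co)[1] %||% "dim 1",
                 ylab = colnames(co)[2] %||% "dim 2",
                 main = paste("component:", component), ...)
  if (smooth) {
    sf <- grid_smooth(co[keep, , drop = FALSE], vv[keep, , drop = FALSE],
                      grid_size = grid_size,
                      influence_radius = x$radius * x$space$max_pairwise_distance)
    ok <- sf$occupied
    x0 <- sf$grid[ok, 1]; y0 <- sf$grid[ok, 2]
    vx <- sf$vectors[ok, 1]; vy <- sf$vectors[ok, 2]
  } else {
    x0 <- co[keep, 1]; y0 <- co[keep, 2]
    vx <- vv[keep, 1]; vy <- vv[keep, 2]
  }
  if (is.null(scale)) {
    span <- max(apply(co, 2, function(z) diff(range(z))))
    vmax <- max(sqrt(vx^2 + vy^2), na.rm = TRUE)
    scale <- if (vmax > 0) 0.05 * span / vmax else 1
  }
  nz <- sqrt(vx^2 + vy^2) > 0
  graphics::arrows(x0[nz], y0[nz], x0[nz] + scale * vx[nz],
                   y0[nz] + scale * vy[nz],
                   length = 0.04, col = "firebrick")
  invisible(x)
}
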