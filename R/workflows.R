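# End-to-end workflow wrappers: thin file-in/file-out layers over the
# package functions, also driven by the exec/sticc command-line script.
# Every table they write starts with commented provenance lines (tool
# version, seed, parameters) and is read back with comment.char = "#".

provenance_header <- function(seed = NULL, ...) {
  extra <- list(...)
  lines <- c(sprintf("# sticc %s",
                     as.character(utils::packageVersion("sticc"))),
             sprintf("# seed: %s", if (is.null(seed)) "NA" else seed))
  if (length(extra))
    lines <- c(lines, sprintf("# %s: %s", names(extra),
                              vapply(extra, function(x)
                                paste(format(x), collapse = " "),
                                character(1))))
  lines
}

write_provenance_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

resolve_topology <- function(topology) {
  if (inherits(topology, "grn_topology")) return(topology)
  if (is.character(topology) && length(topology) == 1) {
    if (toupper(topology) %in% c("REP", "CTS", "IFFL", "TSREP"))
      return(builtin_circuit(topology))
    return(read_topology(topology))
  }
  stop("topology must be a grn_topology, a builtin circuit name, or a file path")
}

#' Simulate a circuit and write the expression files
#'
#' Runs the RACIPE-style ensemble for a topology (or builtin circuit name),
#' optionally applies dropout, log-normalizes, and writes the matrices
#' under `out_dir`: `expression_raw.tsv`, `expression_log.tsv` (and
#' `expression_dropout.tsv` when dropout is requested), plus a `manifest.tsv`
#' recording the settings.
#'
#' @param topology a [grn_topology()], builtin circuit name, or topology
#'   file path.
#' @param n_models ensemble size.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param config a [sim_config()] (its seed is overridden by `seed`).
#' @param dropProb,dropQuantile optional dropout settings (dropProb > 0
#'   triggers the dropout variant).
#' @param signal optional [signal_schedule()] or "gene:fold:rise:hold:fall"
#'   string.
#' @return Invisibly, the log-scale expression matrix.
#' @export
sticc_simulate <- function(topology, n_models = 2000, out_dir = ".",
                           seed = 1, config = sim_config(),
                           dropProb = 0, dropQuantile = 0.2, signal = NULL) {
  top <- resolve_topology(topology)
  if (is.character(signal)) signal <- parse_signal_spec(signal)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- seed
  raw <- simulate_steady_states(top, n_models, config, signal = signal)
  write_expression(raw, file.path(out_dir, "expression_raw.tsv"))
  logm <- normalize_log(raw)
  write_expression(logm, file.path(out_dir, "expression_log.tsv"))
  if (dropProb > 0) {
    dr <- apply_dropout(raw, dropProb, dropQuantile, seed = seed + 1L)
    write_expression(normalize_log(dr),
                     file.path(out_dir, "expression_dropout.tsv"))
  }
  manifest <- data.frame(
    key = c("circuit_genes", "n_models", "n_retained", "seed", "step_size",
            "total_time", "noise_level", "dropProb", "dropQuantile"),
    value = c(paste(top$genes, collapse = ","), n_models, nrow(raw), seed,
              config$step_size, config$total_time, config$noise_level,
              dropProb, dropQuantile))
  write_provenance_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                       provenance_header(seed))
  invisible(logm)
}

parse_signal_spec <- function(spec) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 5)
    stop("signal spec must be gene:fold:t_rise:t_hold:t_fall")
  signal_schedule(parts[1], as.numeric(parts[2]), as.numeric(parts[3]),
                  as.numeric(parts[4]), as.numeric(parts[5]))
}

resolve_space <- function(space_spec, expression, n_pcs = 2) {
  if (is.null(space_spec) || identical(space_spec, "genes")) return(NULL)
  if (is.character(space_spec) && length(space_spec) == 1) {
    if (grepl("^pca(:[0-9]+)?$", space_spec)) {
      k <- sub("^pca:?", "", space_spec)
      n_pcs <- if (nzchar(k)) as.integer(k) else n_pcs
      return(embedding_space(pca_project(expression, n_pcs)$coords,
                             tag = sprintf("pca:%d", n_pcs)))
    }
    co <- read_expression(space_spec, scale = "raw")
    return(embedding_space(co, tag = "coords"))
  }
  if (inherits(space_spec, "embedding_space")) return(space_spec)
  embedding_space(as.matrix(space_spec), tag = "coords")
}

#' Run vector inference end to end and write the result tables
#'
#' Loads (or accepts) a topology and expression matrix, optionally
#' optimizes the sampling radius, fits [sticc()], and writes the per-cell
#' vector table `vectors.tsv`, the smoothed field `smoothed_field.tsv` and
#' a `run_log.tsv` of diagnostics under `out_dir`.
#'
#' @param topology as in [sticc_simulate()].
#' @param expression cells x genes matrix or TSV/CSV path.
#' @param space_spec "genes", "pca", "pca:<k>", a coordinates file path, or
#'   a coordinate matrix.
#' @param radius numeric sampling radius, or "auto" to grid-search via
#'   [optimize_radius()].
#' @param min_neighbors per-cell validity cutoff.
#' @param out_dir output directory.
#' @param seed recorded in provenance (the fit itself is deterministic).
#' @return Invisibly, the [sticc()] fit.
#' @export
sticc_run <- function(topology, expression, space_spec = "genes",
                      radius = 0.15, min_neighbors = 15, out_dir = ".",
                      seed = 1) {
  top <- resolve_topology(topology)
  if (is.character(expression)) expression <- read_expression(expression)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- resolve_space(space_spec, expression)
  diag_tab <- NULL
  if (identical(radius, "auto")) {
    opt <- optimize_radius(top, expression, space = space,
                           min_neighbors = min_neighbors)
    radius <- opt$radius
    diag_tab <- opt$table
    message("optimized radius: ", radius)
  }
  radius <- as.numeric(radius)
  fit <- sticc(top, expression, space = space, radius = radius,
               min_neighbors = min_neighbors, verbose = TRUE)
  hdr <- provenance_header(seed, radius = radius,
                           min_neighbors = min_neighbors,
                           space = fit$space$tag)
  write_provenance_tsv(as.data.frame(fit),
                       file.path(out_dir, "vectors.tsv"), hdr)
  keep <- fit$valid
  sf <- grid_smooth(fit$space$coords[keep, 1:2, drop = FALSE],
                    fit$net_flow[keep, 1:2, drop = FALSE],
                    influence_radius = radius * fit$space$max_pairwise_distance)
  sf_df <- data.frame(x = sf$grid[, 1], y = sf$grid[, 2],
                      vx = sf$vectors[, 1], vy = sf$vectors[, 2],
                      n_contributors = sf$n_contributors)
  write_provenance_tsv(sf_df, file.path(out_dir, "smoothed_field.tsv"), hdr)
  s <- summary(fit)
  log_df <- data.frame(key = c("n_cells", "n_valid", "radius",
                               "median_net_flow", "median_reversibility",
                               "mape"),
                       value = c(s$n_cells, s$n_valid, radius,
                                 s$median_net_flow, s$median_reversibility,
                                 s$mape))
  if (!is.null(diag_tab)) {
    log_df <- rbind(log_df,
                    data.frame(key = sprintf("coverage_r%.3f", diag_tab$radius),
                               value = diag_tab$coverage))
  }
  write_provenance_tsv(log_df, file.path(out_dir, "run_log.tsv"), hdr)
  invisible(fit)
}

#' Edge-sensitivity workflow: perturb, re-fit, write the ranking table
#'
#' @inheritParams sticc_run
#' @param perturbations list of [perturb_topology()] argument lists, or
#'   "nodes:outgoing" / "nodes:incoming" / "nodes:both" to sweep every gene.
#' @return Invisibly, the [edge_sensitivity()] table.
#' @export
sticc_sensitivity <- function(topology, expression, space_spec = "genes",
                              perturbations = "nodes:outgoing",
                              radius = 0.15, min_neighbors = 15,
                              out_dir = ".", seed = 1) {
  top <- resolve_topology(topology)
  if (is.character(expression)) expression <- read_expression(expression)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  space <- resolve_space(space_spec, expression)
  if (is.character(perturbations) && grepl("^nodes:", perturbations))
    perturbations <- node_perturbations(top, sub("^nodes:", "", perturbations))
  tab <- edge_sensitivity(top, expression, space = space,
                          perturbations = perturbations,
                          radius = as.numeric(radius),
                          min_neighbors = min_neighbors)
  write_provenance_tsv(as.data.frame(tab),
                       file.path(out_dir, "sensitivity.tsv"),
                       provenance_header(seed, radius = radius))
  invisible(tab)
}

#' Trajectory-validation workflow: score predictions, write the report
#'
#' @inheritParams sticc_run
#' @param fit a [sticc()] fit (from [sticc_run()] or [sticc()]).
#' @param traj_coords2d time x 2 projected trajectory (same space as
#'   `fit`), or a TSV path with a time column followed by 2 coordinates.
#' @param queries q x 2 matrix of query points, or NULL to auto-place them
#'   on [estimate_basins()] centers and their midpoints.
#' @param component,lag,target_rmsd,capture_fraction see
#'   [validate_against_trajectory()].
#' @return Invisibly, the validation report data.frame.
#' @export
sticc_validate <- function(fit, traj_coords2d, queries = NULL,
                           component = "net", lag = NULL, target_rmsd = NULL,
                           capture_fraction = 0.02, out_dir = ".", seed = 1) {
  if (is.character(traj_coords2d)) {
    df <- utils::read.table(traj_coords2d, header = TRUE, sep = "\t",
                            comment.char = "#")
    traj_coords2d <- as.matrix(df[, -1, drop = FALSE])[, 1:2]
  }
  if (is.null(queries)) {
    centers <- estimate_basins(fit$space$coords[fit$valid, 1:2, drop = FALSE])
    queries <- centers
    if (nrow(centers) >= 2) {
      pairs <- utils::combn(nrow(centers), 2)
      mids <- t(apply(pairs, 2, function(p)
        colMeans(centers[p, , drop = FALSE])))
      queries <- rbind(centers, mids)
    }
  }
  rep_df <- validate_against_trajectory(fit, traj_coords2d, queries,
                                        component = component, lag = lag,
                                        target_rmsd = target_rmsd,
                                        capture_fraction = capture_fraction)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_provenance_tsv(rep_df, file.path(out_dir, "validation.tsv"),
                       provenance_header(seed, component = component))
  invisible(rep_df)
}
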