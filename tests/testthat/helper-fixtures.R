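# Shared simulated fixtures, built once per test run and cached.
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache))
    assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# Repressilator RACIPE snapshot (ensemble steady states), log scale + PCA fit.
fx_rep <- function() fx("rep", function() {
  top <- builtin_circuit("REP")
  raw <- simulate_steady_states(top, 2000, sim_config(seed = 11))
  logm <- normalize_log(raw)
  pr <- pca_project(logm, 2)
  space <- embedding_space(pr$coords, "pca:2")
  fit <- sticc(top, logm, space = space, radius = 0.15)
  list(top = top, raw = raw, log = logm, pr = pr, space = space, fit = fit)
})

# Coupled toggle switch snapshot + fit.
fx_cts <- function() fx("cts", function() {
  top <- builtin_circuit("CTS")
  raw <- simulate_steady_states(top, 2000, sim_config(seed = 12))
  logm <- normalize_log(raw)
  pr <- pca_project(logm, 2)
  space <- embedding_space(pr$coords, "pca:2")
  fit <- sticc(top, logm, space = space, radius = 0.15)
  list(top = top, raw = raw, log = logm, pr = pr, space = space, fit = fit)
})

# Noisy repressilator limit-cycle trajectory with a deterministic reference
# cycle, snapshot subsample, fit, and the trajectory in the snapshot PCA.
fx_rep_traj <- function() fx("rep_traj", function() {
  top <- builtin_circuit("REP")
  p <- rep_cycle_params()
  det <- simulate_trajectory_sde(top, p, sim_config(total_time = 1500,
                                                    print_interval = 0.5,
                                                    seed = 5))
  cyc <- det$states[2001:2400, ]
  tr <- simulate_trajectory_sde(top, p,
          sim_config(total_time = 4000, print_interval = 0.5,
                     noise_level = 0.05, seed = 21),
          noise_ref = colMeans(cyc))
  set.seed(22)
  keep <- sort(sample(nrow(tr$states), 2000))
  snap <- tr$states[keep, ]
  rownames(snap) <- paste0("c", seq_len(nrow(snap)))
  attr(snap, "scale") <- "raw"
  logm <- normalize_log(snap)
  pr <- pca_project(logm, 2)
  space <- embedding_space(pr$coords, "pca:2")
  fit <- sticc(top, logm, space = space, radius = 0.15)
  traj2d <- pca_transform(pr$model, normalize_log(tr$states))
  cyc2d <- pca_transform(pr$model, normalize_log(cyc))
  # 12 query points evenly spaced in angle around the cycle
  ctr <- colMeans(cyc2d)
  ang <- atan2(cyc2d[, 2] - ctr[2], cyc2d[, 1] - ctr[1])
  want <- seq(-pi, pi, length.out = 13)[-13]
  qi <- vapply(want, function(w)
    which.min(abs(atan2(sin(ang - w), cos(ang - w)))), integer(1))
  list(top = top, params = p, cyc2d = cyc2d, traj2d = traj2d,
       fit = fit, space = space, queries = cyc2d[qi, ])
})

# A tiny unregulated topology useful for analytic checks: two genes, two
# edges so the CCC is defined, but A and B regulate a third pair only.
fx_two_edge_top <- function() {
  grn_topology(c("A", "B", "C", "D"),
               data.frame(source = c("A", "B"), target = c("C", "D"),
                          sign = c(1L, 1L)))
}

expect_matrix_equal <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a - b)) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
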