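test_that("shifted Hill factor matches its closed form", {
  expect_equal(shifted_hill(0, 5, 3, 0.1), 1)
  expect_equal(shifted_hill(5, 5, 3, 0.1), (1 + 0.1) / 2)
  expect_equal(shifted_hill(5, 5, 3, 40), (1 + 40) / 2)
  expect_lt(abs(shifted_hill(1e6 * 3, 3, 2, 0.25) - 0.25), 1e-9)
  expect_lt(abs(shifted_hill(1e6 * 3, 3, 2, 7) - 7), 1e-9)
  expect_error(shifted_hill(-1, 5, 3, 0.1))
  expect_error(shifted_hill(1, -5, 3, 0.1))
})

test_that("sampled kinetic parameters respect the RACIPE ranges", {
  top <- builtin_circuit("CTS")
  p <- sample_parameters(top, n_models = 2500, seed = 42)
  expect_true(all(p$G >= 1 & p$G <= 100))
  expect_true(all(p$k >= 0.1 & p$k <= 1))
  expect_true(all(p$n %in% 1:6))
  act <- top$edges$sign == 1
  expect_true(all(p$lambda[, act] > 1 & p$lambda[, act] < 100))
  expect_true(all(p$lambda[, !act] > 0.01 & p$lambda[, !act] < 1))
  expect_true(all(p$threshold > 0))
  # G is uniform on [1, 100]: KS test at n = 10^4
  ks <- stats::ks.test(as.vector(p$G), "punif", 1, 100)
  expect_gt(ks$p.value, 0.001)
  # thresholds stay inside the half-functional window of their regulator
  src <- match(top$edges$source, top$genes)
  M <- p$G[, src] / (2 * p$k[, src])
  expect_true(all(p$threshold >= 0.02 * M & p$threshold <= 1.98 * M))
  # reproducible from seed
  p2 <- sample_parameters(top, n_models = 2500, seed = 42)
  expect_identical(p, p2)
})

test_that("circuit derivative matches hand-evaluated kinetics", {
  iso <- grn_topology(c("A", "B"),
                      data.frame(source = "A", target = "B", sign = 1L))
  p <- make_params(iso, G = c(10, 20), k = c(0.5, 1), lambda = 2, n = 2,
                   threshold = 4)
  # A has no regulators: dA/dt = G - kA; zero at the fixed point G/k
  d <- circuit_derivative(c(A = 3, B = 0), iso, p)
  expect_equal(d[["A"]], 10 - 0.5 * 3)
  d0 <- circuit_derivative(c(A = 10 / 0.5, B = 0), iso, p)
  expect_equal(d0[["A"]], 0)
  # B activated by A: (G_B / lambda) * shifted_hill(A) - k_B * B
  expect_equal(d[["B"]], 20 / 2 * shifted_hill(3, 4, 2, 2))
  # with all regulators at zero an inhibited gene produces at rate G
  rep <- builtin_circuit("REP")
  pr <- make_params(rep, G = 10, k = 0.1, lambda = 0.05, n = 4,
                    threshold = 35)
  dr <- circuit_derivative(c(A = 0, B = 0, C = 0), rep, pr)
  expect_equal(unname(dr), rep(10, 3))
  expect_error(circuit_derivative(c(A = -1, B = 0), iso, p), "non-negative")
  expect_error(
    sticc:::derivative_matrix(matrix(1, 1, 2), p,
                              signal_schedule("Z", 2, 1, 1, 1), 0),
    "unknown signal target")
})

test_that("signal schedules are piecewise linear with the stated phases", {
  s <- signal_schedule("D", 50, 20, 20, 20)
  expect_equal(signal_factor(s, c(0, 10, 20, 30, 40, 50, 60, 100)),
               c(1, 25.5, 50, 50, 50, 25.5, 1, 1))
})

test_that("steady-state ensembles find analytic fixed points and are reproducible", {
  # single unregulated gene pair: steady state G/k per gene
  iso <- grn_topology(c("A", "B"),
                      data.frame(source = c("A", "B"), target = c("B", "A"),
                                 sign = c(1L, 1L)))
  top1 <- grn_topology("A", data.frame(source = character(),
                                       target = character(),
                                       sign = integer()))
  # degenerate edge-free circuit still integrates (production = G)
  m <- simulate_steady_states(top1, 20, sim_config(seed = 3, total_time = 200))
  p <- attr(m, "params")
  expect_lt(max(abs(m[, 1] - p$G[, 1] / p$k[, 1]) / (p$G[, 1] / p$k[, 1])),
            1e-3)
  expect_equal(attr(m, "scale"), "raw")
  # bit-identical rerun from the same seed
  m2 <- simulate_steady_states(top1, 20, sim_config(seed = 3, total_time = 200))
  expect_identical(m, m2)
})

test_that("REP ensembles are rotationally symmetric and CTS ensembles cluster", {
  # repressilator snapshots respect the circuit's three-fold symmetry:
  # every gene dominates a substantial share of cells, and no tight
  # two-cluster structure exists
  rep <- fx_rep()
  dom <- apply(rep$log, 1, which.max)
  expect_true(all(table(factor(dom, levels = 1:3)) / nrow(rep$log) > 0.1))
  km_rep <- stats::kmeans(rep$pr$coords, 2, nstart = 10)
  sil_rep <- local({
    d1 <- sqrt(rowSums((rep$pr$coords - km_rep$centers[km_rep$cluster, ])^2))
    d2 <- sqrt(rowSums((rep$pr$coords - km_rep$centers[3 - km_rep$cluster, ])^2))
    mean((d2 - d1) / pmax(d1, d2))
  })

  # coupled toggle switch: two well-separated major clusters
  cts <- fx_cts()
  km <- stats::kmeans(cts$pr$coords, 2, nstart = 10)
  sil <- local({
    d1 <- sqrt(rowSums((cts$pr$coords - km$centers[km$cluster, ])^2))
    d2 <- sqrt(rowSums((cts$pr$coords - km$centers[3 - km$cluster, ])^2))
    mean((d2 - d1) / pmax(d1, d2))
  })
  expect_gt(sil, 0.3)
  expect_gt(sil, sil_rep)
})

test_that("zero-noise SDE paths equal deterministic Euler integration", {
  top <- builtin_circuit("REP")
  p <- rep_cycle_params()
  cfg <- sim_config(total_time = 20, print_interval = 1, step_size = 0.02,
                    seed = 9)
  tr <- simulate_trajectory_sde(top, p, cfg, init = c(10, 20, 30))
  # independent fixed-step Euler oracle
  S <- c(10, 20, 30)
  rec <- NULL
  for (s in 1:(20 / 0.02)) {
    S <- S + 0.02 * circuit_derivative(S, top, p)
    S[S < 0] <- 0
    if (s %% 50 == 0) rec <- rbind(rec, S)
  }
  expect_lt(max(abs(tr$states - rec)), 1e-12)
})

test_that("isolated-gene trajectories follow the exponential closed form", {
  iso <- grn_topology(c("A", "B"),
                      data.frame(source = c("A", "B"), target = c("B", "A"),
                                 sign = c(1L, 1L)))
  # disable cross-activation by saturating both thresholds high and lambda ~ 1
  p <- make_params(iso, G = c(8, 8), k = c(0.4, 0.4), lambda = 1 + 1e-12,
                   n = 1, threshold = 1e6)
  tr <- simulate_trajectory_sde(iso, p, sim_config(total_time = 10,
                                                   print_interval = 0.5,
                                                   step_size = 0.001),
                                init = c(0, 0))
  expected <- (8 / 0.4) * (1 - exp(-0.4 * tr$times))
  expect_lt(max(abs(tr$states[, 1] - expected)), 0.05)  # O(h) Euler error
})

test_that("noisy CTS trajectories visit multiple basins", {
  top <- builtin_circuit("CTS")
  p <- cts_switch_params()
  ref <- c(A = 37, B = 43, C = 33, D = 51)  # ensemble-scale reference levels
  tr <- simulate_trajectory_sde(top, p,
          sim_config(total_time = 1000, print_interval = 1,
                     noise_level = 0.15, seed = 31),
          noise_ref = ref)
  km <- stats::kmeans(log2(tr$states + 1), 2, nstart = 5)
  expect_gt(sum(diff(km$cluster) != 0), 0)
  expect_true(all(km$size > 10))
  # reproducibility
  tr2 <- simulate_trajectory_sde(top, p,
           sim_config(total_time = 1000, print_interval = 1,
                      noise_level = 0.15, seed = 31),
           noise_ref = ref)
  expect_identical(tr$states, tr2$states)
})

test_that("splicing model has the stated fixed points and large-beta limit", {
  iso <- grn_topology(c("A", "B"),
                      data.frame(source = c("A", "B"), target = c("B", "A"),
                                 sign = c(1L, 1L)))
  p <- make_params(iso, G = c(8, 8), k = c(0.4, 0.4), lambda = 1 + 1e-12,
                   n = 1, threshold = 1e6)
  # stationarity: A_U* = G / beta, A_S* = G / k
  tr <- simulate_with_splicing(iso, p, sim_config(total_time = 60,
                                                  print_interval = 1),
                               beta = 0.7, init = c(0, 0))
  fin <- tr$states[nrow(tr$states), ]
  expect_lt(abs(fin[["A_U"]] - 8 / 0.7) / (8 / 0.7), 0.01)
  expect_lt(abs(fin[["A_S"]] - 8 / 0.4) / (8 / 0.4), 0.01)
  expect_equal(formals(simulate_with_splicing)$beta, 0.7)

  # beta -> infinity: spliced track approaches the no-splicing model
  top <- builtin_circuit("REP")
  pr <- rep_cycle_params()
  cfg <- sim_config(total_time = 60, print_interval = 1, step_size = 0.005)
  base <- simulate_trajectory_sde(top, pr, cfg, init = c(30, 10, 50))
  spl <- simulate_with_splicing(top, pr, cfg, beta = 1000 * 0.1,
                                init = c(30, 10, 50))
  s_cols <- paste0(top$genes, "_S")
  relerr <- abs(spl$states[, s_cols] - base$states) /
    pmax(abs(base$states), 1)
  expect_lt(stats::median(relerr), 0.05)
})

test_that("log normalization is log2 with pseudocount 1 and invertible", {
  m <- matrix(c(0, 1, 3, 7), 2, 2, dimnames = list(c("c1", "c2"),
                                                   c("g1", "g2")))
  attr(m, "scale") <- "raw"
  lm_ <- normalize_log(m)
  expect_equal(lm_[1, 1], 0)
  expect_equal(lm_[2, 1], 1)
  expect_equal(attr(lm_, "scale"), "log")
  expect_lt(max(abs((2^lm_ - 1) - m)), 1e-12)
  expect_error(normalize_log(lm_), "raw-scale")
  m[1, 1] <- -1
  expect_error(normalize_log(m), "non-negative")
})

test_that("z-scoring centers and scales per gene, dropping constant genes", {
  m <- cbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5), g3 = c(2, 8, 14))
  rownames(m) <- paste0("c", 1:3)
  expect_warning(z <- zscore(m), "zero-variance")
  expect_equal(colnames(z), c("g1", "g3"))
  expect_equal(unname(z[, "g1"]), c(-1, 0, 1))
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(unname(apply(z, 2, stats::sd)), c(1, 1))
  expect_error(zscore(m[1, , drop = FALSE]), "2 cells")
})

test_that("dropout zeroes only sub-quantile entries at the stated rate", {
  set.seed(5)
  m <- matrix(stats::runif(400, 1, 10), 40, 10,
              dimnames = list(paste0("c", 1:40), paste0("g", 1:10)))
  expect_identical(apply_dropout(m, 0, 0.2, seed = 1), m)

  # dropProb = 1: exactly the entries strictly below the per-gene type-7
  # quantile become 0 (independent quantile oracle)
  d1 <- apply_dropout(m, 1, 0.2, seed = 1)
  for (g in 1:10) {
    thr <- stats::quantile(m[, g], 0.2, type = 7, names = FALSE)
    expect_identical(unname(d1[, g] == 0), unname(m[, g] < thr))
  }

  # binomial expectation: fraction zeroed ~ dropProb * dropQuantile
  set.seed(6)
  big <- matrix(stats::runif(10000, 1, 10), 1000, 10)
  dimnames(big) <- list(paste0("c", 1:1000), paste0("g", 1:10))
  db <- apply_dropout(big, 0.5, 0.2, seed = 2)
  p_exp <- 0.5 * 0.2
  sigma <- sqrt(p_exp * (1 - p_exp) / length(big))
  expect_lt(abs(mean(db == 0) - p_exp), 3.5 * sigma + 1e-3)

  expect_identical(apply_dropout(m, 0.3, 0.2, seed = 7),
                   apply_dropout(m, 0.3, 0.2, seed = 7))
})
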