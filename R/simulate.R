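#' Simulation settings for circuit ensembles and trajectories
#'
#' @param step_size Euler step h, in time units.
#' @param total_time maximum integration time.
#' @param noise_level SDE noise amplitude multiplier (0 = deterministic);
#'   the per-gene noise is `noise_level` times a per-gene reference level
#'   (see [simulate_trajectory_sde()]).
#' @param print_interval spacing of recorded trajectory states, in time
#'   units; 0 means steady state only.
#' @param tol convergence tolerance: a model counts as converged when
#'   max |dA/dt| over genes drops below `tol`, checked once per time unit.
#' @param seed integer seed; every stochastic entry point is reproducible
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(step_size = 0.02, total_time = 100, noise_level = 0,
                       print_interval = 0, tol = 1e-6, seed = NULL) {
  stopifnot(step_size > 0, total_time >= step_size, noise_level >= 0,
            print_interval >= 0, tol > 0)
  structure(list(step_size = step_size, total_time = total_time,
                 noise_level = noise_level, print_interval = print_interval,
                 tol = tol, seed = seed),
            class = "sim_config")
}

#' Kinetic parameter sampling ranges (RACIPE convention)
#'
#' Maximum production rate G ~ U[1, 100]; degradation rate k ~ U[0.1, 1];
#' Hill coefficient n uniform on integers 1..6; regulation fold change
#' lambda ~ U[1, 100] for activation and the reciprocal for inhibition;
#' regulation threshold ~ U[0.02 M, 1.98 M] around the regulator's
#' half-maximal level M = G/(2k) (half-functional approximation).
#'
#' @param G,k,fold length-2 numeric ranges.
#' @param n_range integer range for the Hill coefficient.
#' @param threshold_scale length-2 multiplier range applied to M = G/(2k).
#' @return A list of ranges consumed by [sample_parameters()].
#' @export
param_ranges <- function(G = c(1, 100), k = c(0.1, 1), n_range = c(1L, 6L),
                         fold = c(1, 100), threshold_scale = c(0.02, 1.98)) {
  list(G = G, k = k, n_range = n_range, fold = fold,
       threshold_scale = threshold_scale)
}

#' Sample random kinetic parameters for a circuit
#'
#' Draws one or more RACIPE-style parameter sets for the given topology,
#' each representing one "cell" of the simulated ensemble. All marginals
#' are uniform on the ranges in [param_ranges()].
#'
#' @param topology a [grn_topology()].
#' @param n_models number of parameter sets to draw.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param ranges see [param_ranges()].
#' @return An object of class `kinetic_params`: a list with matrices
#'   `G`, `k` (n_models x genes) and `lambda`, `n`, `threshold`
#'   (n_models x edges), aligned with the topology's gene and edge order.
#' @export
sample_parameters <- function(topology, n_models = 1L, seed = NULL,
                              ranges = param_ranges()) {
  stopifnot(inherits(topology, "grn_topology"), n_models >= 1)
  if (!is.null(seed)) set.seed(seed)
  ng <- length(topology$genes)
  ne <- nrow(topology$edges)
  runifm <- function(nr, nc, lo, hi)
    matrix(stats::runif(nr * nc, lo, hi), nr, nc)
  G <- runifm(n_models, ng, ranges$G[1], ranges$G[2])
  k <- runifm(n_models, ng, ranges$k[1], ranges$k[2])
  colnames(G) <- colnames(k) <- topology$genes
  n <- matrix(sample(seq(ranges$n_range[1], ranges$n_range[2]),
                     n_models * ne, replace = TRUE), n_models, ne)
  raw_fold <- runifm(n_models, ne, ranges$fold[1], ranges$fold[2])
  sgn <- matrix(topology$edges$sign, n_models, ne, byrow = TRUE)
  lambda <- ifelse(sgn == 1, raw_fold, 1 / raw_fold)
  # threshold around the regulator's half-maximal level in this model
  src <- match(topology$edges$source, topology$genes)
  M <- G[, src, drop = FALSE] / (2 * k[, src, drop = FALSE])
  threshold <- M * runifm(n_models, ne, ranges$threshold_scale[1],
                          ranges$threshold_scale[2])
  structure(list(G = G, k = k, lambda = lambda, n = n,
                 threshold = threshold, topology = topology,
                 n_models = n_models),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic parameters: %d model(s), %d genes, %d edges\n",
              x$n_models, ncol(x$G), ncol(x$lambda)))
  invisible(x)
}

# Extract a single model's parameters (still 1-row matrices).
params_model <- function(params, i) {
  stopifnot(inherits(params, "kinetic_params"), i >= 1, i <= params$n_models)
  out <- params
  for (f in c("G", "k", "lambda", "n", "threshold"))
    out[[f]] <- params[[f]][i, , drop = FALSE]
  out$n_models <- 1L
  out
}

#' Shifted Hill regulation factor
#'
#' The multiplicative effect of a regulator at level `B` on its target:
#' `lambda + (1 - lambda) / (1 + (B / B0)^n)`. Equal to 1 at B = 0, to
#' `(1 + lambda) / 2` at B = B0, and approaches `lambda` as B >> B0.
#'
#' @param B regulator level(s), non-negative.
#' @param B0 threshold level, positive.
#' @param n Hill coefficient, >= 1.
#' @param lambda fold change: > 1 activation, in (0, 1) inhibition.
#' @return Regulation factor(s), same shape as `B`.
#' @examples
#' shifted_hill(0, 5, 3, 0.1)   # 1
#' shifted_hill(5, 5, 3, 0.1)   # (1 + 0.1) / 2
#' @export
shifted_hill <- function(B, B0, n, lambda) {
  if (any(B < 0) || any(B0 <= 0) || any(n < 1) || any(lambda <= 0))
    stop("shifted_hill: B >= 0, B0 > 0, n >= 1, lambda > 0 required")
  lambda + (1 - lambda) / (1 + (B / B0)^n)
}

#' Piecewise-linear signal schedule
#'
#' Multiplier s(t) applied to the production rate of one gene: rises
#' linearly from 1 to `fold` over [0, t_rise], holds at `fold` for
#' `t_hold`, decays linearly back to 1 over `t_fall`, and is 1 afterward.
#'
#' @param target_gene gene whose production rate is scaled.
#' @param fold maximal multiplier (>= 1).
#' @param t_rise,t_hold,t_fall phase durations in time units.
#' @return A list of class `signal_schedule`.
#' @export
signal_schedule <- function(target_gene, fold, t_rise, t_hold, t_fall) {
  stopifnot(fold >= 1, t_rise >= 0, t_hold >= 0, t_fall >= 0)
  structure(list(target_gene = target_gene, fold = fold, t_rise = t_rise,
                 t_hold = t_hold, t_fall = t_fall),
            class = "signal_schedule")
}

#' Evaluate a signal schedule at time t
#' @param schedule a [signal_schedule()].
#' @param t time (scalar or vector).
#' @return multiplier(s) s(t).
#' @export
signal_factor <- function(schedule, t) {
  with(schedule, {
    up <- t_rise; hold <- t_rise + t_hold; down <- t_rise + t_hold + t_fall
    out <- rep(1, length(t))
    r <- t >= 0 & t < up
    out[r] <- 1 + (fold - 1) * (if (up > 0) t[r] / up else 1)
    out[t >= up & t < hold] <- fold
    f <- t >= hold & t < down
    out[f] <- fold - (fold - 1) * (t[f] - hold) / (down - hold)
    out
  })
}

# Vectorised production term: states is n_models x genes, params aligned.
# Returns n_models x genes matrix of production rates before signal scaling.
production_rates <- function(states, params) {
  top <- params$topology
  nm <- nrow(states)
  prod_hill <- matrix(1, nm, ncol(states))
  ne <- nrow(top$edges)
  if (ne > 0) {
    src <- match(top$edges$source, top$genes)
    tgt <- match(top$edges$target, top$genes)
    for (e in seq_len(ne)) {
      H <- params$lambda[, e] +
        (1 - params$lambda[, e]) /
        (1 + (states[, src[e]] / params$threshold[, e])^params$n[, e])
      prod_hill[, tgt[e]] <- prod_hill[, tgt[e]] * H
    }
  }
  # G is divided by the fold change of each ACTIVATING incoming edge so the
  # maximum achievable production rate stays G (an inhibiting edge's shifted
  # Hill factor already has maximum 1, so it needs no normalization)
  lam_prod <- matrix(1, nm, ncol(states))
  if (ne > 0) {
    tgt <- match(top$edges$target, top$genes)
    for (e in seq_len(ne)) {
      if (top$edges$sign[e] == 1)
        lam_prod[, tgt[e]] <- lam_prod[, tgt[e]] * params$lambda[, e]
    }
  }
  (params$G / lam_prod) * prod_hill
}

#' Time derivative of a circuit state
#'
#' dA/dt = s_A(t) * (G_A / prod lambda) * prod shifted_hill(B_i) - k_A A,
#' where the product runs over A's incoming edges (empty product = 1) and
#' s_A(t) is 1 unless A is the signal schedule's target.
#'
#' @param state named non-negative vector of gene levels (topology order).
#' @param topology a [grn_topology()].
#' @param params a single-model [sample_parameters()] object.
#' @param signal optional [signal_schedule()].
#' @param t time (used only by the signal).
#' @return Named vector of per-gene rates.
#' @export
circuit_derivative <- function(state, topology, params, signal = NULL, t = 0) {
  stopifnot(inherits(params, "kinetic_params"), params$n_models == 1L)
  if (any(state < 0)) stop("state must be non-negative")
  S <- matrix(state, 1L, length(topology$genes))
  rate <- derivative_matrix(S, params, signal, t)
  stats::setNames(drop(rate), topology$genes)
}

# Vectorised derivative on an n_models x genes state matrix.
derivative_matrix <- function(states, params, signal = NULL, t = 0) {
  prod_rate <- production_rates(states, params)
  if (!is.null(signal)) {
    gi <- match(signal$target_gene, params$topology$genes)
    if (is.na(gi)) stop("unknown signal target gene: ", signal$target_gene)
    prod_rate[, gi] <- prod_rate[, gi] * signal_factor(signal, t)
  }
  prod_rate - params$k * states
}

#' Simulate an ensemble of steady-state expression profiles
#'
#' RACIPE-style snapshot generation: each model gets random kinetic
#' parameters and a random initial condition uniform in [0, G/k] per gene,
#' then is integrated by fixed-step Euler until the maximum per-unit-time
#' change falls below `config$tol` or `config$total_time` is reached.
#' Non-converged models (e.g., repressilator-type oscillators) are retained
#' and flagged; models whose state becomes non-finite are dropped with a
#' warning.
#'
#' @param topology a [grn_topology()].
#' @param n_models ensemble size.
#' @param config a [sim_config()]; its `seed` drives all randomness.
#' @param signal optional [signal_schedule()] held fixed at its t = Inf
#'   baseline during steady-state runs (rarely useful; mainly for API
#'   symmetry).
#' @return A cells x genes numeric matrix (scale tag "raw") with attributes
#'   `converged` (logical per retained model) and `params` (the sampled
#'   [sample_parameters()] object, including dropped models).
#' @export
simulate_steady_states <- function(topology, n_models, config = sim_config(),
                                   signal = NULL) {
  stopifnot(inherits(topology, "grn_topology"), n_models >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  params <- sample_parameters(topology, n_models)
  ng <- length(topology$genes)
  S <- matrix(stats::runif(n_models * ng), n_models, ng) * (params$G / params$k)
  h <- config$step_size
  steps_per_window <- max(1L, round(1 / h))
  n_windows <- ceiling(config$total_time / (steps_per_window * h))
  converged <- rep(FALSE, n_models)
  t <- 0
  for (w in seq_len(n_windows)) {
    for (s in seq_len(steps_per_window)) {
      S <- S + h * derivative_matrix(S, params, signal, t)
      S[S < 0] <- 0
      t <- t + h
    }
    rate <- derivative_matrix(S, params, signal, t)
    ok <- is.finite(rowSums(S)) & is.finite(rowSums(rate))
    mx <- apply(abs(rate), 1, max)
    converged <- ok & (mx < config$tol)
    if (all(converged)) break
  }
  finite <- is.finite(rowSums(S))
  if (!all(finite))
    warning(sum(!finite), " model(s) diverged to non-finite states and were dropped")
  out <- S[finite, , drop = FALSE]
  colnames(out) <- topology$genes
  rownames(out) <- paste0("model_", which(finite))
  attr(out, "scale") <- "raw"
  attr(out, "converged") <- converged[finite]
  attr(out, "params") <- params
  out
}

#' Simulate a stochastic expression trajectory for one model
#'
#' Euler-Maruyama integration of the circuit SDE: at each step
#' `A <- A + f(A) h + xi_A sqrt(h) N(0, 1)`, clipped at 0 (concentrations
#' are non-negative). The per-gene noise amplitude `xi_A` is
#' `config$noise_level` times a per-gene reference level: by default
#' (`noise_scaling = "ensemble"`) the ensemble mean of deterministic steady
#' states for the same topology (precomputed once, or supplied via
#' `noise_ref`); with `"running"` a running average of the trajectory
#' itself. With `noise_level = 0` the path is exactly the deterministic
#' Euler path.
#'
#' @param topology a [grn_topology()].
#' @param params a single-model `kinetic_params` (use [params_model()] to
#'   slice an ensemble draw).
#' @param config a [sim_config()]; `print_interval` must be > 0.
#' @param signal optional [signal_schedule()].
#' @param init optional initial state (default: uniform in [0, G/k]).
#' @param noise_scaling "ensemble" or "running" (see above).
#' @param noise_ref optional per-gene reference expression used to scale
#'   the noise; overrides the precomputed ensemble mean.
#' @return A list of class `trajectory`: `times` (recorded time points) and
#'   `states` (time x genes matrix), plus the model parameters.
#' @export
simulate_trajectory_sde <- function(topology, params, config,
                                    signal = NULL, init = NULL,
                                    noise_scaling = c("ensemble", "running"),
                                    noise_ref = NULL) {
  stopifnot(inherits(params, "kinetic_params"), params$n_models == 1L,
            config$print_interval > 0)
  noise_scaling <- match.arg(noise_scaling)
  if (!is.null(config$seed)) set.seed(config$seed)
  ng <- length(topology$genes)
  if (config$noise_level > 0 && is.null(noise_ref) &&
      noise_scaling == "ensemble") {
    ref_cfg <- sim_config(step_size = config$step_size, total_time = 50,
                          tol = config$tol, seed = NULL)
    ens <- simulate_steady_states(topology, 200L, ref_cfg)
    noise_ref <- colMeans(ens)
  }
  if (is.null(init)) {
    init <- stats::runif(ng) * drop(params$G / params$k)
  }
  h <- config$step_size
  n_steps <- floor(config$total_time / h)
  rec_every <- max(1L, round(config$print_interval / h))
  n_rec <- floor(n_steps / rec_every)
  states <- matrix(NA_real_, n_rec, ng,
                   dimnames = list(NULL, topology$genes))
  times <- numeric(n_rec)
  S <- matrix(init, 1L, ng)
  run_mean <- S
  sq_h <- sqrt(h)
  ri <- 0L
  for (s in seq_len(n_steps)) {
    t <- (s - 1L) * h
    dS <- derivative_matrix(S, params, signal, t)
    if (config$noise_level > 0) {
      ref <- if (noise_scaling == "running") run_mean else noise_ref
      S <- S + h * dS +
        config$noise_level * ref * sq_h * stats::rnorm(ng)
    } else {
      S <- S + h * dS
    }
    S[S < 0] <- 0
    if (!all(is.finite(S)))
      stop("trajectory diverged to non-finite state at t = ", t)
    if (noise_scaling == "running")
      run_mean <- run_mean + (S - run_mean) / (s + 1)
    if (s %% rec_every == 0L) {
      ri <- ri + 1L
      times[ri] <- s * h
      states[ri, ] <- S
    }
  }
  structure(list(times = times, states = states, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d recorded states, %d tracks (t in [%g, %g])\n",
              nrow(x$states), ncol(x$states), min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate a trajectory with explicit mRNA splicing
#'
#' Variant of [simulate_trajectory_sde()] where each gene carries an
#' unspliced track `A_U` and a spliced track `A_S`:
#' `dA_U/dt = production - beta A_U`, `dA_S/dt = beta A_U - k A_S`,
#' with regulators read from the spliced levels. At stationarity of an
#' isolated gene, `A_U* = G / beta` and `A_S* = G / k`. As beta grows the
#' spliced track approaches the no-splicing model.
#'
#' @inheritParams simulate_trajectory_sde
#' @param beta constant splicing rate (default 0.7).
#' @return A `trajectory` whose `states` has columns `<gene>_U` and
#'   `<gene>_S` per gene.
#' @export
simulate_with_splicing <- function(topology, params, config, beta = 0.7,
                                   signal = NULL, init = NULL,
                                   noise_ref = NULL) {
  stopifnot(inherits(params, "kinetic_params"), params$n_models == 1L,
            beta > 0, config$print_interval > 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  ng <- length(topology$genes)
  if (config$noise_level > 0 && is.null(noise_ref)) {
    ref_cfg <- sim_config(step_size = config$step_size, total_time = 50,
                          tol = config$tol, seed = NULL)
    ens <- simulate_steady_states(topology, 200L, ref_cfg)
    noise_ref <- colMeans(ens)
  }
  if (is.null(init)) init <- stats::runif(ng) * drop(params$G / params$k)
  U <- matrix(init * drop(params$k) / beta, 1L, ng)  # start near U = kS/beta
  S <- matrix(init, 1L, ng)
  h <- config$step_size
  n_steps <- floor(config$total_time / h)
  rec_every <- max(1L, round(config$print_interval / h))
  n_rec <- floor(n_steps / rec_every)
  states <- matrix(NA_real_, n_rec, 2L * ng,
                   dimnames = list(NULL, c(paste0(topology$genes, "_U"),
                                           paste0(topology$genes, "_S"))))
  times <- numeric(n_rec)
  sq_h <- sqrt(h)
  ri <- 0L
  for (s in seq_len(n_steps)) {
    t <- (s - 1L) * h
    prod_rate <- production_rates(S, params)
    if (!is.null(signal)) {
      gi <- match(signal$target_gene, topology$genes)
      if (is.na(gi)) stop("unknown signal target gene: ", signal$target_gene)
      prod_rate[, gi] <- prod_rate[, gi] * signal_factor(signal, t)
    }
    dU <- prod_rate - beta * U
    dS <- beta * U - params$k * S
    if (config$noise_level > 0) {
      U <- U + h * dU + config$noise_level * noise_ref * sq_h * stats::rnorm(ng)
      S <- S + h * dS + config$noise_level * noise_ref * sq_h * stats::rnorm(ng)
    } else {
      U <- U + h * dU
      S <- S + h * dS
    }
    U[U < 0] <- 0
    S[S < 0] <- 0
    if (s %% rec_every == 0L) {
      ri <- ri + 1L
      times[ri] <- s * h
      states[ri, ] <- c(U, S)
    }
  }
  structure(list(times = times, states = states, params = params,
                 beta = beta),
            class = "trajectory")
}
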