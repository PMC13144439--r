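#' Build a fixed kinetic parameter set
#'
#' Constructs a single-model `kinetic_params` object from explicit values,
#' recycled as needed, for use with [simulate_trajectory_sde()] and
#' [simulate_with_splicing()].
#'
#' @param topology a [grn_topology()].
#' @param G,k per-gene production and degradation rates (recycled).
#' @param lambda,n,threshold per-edge fold change, Hill coefficient and
#'   threshold, in the topology's edge order (recycled).
#' @return A 1-model `kinetic_params`.
#' @export
make_params <- function(topology, G, k, lambda, n, threshold) {
  ng <- length(topology$genes)
  ne <- nrow(topology$edges)
  rowm <- function(v, nc) matrix(rep_len(v, nc), 1L, nc)
  p <- structure(list(G = rowm(G, ng), k = rowm(k, ng),
                      lambda = rowm(lambda, ne), n = rowm(n, ne),
                      threshold = rowm(threshold, ne),
                      topology = topology, n_models = 1L),
                 class = "kinetic_params")
  colnames(p$G) <- colnames(p$k) <- topology$genes
  act <- topology$edges$sign == 1
  if (any(p$lambda[, act] <= 1) || any(p$lambda[, !act] >= 1))
    stop("lambda must be > 1 on activating and < 1 on inhibiting edges")
  p
}

#' Synthetic repressilator parameter set with a limit cycle
#'
#' A symmetric parameter set for the [builtin_circuit()] "REP" topology
#' chosen so the deterministic dynamics settle on a stable limit cycle
#' (strong inhibition, steep Hill kinetics). This is a synthetic fixture
#' constructed to reproduce the oscillatory regime, used as ground truth
#' for trajectory-based validation.
#'
#' @return A 1-model `kinetic_params` for the REP topology.
#' @export
rep_cycle_params <- function() {
  top <- builtin_circuit("REP")
  # moderate repression and a mid-range threshold give a slow (~36 time
  # units), near-circular limit cycle in log-PCA space
  make_params(top, G = 10, k = 0.1, lambda = 0.05, n = 4, threshold = 35)
}

#' Synthetic coupled-toggle-switch parameter set with noise-driven switching
#'
#' A symmetric parameter set for the [builtin_circuit()] "CTS" topology
#' with two major attractors (A/C-high and B/D-high); under sufficient SDE
#' noise, trajectories switch stochastically between the basins. This is a
#' synthetic fixture constructed to reproduce the multistable switching
#' regime.
#'
#' @return A 1-model `kinetic_params` for the CTS topology.
#' @export
cts_switch_params <- function() {
  top <- builtin_circuit("CTS")
  # edge order: A-|B, B-|A, C-|D, D-|C, A->C, C->A, B->D, D->B
  make_params(top, G = 50, k = 0.5,
              lambda = c(0.05, 0.05, 0.05, 0.05, 3, 3, 3, 3),
              n = 4, threshold = 25)
}
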