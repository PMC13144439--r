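---
title: "Inferring reversible and irreversible cell state transitions from a gene regulatory network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring reversible and irreversible cell state transitions from a gene regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sticc)
```

## The problem

Single-cell expression snapshots show *where* cells sit in state space but
not *where they are going*. If, however, a set of signed regulator–target
interactions is known, the time delay between a regulator's activity and
its targets' response leaves a usable trace in static data: a cell whose
current regulator state "predicts" another cell's target state is likely
upstream of it in time. This package turns that idea into a per-cell
vector field and — its distinguishing feature — separates the
*irreversible* component of local transitions (directed flux, as around a
limit cycle) from the *reversible* component (bidirectional wandering
between attractors, as in a multistable switch).

## The model

### Cross-cell correlation

Let the network have edges $k = 1, \dots, K$ with source $R_k$, target
$T_k$ and sign $s_k \in \{+1, -1\}$. For cells $i, j$ define the
cross-cell correlation (CCC)

$$\rho_{i \to j} = \mathrm{corr}\!\left(e_{R,i} \odot s,\; e_{T,j}\right),$$

the Pearson correlation over edges between the sign-adjusted regulator
expression of cell $i$ ($e_{R,i}[k]$ = expression of $R_k$ in cell $i$)
and the target expression of cell $j$. A high $\rho_{i \to j}$ marks cell
$j$ as a plausible time evolution of cell $i$ under the network. At least
two edges are required; cells whose regulator or target vector has zero
variance get undefined correlations and are flagged rather than imputed.
Note that a cell with flat expression can still have a well-defined
regulator vector when edge signs are mixed, because the sign adjustment
restores variance — only the target side is then undefined.

### Local regression and decomposition

For each center cell $i$, all cells within a sampling radius (a fraction
of the maximum pairwise distance of the embedding) form the neighborhood.
With $X$ the matrix of relative positions $x_j - x_i$ and
$y_{1,j} = \rho_{i \to j} - \rho_{i \to i}$, the outgoing vector is the
least-squares gradient $v_1 = (X^\top X)^{-1} X^\top y_1$. The incoming
vector uses $y_{2,j} = \rho_{j \to i} - \rho_{i \to i}$ with a negated
estimator, $v_2 = -(X^\top X)^{-1} X^\top y_2$, so both vectors point
*away from the past / toward the future* of cell $i$. The decomposition

$$\text{net flow} = \tfrac{1}{2}(v_1 + v_2), \qquad
  \text{reversibility} = \tfrac{1}{2}(v_1 - v_2)$$

is exact: net $\pm$ rev recovers $v_1$ / $v_2$ identically. If the CCC
were symmetric ($\rho_{i \to j} = \rho_{j \to i}$), net flow would vanish
for every cell — irreversibility is precisely the asymmetric part of the
correlation field. Reversibility has no preferred sign; it is axial data.

CCCs are always computed on the network genes' expression as supplied
(log-normalized or z-scored upstream — the package does not silently
rescale). The regression space is separate: network-gene expression by
default, or principal components / user coordinates for larger panels.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `radius` | 0.15 | neighborhood radius as a fraction of the maximum pairwise distance |
| `min_neighbors` | 15 | cells below this usable-neighbor count are flagged invalid, not fitted |
| `n_pcs` | 2 | components when `space = "pca"` |

The radius trades noise averaging against locality. `optimize_radius()`
grid-searches 11 evenly spaced radii on [0.05, 0.30] and maximizes
coverage (fraction of cells with at least `min_neighbors` neighbors)
divided by MAPE (median over valid cells of the per-cell median absolute
percentage regression error; components with $|y| < 10^{-9}$ are excluded
from the percentage to avoid division blow-ups). Ties go to the smaller
radius. When optimization is skipped the default is 0.15.

Numerical choices: regressions use a QR solve, falling back to the
minimum-norm SVD pseudo-inverse (flagged per cell) when $X$ is
rank-deficient; neighbors with undefined CCC are dropped from the fit; a
center cell with undefined self-CCC is invalid with a reason code.
Distances are Euclidean in the chosen space.

## The circuit simulator

Because ground truth for transition directions barely exists in real
data, the package ships an ensemble simulator in the RACIPE tradition:
each "cell" is one random parameterization of the same circuit topology.
A gene $A$ with regulators $B_i$ follows

$$\frac{dA}{dt} = \frac{G_A}{\prod_{i \in \text{act}} \lambda_{B_i A}}
  \prod_i \left(\lambda_{B_i A} + \frac{1 - \lambda_{B_i A}}
  {1 + (B_i / B_{iA,0})^{n_{B_i A}}}\right) - k_A A,$$

the product of shifted Hill factors per incoming edge. $G$ is normalized
by the fold change of each *activating* edge only, so the maximum
achievable production rate is exactly $G$; an inhibitory factor already
has maximum 1 and needs no normalization. (Normalizing by inhibitory fold
changes as well would push every inhibited regulator permanently above
the sampled thresholds and abolish multistability — we verified this
empirically on the toggle-switch fixtures.)

Parameters are sampled uniformly: $G \in [1, 100]$, $k \in [0.1, 1]$,
Hill $n \in \{1..6\}$, fold change $\lambda \in [1, 100]$ for activation
and its reciprocal for inhibition, and thresholds in
$[0.02, 1.98] \times G_B/(2 k_B)$ (the regulator's half-maximal level —
the half-functional rule). Initial conditions are uniform on $[0, G/k]$
per gene. Integration is fixed-step Euler ($h = 0.02$ default) to a
per-model convergence test (max $|dA/dt| <$ `tol`, checked once per time
unit) or `total_time`; oscillators legitimately never converge and are
retained with `converged = FALSE`. Models reaching non-finite states are
dropped with a warning.

Stochastic trajectories use Euler–Maruyama,
$A \leftarrow A + f(A)h + \xi_A \sqrt{h}\, \eta$, clipped at zero
(concentrations are non-negative). The per-gene amplitude $\xi_A$ is
`noise_level` times a reference expression level — by default the
ensemble mean of deterministic steady states for the topology, computed
once (a running trajectory average is available as an option, and
`noise_ref` can be supplied directly). A splicing variant carries
unspliced/spliced tracks per gene
($\dot A_U = \text{production} - \beta A_U$,
$\dot A_S = \beta A_U - k A_S$, $\beta = 0.7$ by default, regulators read
from spliced levels); at an isolated gene's stationary point
$A_U^* = G/\beta$ and $A_S^* = G/k$, and the spliced track converges to
the one-track model as $\beta \to \infty$. A piecewise-linear signal
schedule can multiply one gene's production rate (rise / hold / fall).

Raw ensembles are log-normalized as $\log_2(x + 1)$ (the convention that
maps 0 to 0 and 1 to 1); z-scoring uses the $n - 1$ standard deviation
and drops constant genes with a warning. The dropout model zeroes, per
gene, entries strictly below the empirical `dropQuantile` (type-7
quantile — the dialect is fixed and documented since alternatives differ
at small $n$) with probability `dropProb`, applied to raw values before
normalization, so the expected zeroed fraction is
`dropProb * dropQuantile`.

### Circuit fixtures and what they emulate

Four built-in topologies cover the qualitative regimes: the repressilator
`REP` (irreversible rotation), the coupled toggle switch `CTS`
(reversible switching between an A/C-high and a B/D-high state, plus two
minor states), the incoherent feedforward loop `IFFL` (pulse adaptation),
and the toggle/repressilator hybrid `TSREP`. The CTS and TSREP wiring is
a design choice validated by simulation — two-cluster structure and
reversibility-dominated vector fields for CTS — rather than copied from a
printed edge list.

`rep_cycle_params()` (G = 10, k = 0.1, λ = 0.05, n = 4, threshold = 35)
is a synthetic fixed parameter set chosen from a scan of the oscillatory
regime for a *slow, nearly circular* limit cycle in log-PCA (period ≈ 36
time units, radial coefficient of variation ≈ 4%): round cycles make the
tangential direction well defined at every phase, which is what the
validation harness needs. `cts_switch_params()` is its multistable
counterpart; under moderate SDE noise trajectories hop between basins.

These ensembles emulate parametric cell-to-cell variability and (via the
dropout model) zero inflation. They do not emulate library-size effects,
amplification noise, batch structure, or transcriptional bursting, so
passing tests here demonstrates correctness of the inference given the
modeling assumptions, not robustness to everything real data does.

## Post-inference analysis

PCA (`pca_project()`) is centered, unscaled, with a deterministic sign
convention (the largest-magnitude loading of each component is made
positive) so axes cannot flip between runs. Vector fields are smoothed
for display on a uniform grid by inverse-distance weighting
($w = 1/(d + 10^{-9})^2$, nodes with no cell within the influence radius
masked). Basins are estimated as local *maxima* of a Gaussian kernel
density (Scott bandwidth, 100 × 100 grid, 8-neighborhood), discarding
peaks below 10% of the global maximum — an automated version of removing
spurious far-field extrema by hand. We read the basin literature's
occasional "density minima" phrasing as a slip: attractor basins are
high-density regions.

Edge-sensitivity analysis re-runs the inference with edges or a node's
edges removed (the gene list, and hence the expression columns, stay
fixed) and summarizes each perturbation by the median per-cell Euclidean
norm of the vector difference, for net flow and reversibility separately;
the alternative reading — absolute difference of magnitudes — is reported
alongside (`dmag_abs`). The top 15% of perturbations by combined change
are flagged. Perturbations leaving fewer than two edges are recorded as
degenerate, never computed. The identity perturbation scores exactly
zero, which doubles as a determinism check.

## Trajectory validation

Predicted vectors are scored against stochastic trajectories of fixed
fixture models. Around a query point, all trajectory timepoints within 2%
(default) of the trajectory's maximum pairwise distance become start
points; observed vectors run from each start to the state `lag` recorded
steps later. The lag is chosen by scanning 1..200 for the start→end RMSD
closest to a target — large enough to rise above step-to-step noise,
small enough to stay local; the target is dataset-specific configuration,
not a constant. Observed angle distributions are summarized by a von
Mises kernel density (κ = 8, 360-point grid, peaks ≥ 20% of the maximum,
wrap-around handled so a cluster straddling ±π is one peak), and a
prediction is scored by the cosine to its *nearest* peak, so multi-route
regions are not penalized. Reversibility, being sign-free, is scored at
both ends.

For the end-to-end check on the repressilator cycle we compare the median
nearest-peak cosine over 12 query points against a Monte-Carlo null: the
same median statistic recomputed with uniformly random predicted angles
against the same per-query peak sets, 400 replicates, requiring the
observed median to exceed the null's 95th percentile. We use the null
distribution of the *statistic* (not of single random-angle scores)
because that is the coherent significance test for a median; the package
measures medians around 0.96–0.98 against a null 95th percentile near
0.5.

## Problem sizes

The shipped tests and the acceptance script run each ensemble at 2,000
models, trajectories at a few thousand recorded states, and the radius
optimizer on 500-cell subsets — sizes at which every regime (rotation
sign-consistency above 98%, reversibility-dominated CTS fields,
dropout angle changes two orders of magnitude below the shuffled null)
is already unambiguous.

## Known limitations

- Predictions inherit the input network's quality; a wrong or incomplete
  topology shifts vectors (that sensitivity is itself the point of the
  perturbation analysis).
- The CCC treats all interactions on one timescale; signaling and
  transcriptional edges are not distinguished.
- Vector magnitudes are relative within a dataset and not calibrated to
  physical time.
- The regression is linear and local: structure below the sampling radius
  or strongly curved flows within one neighborhood are smoothed over.
- On the repressilator fixture the inferred flow is tangential to the
  *data cloud's* circular structure; where a deterministic orbit is
  locally non-circular (corners of the triangular cycle of a stiff
  repressilator), predicted and observed directions can disagree by
  10–15 degrees even when everything works as designed — one reason the
  shipped cycle fixture is deliberately round.
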