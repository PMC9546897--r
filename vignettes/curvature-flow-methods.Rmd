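---
title: "Community detection by curvature-driven optimal transport: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community detection by curvature-driven optimal transport: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orcflow)
```

## The model

`orcflow` detects communities in a weighted undirected graph $G = (V, E, W)$
by measuring, for every edge $(i, j)$, how expensive it is to transport the
probability mass sitting on $i$'s neighborhood onto $j$'s neighborhood.  If
the two nodes share a community, their neighborhoods overlap heavily and the
transport is cheap relative to the distance between them; across a
community boundary it is expensive.

**Neighborhood masses.**  Each node $i$ carries the distribution
$m_i^\alpha$: mass $\alpha$ on $i$ itself and $(1 - \alpha)/|\mathcal N(i)|$
on each neighbor.  All benchmarks use $\alpha = 0$ (the one-step random-walk
distribution); `neighborhood_mass()` supports any $\alpha \in [0, 1]$, but
$\alpha > 0$ puts a node on both sides of its own transport problem and we
benchmark only $\alpha = 0$.

**Local transport problems.**  For an edge $(i, j)$ the transport is posed on
an auxiliary complete bipartite graph: left nodes $\mathcal N(i) \cup \{i\}$,
right nodes $\mathcal N(j) \cup \{j\}$, the cost of a left–right pair being
the weighted shortest-path distance between the two nodes in $G$ (zero when
they coincide).  Because shortest-path distances form a metric, routing mass
through intermediate pairs can never undercut the direct pair, and the
optimal flux cost coincides with the transport-plan (Monge–Kantorovich)
optimum at $\beta = 1$.  This matters for testing: the random oracle
instances use metric costs (distances between random planar points), since
with arbitrary non-metric cost matrices a flux-based solver may legitimately
relay mass through zero-mass nodes and beat the plan optimum.

**The DMK dynamics.**  The transport problem is solved with the discrete
dynamical Monge–Kantorovich system: potentials $u$ obey Kirchhoff's law
$B\,\mathrm{diag}(\mu/w)\,B^T u = f$ with forcing $f = m_i - m_j$, fluxes
are $q_e = (\mu_e/w_e)\,|u_k - u_l|$, and conductivities relax as
$\mu_e' = q_e^\beta - \mu_e$.  The traffic rate $\beta \in (0, 2]$ is the
single scientific tuning knob: $\beta = 1$ yields the 1-Wasserstein distance,
$\beta < 1$ congested transport (flux spread over many routes), $\beta > 1$
branched transport (flux consolidated on few routes).  The steady-state cost
$W_\beta = \sum_e q_e^* \omega_e$ is the $\beta$-Wasserstein cost.

**Curvature and flow.**  The edge curvature is
$\kappa_\beta(i,j) = 1 - W_\beta / d_{ij}$, with $d_{ij}$ the current
shortest-path distance between the endpoints (which can be smaller than the
edge's own weight).  The Ricci flow iterates
$w_{ij} \leftarrow d_{ij}(1 - \kappa_\beta)$ — algebraically exactly
$W_\beta$ — followed by normalization of all weights to unit total sum,
starting from $w^{(0)} = d^{(0)}$.  Positively curved (intra-community)
edges shrink; negatively curved bridges stretch.

**Surgery.**  After (and during) the flow, communities are read off by
cutting all edges longer than a threshold and taking connected components.
The threshold is chosen by scanning every candidate (midpoints between
consecutive distinct weights, plus the maximum) and keeping the cut with the
highest Newman modularity, ties broken toward fewer communities.  Modularity
is evaluated on the *original* graph's weights: communities are claims about
the network as observed, not about the deformed weights.  The number of
communities is never an input.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `beta` | 1 | traffic rate in $(0, 2]$; $>1$ suits crisp assortative blocks, $<1$ hub-dominated structures |
| `alpha` | 0 | mass retained at the node itself |
| `max_iter` | 15 | Ricci flow iterations; the benchmarks all use 15 |
| `dt` | 0.1 | explicit-Euler step of the conductivity dynamics; halved internally for $\beta \ge 1.8$ where the dynamics stiffen |
| `tol` | `1e-5` | stationarity threshold of the dynamics (see below) |
| `max_steps` | 2000 | per-edge integration cap; exceeding it flags `converged = FALSE` without aborting |
| `eps_cost` | `1e-10` | stand-in for exactly-zero costs inside the solver only |

`detect_communities()` selects the snapshot by modularity by default
(deployment: no ground truth needed).  `selection = "ari"` instead picks the
snapshot with the best adjusted Rand index against a supplied truth — the
protocol used for all synthetic benchmarks, where the question is how well
the flow *can* recover the planted structure.

## Numerical choices

* **Time discretization.**  The continuous dynamics are integrated by
  explicit Euler with `dt = 0.1`.  The dynamics relax at unit rate, so this
  is comfortably inside the stability region; for $\beta \ge 1.8$ the
  effective step is halved because the branched dynamics stiffen near
  lock-in.
* **Convergence.**  A run is declared converged when the stationarity
  residual $\max_e |q_e^\beta - \mu_e|$, scaled by the conductivity
  magnitude, falls below `tol` *and* the relative change of the transport
  cost has stayed below `tol` for 10 consecutive steps.  A plain
  relative-change criterion on $\mu$ was rejected: near-degenerate instances
  contain conductivities that decay exponentially at arbitrarily slow rates,
  keeping the relative change large for thousands of steps after the cost
  has converged to well below the accuracy the flow needs.
* **Zero costs.**  Pairs of the form $(k, k)$ have cost zero, which would
  sit in a denominator of the dynamics; inside the solver they are replaced
  by `eps_cost = 1e-10`, while all reported costs use the true zeros.  The
  bias is at most `eps_cost` per unit mass.
* **Singular Laplacian.**  The bipartite Laplacian is reduced by a Schur
  complement of its diagonal block to a dense SPD system on the smaller
  side; the constant-potential null direction is removed by a ground-node
  penalty, which is exact because the forcing sums to zero.
* **Conductivity floor and freezing.**  Conductivities are floored at
  $10^{-14}$.  For $\beta > 1$ an edge whose conductivity sits on the floor
  for 20 consecutive steps is frozen out of the solve (in the branched
  regime $\mu' \approx -\mu$ there, so revival is impossible), and once few
  edges remain active the Schur complement is accumulated sparsely.  An edge
  is never frozen if it is the last active edge of a node carrying mass.
  This changes results only at the level of the floor itself but makes the
  dense benchmark graphs tractable.
* **Warm starts.**  Across Ricci-flow iterations the topology is fixed, so
  each edge's conductivities are warm-started from the previous iteration's
  steady state.  Results are identical to cold starts up to the convergence
  tolerance; only the step counts drop.
* **Weight floor.**  Updated weights are floored at $10^{-12}$ before
  normalization so that near-identical neighborhoods ($\kappa \to 1$) cannot
  produce zero-length edges that corrupt shortest paths.
* **Determinism.**  Node orderings are sorted everywhere; all generators
  take explicit seeds; `detect_communities()` is bitwise reproducible from
  its inputs.

## Synthetic benchmarks

`generate_sbm(n, k, d, r, seed)` plants $K$ equal blocks (remainder spread
over the first blocks) and connects within-block pairs with
$p_\mathrm{intra} = dK/N$ and between-block pairs with
$r \cdot p_\mathrm{intra}$, unit weights.  The study conditions used in the
acceptance checks are the scaled-down benchmark $N = 150$, $K = 3$,
$d = 15$, five realisations, $\beta = 2$, ARI selection — at $r = 0.01$ the
blocks are essentially disconnected and recovery should be near-perfect,
while at $r = 0.5$ inter- and intra-degrees are comparable and the ARI
should sit near zero.  The full-scale sweep ($N = 500$,
$r \in [0.01, 0.5]$) runs through the same `run_benchmark()` harness.

`generate_lfr()` implements the LFR construction: degrees from a discrete
power law with exponent $\tau_1$ (minimum degree solved numerically to hit
the target mean $d$), community sizes from a power law with exponent
$\tau_2$, degree-compatible community assignment, and stub matching within
and between communities.  Collisions are re-matched for up to 30 rounds
rather than dropped, so realized degrees and mixing track the sampled
sequences closely ($\pm$ a few percent); the construction is statistical,
not an instance-level replica of any external implementation.  At the
benchmark parameters ($N = 500$, $\tau_1 = 2$, $\tau_2 = 1$, $d = 20$,
$\mu = 0.35$, at most 50 communities) the planted community count lands
around 16–24.  Community-size bounds default to
$[\max(\lceil(1-\mu)k_{\min}\rceil + 1, d/2),\;
\max(3d, 3N/K_{\max})]$, chosen so the expected count respects the
community cap at any $N$.

The semi-synthetic robustness tests perturb a real network: `flip_entries()`
toggles $R = \mathrm{round}(r\,|V|^2)$ uniformly random node pairs (an
independent-Bernoulli mode is also available), and `remove_intra_edges()`
deletes $R = \mathrm{round}(r\,|E|)$ within-community edges, re-evaluating
eligibility after each removal so that no edge incident to a degree-1 node
is ever sampled and no node is isolated.  `pairwise_win_rate()` counts ties
as wins for the first method by default; the policy is explicit and
configurable because reasonable conventions differ.

What passing these benchmarks does *not* show: the SBM and LFR generators
produce unweighted graphs with planted, non-overlapping, assortative
communities.  Real networks mix assortative and disassortative patterns,
carry hubs and sparse peripheries, and their metadata need not align with
structural communities; on such data the method tends to produce extra
small or singleton communities, which are reported as-is (no reattachment
heuristic).

## Problem sizes

The test-suite and acceptance-script runs use the scaled study conditions
stated above: 50 random transport oracles per traffic rate with at most 8
nodes per side, SBM recovery at $N = 150$ over five realisations per
regime, and single LFR draws at $N \le 2000$.  These sizes were chosen so
the full suite replays the benchmarks end-to-end in minutes on one core
while keeping every statistical margin (three standard errors for the
Monte-Carlo checks, wide brackets for power-law tail estimates) intact.

## Known limitations

* The steady state is provably the transport optimum only for $\beta = 1$;
  for $\beta > 1$ it may be one of several local branched optima, so
  branched-regime tests assert qualitative behavior (route consolidation,
  lower-bound feasibility), not uniqueness.
* Neighborhood distributions are degree-uniform; diffusion-based masses are
  out of scope.
* Directed graphs, multigraphs and self-loops are rejected at the door;
  disconnected inputs are handled per component, and isolated nodes become
  singleton communities.
* The method over-counts communities on sparse or disassortative
  structures; merging small communities into larger ones is deliberately
  not implemented.

## A worked example

```{r example, eval = FALSE}
library(orcflow)

net <- generate_sbm(n = 150, k = 3, d = 15, r = 0.01, seed = 1)
fit <- detect_communities(net$graph, beta = 2, max_iter = 15,
                          selection = "ari", truth = net$partition)
glance(fit)
autoplot(fit$trace)
```
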