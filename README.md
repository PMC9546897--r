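# orcflow

Community detection on weighted undirected networks by a discrete Ricci
flow driven by a **β-tunable Ollivier–Ricci curvature**, with the
underlying optimal-transport problems solved by a dynamical
Monge–Kantorovich (DMK) system.

## The idea

For every edge (i, j), compare the probability mass on i's neighborhood
with the mass on j's neighborhood by optimal transport on a local complete
bipartite graph whose costs are shortest-path distances in the network.
The edge curvature is

    κ_β(i, j) = 1 − W_β(m_i, m_j) / d_ij

where `W_β` is the steady-state transport cost of the DMK dynamics

    B diag(μ/w) Bᵀ u = f,      μ′ = ((μ/w)|Bᵀu|)^β − μ,      f = m_i − m_j

and the traffic rate `β ∈ (0, 2]` interpolates between **congested**
transport (β < 1, flux spread over many routes; at β = 1 exactly the
1-Wasserstein distance) and **branched** transport (β > 1, flux
consolidated on few routes).  Edges inside communities have positive
curvature, bridges between communities negative curvature.  The Ricci flow

    w_ij ← d_ij (1 − κ_β(i, j)),   then normalize weights to unit sum

shrinks intra-community edges and stretches bridges; after each iteration a
**surgery** cuts all edges above a threshold chosen to maximize Newman
modularity, and communities are the connected components.  The number of
communities is discovered, never supplied.

For whom: anyone clustering networks who wants a geometry-based detector
whose sensitivity to community granularity can be tuned through a single
transport parameter, together with exact (LP) and entropic (Sinkhorn)
reference solvers and fully seeded synthetic benchmarks.

## A worked example

```r
library(orcflow)

net <- generate_sbm(n = 150, k = 3, d = 15, r = 0.01, seed = 1)
fit <- detect_communities(net$graph, beta = 2, max_iter = 15,
                          selection = "ari", truth = net$partition)
fit
#> <community_fit> 3 communities over 150 nodes
#>   selected iteration 1 by ari = 1  (beta = 2 , dmk solver)
```

The planted three-block structure (inter/intra edge-probability ratio
r = 0.01) is recovered perfectly: 3 communities, adjusted Rand index 1
against the planted labels, found at the first flow iteration.  On the
structureless regime (`r = 0.5`) the same call returns ARI ≈ 0.06 — there
is nothing to find.  `glance(fit)` gives the one-row summary,
`tidy(fit)` the node→community table, `autoplot(fit$trace)` the modularity
trajectory of the flow.

Per-edge curvatures directly:

```r
g <- read_graph_file("network.gml")
curvature_all_edges(g, beta = 0.5)   # tibble: from, to, weight, distance,
                                     # wasserstein, kappa, converged, steps
```

A command line mirrors the R API (`inst/exec/orcflow`):

```sh
orcflow detect graph.gml --beta 1.5 --max-iter 15 --output run1
orcflow stats graph.gml
orcflow benchmark-sbm --params 0.01,0.1,0.3 --betas 0.5,1,2 --n-seeds 10
orcflow compare graph.gml --truth labels.tsv --mode remove_intra
```

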