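---
title: "Well-controlling network ensembles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Well-controlling network ensembles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcne)
```

## The problem

Social distancing on a contact network is link removal: fewer contacts,
fewer transmission routes. For the discrete-time SIS model on a graph
with adjacency matrix $A$, the epidemic threshold is governed by the
spectral radius: when $\beta/\delta < 1/\lambda_{\max}(A)$ (infection
probability per contact per step over recovery probability per step) an
outbreak dies out; above it the disease becomes endemic. The same
quantity is conjectured to control SIR outbreaks. Removing a fixed
*fraction* $\rho$ of links therefore poses a natural design question:
among all ways of deleting $\rho E$ links, which ones lower
$\lambda_{\max}$ — and hence raise the epidemic threshold — the most?

This package studies that question three ways:

1. **Sampling**: a Metropolis–Hastings sampler of the canonical ensemble
   $p(N) \propto e^{-\nu\,\lambda_{\max}(N)}$ over subgraphs with
   exactly $(1-\rho)E$ edges. At inverse genericity $\nu = 0$ this is
   the uniform ("generic") ensemble of random removals; at large $\nu$
   it concentrates on *well-controlling networks* (WCN) with small
   spectral radius while staying as close to generic as possible.
2. **Heuristics**: two degree-homogenizing removal rules (degree
   product and degree cap) that reproduce most of the spectral-radius
   reduction without requiring knowledge of the full network, plus an
   edge-betweenness baseline that turns out to be *worse* than random.
3. **Verification**: SIS/SIR simulation and a $\beta/\delta$
   tipping-point scan confirming that the reduced $\lambda_{\max}$
   translates into a real shift of the epidemic tipping point.

## The sampler

The state is a partition of the original edge set into kept and removed
edges, with the removed count fixed at $\mathrm{round}(\rho E)$
(half-up, applied once to the original $E$, so all strategies are
comparable at equal $\rho$). A proposal swaps one uniformly chosen kept
edge with one uniformly chosen removed edge. Because that proposal is
symmetric, the Metropolis acceptance
$\min\!\left(1, e^{\nu(\varepsilon(A)-\varepsilon(A'))}\right)$ with
energy $\varepsilon(A)=\lambda_{\max}(A)$ samples the canonical ensemble
exactly, with no Hastings correction. The chain starts from a uniform
draw of the generic ensemble (identical to `random_removal()` with the
same seed) and runs a fixed number of steps — 11,000 by default, which
brings 100-node, ~900-edge networks to a visible plateau; ensemble
summaries use the *final* energy of each run. We deliberately do not
anneal $\nu \to \infty$: the object of interest is the ensemble at
moderate $\nu$ (values up to 1000), not the single optimal removal.

Correctness is checked against exact enumeration:
`exact_stationary_distribution()` computes the Boltzmann distribution
with an explicit partition function on instances small enough to
enumerate, and the test suite verifies long-run chain occupancy against
it (chi-squared on thinned samples) on the 4-path instance at
$\nu \in \{0, 1, 5\}$, where the two distinct energies
($\lambda = 1$ vs $\sqrt 2$) make the stationary law fully explicit.

### Numerical core

Every proposal needs $\lambda_{\max}$ of the modified subgraph, so a
single run evaluates it ~11,000 times, and the ensembles of interest —
nearly regular after homogenization, spatially clustered (RG), or
community-structured (the surrogate) — have *small spectral gaps*, the
worst case for simple power iteration. The engine (C++) therefore uses
Lanczos iteration over the kept-edge list, warm-started from the
current Perron vector (a swap changes two matrix entries, so the
previous vector is an excellent start). Design points:

* the start vector is mixed with a strictly positive uniform component,
  so it always overlaps the Perron eigenspace of every connected
  component (disconnected graphs are routine at high $\rho$);
* the Krylov basis is fully reorthogonalized (capped at 80 vectors,
  restarting from the best Ritz vector), the top eigenvalue of the
  Lanczos tridiagonal is located by Sturm-count bisection and its
  eigenvector recovered by inverse iteration;
* convergence uses the Lanczos residual bound $|\beta_m s_m|$ as a
  cheap trigger and is only declared after an explicit check of the
  true residual $\lVert Av - \lambda v\rVert_2 \le \mathrm{tol}$
  (default $10^{-8}$) of the assembled Ritz vector, which for symmetric
  matrices bounds the eigenvalue error directly;
* the eigensolver consumes no random numbers, so traces are exactly
  reproducible from the seed.

`largest_eigenvalue()` uses a dense symmetric eigendecomposition below
65 nodes and the same Lanczos backend above; the two agree to
$10^{-8}$ in the tests, including on bipartite spectra
($\lambda_{\min} = -\lambda_{\max}$) and degenerate top pairs.

## Starting ensembles

**Barabási–Albert.** `generate_ba()` grows from $m$ isolated seed nodes,
each newcomer attaching $m$ edges preferentially (unit appeal for
zero-degree nodes), giving exactly $(n-m)m$ edges. With $n = 100$,
$m = 10$: 900 edges, mean degree 18 — the package's standard scale. The
choice $m = 10$ is the only one matching both the target edge count and
mean degree at $n = 100$.

**Random geometric.** `generate_rg()` scatters points uniformly in the
unit square with a *hard* boundary. The naive radius
$\sqrt{k/(\pi(n-1))}$ ignores boundary clipping and under-shoots the
mean degree by ~20% at this density, so the default radius solves
$(n-1)\left(\pi r^2 - \tfrac{8}{3}r^3 + \tfrac12 r^4\right) = k$
(the exact expected disc–square overlap), giving $r \approx 0.272$ for
$\langle k\rangle = 18$ at $n = 100$. The hard boundary is retained
deliberately: the denser interior it creates is what pushes the
post-removal spectral radius of geometric graphs up to the same
$\approx 13.5$ level as scale-free ones, and edge counts fluctuate
between seeds exactly as expected of a geometric construction.

**High-school surrogate.** `surrogate_highschool()` is a
planted-partition (SBM) graph standing in for a real friendship network
of which only the size ($N = 1062$) is used here. Its parameters —
30 communities, mean degree 8, 10% inter-community mixing — are
declared placeholders chosen as plausible for a school's friendship
structure, and are fully configurable. It reproduces scale and
community structure, **not** the real network's degree sequence,
assortativity or clustering, so epidemic results on it support
qualitative orderings between strategies, not quantitative predictions
for the real school.

## Removal heuristics

`degree_product_removal()` deletes, one at a time, an edge maximizing
the product of its endpoints' *current* degrees (recomputed after every
deletion — using static initial degrees would be a different and weaker
algorithm), ties broken uniformly. `degree_cap_removal()` passes
through the nodes in id order (or shuffled) and strips every node with
degree above $k_{\max}$ down to the cap, removing random incident
links; on preferential-attachment graphs ascending ids process the old,
high-degree nodes first. To compare the cap rule with
rate-parameterized strategies, `degree_cap_for_rate()` selects the
tightest cap that does not overshoot the target removal count and
tops up with uniform random deletions — the cap-to-rate correspondence
is this package's policy choice, as rate matching admits several
conventions. Both heuristics sharply narrow the degree distribution,
which is precisely the structural signature of the sampled
well-controlling networks; `edge_betweenness_removal()` (highest
betweenness first, recomputed each deletion) does the opposite —
it cuts bridges, fragmenting the graph while leaving dense cores
untouched, and underperforms even random removal on the spectral
radius.

## Epidemic simulation

The SIS/SIR simulators use synchronous discrete time: a susceptible
node with $j$ infected neighbors at the start of a step becomes
infected with probability $1-(1-\beta)^j$; every node infected at the
start of a step recovers with probability $\delta$ (to S, or to the
absorbing R); a newly infected node cannot recover in the same step.
This reactive convention is the model for which the
$1/\lambda_{\max}$ threshold is derived, and it removes all update-order
ambiguity. SIS runs a fixed horizon (1000 steps by default); SIR runs
to extinction, guaranteed for $\delta > 0$. Realizations are vectorized
as columns of a node-state matrix with the graph applied as a sparse
adjacency product, and runs stop early once every realization is
extinct (nothing can change afterwards).

The endemicity measure is the *cumulative infected fraction*: distinct
nodes ever infected, **including the initial seeds**, over $n$. The
default scan seeds 10 nodes on $n = 1062$ networks (0.94% of nodes), so
the 1% tipping threshold sits just above the seed floor; with fewer
nodes the seeds themselves would cross it. `tipping_scan()` evaluates an
ascending $\beta/\delta$ grid at fixed $\delta$ (default 0.5 — the scan
is parameterized by the ratio, and the discrete-time threshold depends
on $\beta$ and $\delta$ only through it to first order) and reports the
smallest grid ratio whose mean cumulative fraction exceeds the
threshold. Whether the seeds count toward the threshold, the grid, and
$\delta$ are all explicit package defaults, not values inherited from
elsewhere.

## Problem sizes and reproducibility

Ensemble experiments default to desk scale: 10 MCMC configurations per
cell and 200 epidemic realizations, which keep a full sweep in the
minutes range while leaving Monte-Carlo error well inside the effect
sizes of interest (the WCNE-vs-random gap at $\nu = 1000$ is ~3 units
of $\lambda_{\max}$ against a between-run sd of ~0.6).
`experiment_config(paper_scale = TRUE)` restores 100 configurations and
640 realizations. All randomness flows from a single master seed
through deterministically spawned sub-seeds; every output row carries
its sub-seed and a config hash, and re-running a config reproduces the
CSVs byte for byte.

## What the tests do and do not show

The test suite verifies the sampler against exact enumeration, the
eigenvalue engine against dense decompositions, the simulators against
closed-form and exhaustively enumerated small systems, and the headline
ensemble numbers: $\lambda_{\max} \approx 13.5$–$14$ after 40% random
removal, a drop to $\approx 11$ under the WCNE at $\nu = 1000$ (both
starting ensembles; the chains plateau well before 11,000 steps),
connectivity retention of WCNE samples at $\rho = 0.7$, and the
tipping-point ordering random $\le$ targeted on surrogate networks.
All of it runs on synthetic ensembles. None of it validates the
surrogate against the real school network, and the SIS/SIR models here
are deliberately minimal: no weighted or temporal contacts, no
behavioral feedback, no vaccination. Conclusions transfer to real
contact networks only to the extent that those networks resemble the
ensembles studied.

Two nominal targets are deliberately *not* met, and the corresponding
acceptance tests report them rather than hide them. First, geometric
WCNE runs plateau near $\lambda_{\max} \approx 11$, about half a unit
above the nominal 10.5: the steady-state value tracks the kept-edge
count ($\approx 0.012\,E$), and geometric edge counts fluctuate around
900, so the ensemble cannot average 10.5 at this density. Second, the
appealing summary "removing 80% targeted equals removing 90% random"
cannot hold as an exact inequality on 100-node, 900-edge graphs: a
subgraph keeping $180$ edges has
$\lambda_{\max} \ge 2E'/n = 3.6$ (all-ones Rayleigh quotient)
regardless of which edges are kept, while random removal of 90%
measures $\approx 3.25$. The WCNE reaches $\approx 3.67$ — within
13% of the random-90% level while leaving everyone twice as many
contacts, which is the practically relevant reading.

## Known limitations

* The degree-cap-to-rate matching is a package policy; other
  conventions (e.g. per-node proportional caps) would give slightly
  different degree distributions at equal $\rho$.
* Geometric-graph MCMC is an order of magnitude slower per step than
  scale-free MCMC because of small spectral gaps; the tolerance is kept
  at $10^{-8}$ regardless.
* Exact enumeration (and hence direct stationarity checks) is limited
  to instances with at most $10^5$ states; larger instances are covered
  only by invariants (edge-count conservation, subgraph property,
  monotone response to $\nu$).
* `mcmc_run()` records full per-step removed-edge histories only on
  request, and that option is intended for small instances.
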