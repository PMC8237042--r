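# wcne

Topologically targeted social distancing on contact networks: which
links should be removed so that an epidemic dies out?

For SIS dynamics on a graph with adjacency matrix $A$, an outbreak with
per-contact infection probability $\beta$ and recovery probability
$\delta$ dies out when $\beta/\delta < 1/\lambda_{\max}(A)$. Removing a
fraction $\rho$ of links always lowers $\lambda_{\max}$ — but *which*
links are removed matters enormously. This package:

* samples the **well-controlling network ensemble (WCNE)** — the
  canonical ensemble $p(N) \propto e^{-\nu \lambda_{\max}(N)}$ over
  subgraphs with exactly $(1-\rho)E$ edges — by Metropolis–Hastings
  edge swaps, interpolating from uniform random removals ($\nu = 0$) to
  spectral-radius-minimizing ones (large $\nu$);
* implements **degree-homogenizing heuristics** (iterative
  highest-degree-product deletion; a per-node degree cap) that achieve
  most of the same effect with local information, plus an
  edge-betweenness baseline that performs *worse* than random;
* verifies the resulting threshold shift with discrete-time **SIS/SIR
  simulations** and a $\beta/\delta$ tipping-point scan on
  community-structured surrogate networks ($N = 1062$).

Headline effect at the standard scale (100 nodes, ~900 edges): random
removal of 40% of edges leaves $\lambda_{\max} \approx 13.9$, while
WCNE samples at $\nu = 1000$ reach $\approx 10.9$ — and a *targeted*
removal of 80% of links brings the spectral radius to within ~13% of
what a *random* removal of 90% achieves, while leaving everyone twice
as many contacts.

## Worked example

```r
library(wcne)

g <- generate_ba(100, 10, seed = 1)   # scale-free contact graph, 900 edges
largest_eigenvalue(g)
#> [1] 22.53954
epidemic_threshold(g)
#> [1] 0.04436647

# generic social distancing: drop a random 40% of contacts
rnd <- random_removal(g, rho = 0.4, seed = 2)
largest_eigenvalue(rnd)
#> [1] 13.98567

# targeted: sample the well-controlling ensemble at nu = 1000
tr <- mcmc_run(g, rho = 0.4, nu = 1000, steps = 11000, seed = 3)
tr
#> mcmc_trace: 11000 steps (rho=0.40, nu=1000), lambda_max 13.990 -> 10.894, acceptance 10.0%

# same edge budget, ~28% higher epidemic threshold
epidemic_threshold(tr$final_graph) / epidemic_threshold(rnd)
#> [1] 1.283767
```

The same comparison at the ensemble level, and the epidemic
verification:

```r
ens <- sample_ensemble(function(s) generate_ba(100, 10, seed = s),
                       rho = 0.4, nu = 1000, steps = 11000,
                       n_configs = 10, seed = 1)
ens
#> ensemble_summary: 10 configs (rho=0.40, nu=1000): mean lambda_max 10.912 (sd 0.009)

sg  <- surrogate_highschool(seed = 4)          # N = 1062, 30 communities
red <- degree_product_removal(sg, rho = 0.6, seed = 5)
tc  <- tipping_scan(red, ratios = seq(0.05, 0.95, by = 0.05), delta = 0.5,
                    params = epidemic_params(0, 0.5, initial_infected = 10,
                                             n_realizations = 200),
                    seed = 6)
tc
#> tipping_curve (SIS, delta=0.50): critical beta/delta = 0.05 (threshold 1.00%)
```

`mean lambda_max 10.912` is the steady-state spectral radius of the
well-controlling ensemble (one final value per independent starting
graph). The tipping curve's critical ratio is the smallest
infection-to-recovery ratio at which more than 1% of the school is ever
infected; because the 10 seeded cases already put 0.94% of nodes in the
cumulative count, even slightly supercritical spreading crosses the 1%
line, so critical ratios are small and comparisons between strategies
(the package's tipping reports) matter more than their absolute size.

A command-line front end over the same functions is installed at
`inst/cli/wcne.R` (`generate`, `remove`, `mcmc`, `simulate`, `scan`).
The methods vignette (`vignettes/well-controlling-ensembles.Rmd`)
documents the model, the numerical core, and every tunable default.

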