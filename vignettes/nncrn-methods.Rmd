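---
title: "Methods: correlated random networks and structural robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlated random networks and structural robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(nncrn)
```

This vignette documents the model, the algorithms and the numerical
conventions the package implements, including the places where a
convention had to be chosen among several defensible options.

## The model: degree correlations at distance l

For an undirected simple graph, let $r_l$ be the Pearson correlation
coefficient of the degrees $(k_i, k_j)$ over all ordered node pairs whose
unweighted shortest-path distance is exactly $l$. Each unordered pair
contributes once (twice as an ordered pair), *regardless of how many
distinct shortest paths* connect it -- the "pairs" convention, not the
"walks" convention. $r_1$ is the classical assortativity coefficient;
$r_2$ measures the long-range correlation between second-nearest
neighbours.

$r_l$ is undefined (the package raises an error rather than returning
`NaN`) when no pair exists at distance $l$, or when the degrees over
those pairs have zero variance -- e.g. any regular graph:

```{r}
pearson_r_at_distance(fixture_graph("path_4"), 1)   # -0.5 exactly
pearson_r_at_distance(fixture_graph("path_4"), 2)   # -1 exactly
try(pearson_r_at_distance(fixture_graph("cycle_5"), 1))
```

An *l-NNCRN* (l-th nearest-neighbour correlated random network) is a
maximum-entropy random graph with a prescribed degree sequence and a
coupling $J$ that tilts the distribution by $e^{J r_l}$.

## Metropolis-Hastings rewiring

Both chains are built from the degree-preserving double-edge swap
$(u_1,u_2),(v_1,v_2) \to (u_1,v_2),(v_1,u_2)$ and are lazy: with
probability $1/2$ a step does nothing, which keeps the chain aperiodic.
Every step -- lazy, structurally rejected, Metropolis-rejected or
applied -- consumes one unit of the proposal budget, so acceptance
statistics are directly comparable across runs.

* **Distance 1.** Two ordered edges are drawn uniformly. Proposals that
  would create a self-loop or multi-edge (or that are degenerate no-ops)
  are structurally rejected. Admissible proposals are accepted with
  probability $\min(1, e^{J\,(r_1' - r_1)})$. The degree sequence is
  conserved exactly.
* **Distance 2.** The first ordered edge $(u_1,u_2)$ is uniform; the
  second is drawn uniformly among ordered edges whose *source has the
  same degree* as $u_1$, via degree-indexed edge buckets. Because
  $\deg(v_1)=\deg(u_1)$, the swap conserves not only the degree sequence
  but the entire joint nearest-neighbour degree profile $P(k,k'\mid l=1)$
  -- and therefore $r_1$ -- as a hard constraint, while $J$ tilts $r_2$.

**Sign convention.** The package accepts with
$\min(1, e^{+J\Delta r})$, so positive $J$ drives $r_l$ positive
(assortative) and negative $J$ drives it negative. Some presentations of
the same algorithm write the acceptance rule with the opposite sign while
still labelling positive couplings as assortative; `flip_sign = TRUE`
switches to $\min(1, e^{-J\Delta r})$ for comparison with that form. All
couplings are conventionally quoted in units of the edge count $M$
(`J = 2` means $J_{\mathrm{abs}} = 2M$).

**Incremental statistics.** $r_l$ is a deterministic function of four
pair-moment sums ($n$, $S_1$, $S_2$, $S_{11}$; see
`pair_moment_stats()`). For $l=1$ only pairs incident to the four swap
endpoints change. For $l=2$, any pair whose distance-2 status changes has
at least one endpoint in $\{u_1,u_2,v_1,v_2\}$, and whether a pair is at
distance 2 (non-adjacent with a common neighbour) is decidable locally;
the chain therefore re-examines only the neighbourhoods of the four
endpoints, at expected cost $O(\langle k^2\rangle^2/\langle k\rangle^2)$
per proposal. To bound floating-point drift the sums are recomputed from
scratch every `full_recompute_every` accepted moves (the recomputation
doubles as a consistency check and stops the chain on disagreement), and
`audit = TRUE` compares the incremental and full values after *every*
accepted move.

```{r}
g <- erdos_renyi_graph(500, 5, seed = 1)
res <- rewire_nncrn(g, distance = 1, J = 2, budget_sweeps = 100, seed = 2)
res
```

The distance-2 chain's hard constraint can be verified exactly:

```{r}
res2 <- rewire_nncrn(res$graph, distance = 2, J = 2, budget_sweeps = 50,
                     seed = 3)
audit_constraints(res$graph, res2$graph)   # integer equality of profiles
```

**Extrinsic baseline.** Running the distance-2 chain at $J=0$ samples
uniformly from the graphs sharing the input's degree sequence and
$P(k,k'\mid l=1)$; the average $r_2$ over spaced samples,
`estimate_r2ext()`, is the part of $r_2$ induced purely by the degree
structure and $r_1$. Strongly assortative *or* disassortative networks
both have a positive extrinsic baseline; a network is *intrinsically*
correlated at distance 2 only to the extent its observed $r_2$ departs
from it.

## Generators

* `erdos_renyi_graph(n, mean_degree)` draws $G(N, M)$ with
  $M = \mathrm{round}(N\langle k\rangle/2)$, so the mean degree is exact
  and the degree distribution is asymptotically Poisson.
* `powerlaw_configuration_graph(n, gamma, k_min, k_c)` draws i.i.d.
  degrees from $P(k)\propto k^{-\gamma}$ on the integer support
  $[k_{\min}, k_c]$ (inverse-CDF sampling; one uniformly chosen degree is
  redrawn while the sum is odd), matches stubs uniformly, and removes
  self-loops and multi-edges by degree-preserving swaps against uniformly
  chosen partner edges -- so the realized degree sequence equals the
  drawn one *exactly*, rather than approximately as under edge deletion.
  The default cutoff is the structural cutoff
  $k_c=\lfloor\sqrt{N}\rfloor$, above which an uncorrelated simple graph
  cannot avoid induced degree-degree correlations; with $\gamma = 2.5$,
  $k_{\min}=2$ and $N = 20000$ this gives $k_c = 141$ and a Molloy-Reed
  threshold of $0.07$:

```{r}
tp <- truncated_powerlaw(2.5, 2, floor(sqrt(20000)))
molloy_reed_threshold(k = tp$k, pk = tp$pk)
```

## Percolation and robustness

Robustness is measured by removing edges or nodes and tracking the
largest connected component $N_{\mathrm{LCC}}$. The package uses the
Newman-Ziff union-find method: a removal process that deletes elements in
some order is the mirror image of *adding* them in the reverse order, so
one incremental union-find sweep yields the whole curve. All quantities
live on the **microcanonical occupation grid**: after $n$ of the $M$
edges (or $n$ of the $N$ nodes) are present, with $p = n/M$ (or $n/N$) --
no binomial convolution is applied.

Modes (`make_removal_plan()`): uniform random edges, uniform random
nodes, and targeted attack removing nodes by decreasing **initial**
degree. The targeted order is *static* -- degrees are not recomputed as
the attack proceeds, which is what a fixed addition sequence requires --
and ties are broken uniformly at random per run, so ensembles average
over tie orders. Conventions at $n=0$: edge mode starts at
$N_{\mathrm{LCC}} = 1$ (all nodes present, no edges), node modes at $0$.

Summaries (`robustness_summary()`):

* $f_x$: with $p_x$ the largest grid retention at which
  $\langle N_{\mathrm{LCC}}\rangle < xN$ still holds, $f_x = 1-p_x$ is
  the fraction of removals withstood before collapse below $xN$ (default
  $x = 1\%$). If the condition holds nowhere -- e.g. $xN \le 1$ under
  edge removal, where one node always remains -- the convention is
  $p_x = 0$, $f_x = 1$.
* Schneider $R$: the uniform grid average of
  $S = N_{\mathrm{LCC}}/N$, i.e. the area under the relative
  giant-component curve.
* Susceptibility
  $\chi = (\langle N_{\mathrm{LCC}}^2\rangle - \langle
  N_{\mathrm{LCC}}\rangle^2)/\langle N_{\mathrm{LCC}}\rangle$, set to 0
  where the mean is 0. `susceptibility_peaks()` reports local maxima
  after optional moving-average smoothing; *two* peaks signal a double
  transition, e.g. a dense assortative core collapsing at much lower
  retention than the periphery.

```{r}
cv <- ensemble_curves(res$graph, "random_edge", n_runs = 100, seed = 4)
robustness_summary(cv, x = 0.01, window = 21)
```

## Structural metrics

* `k_core_profile()`: sizes of the maximal subgraphs with minimum
  internal degree $k$ (iterative pruning); assortative rewiring builds
  deep cores at fixed degree sequence.
* `efficiency()`: the mean inverse shortest-path length over ordered
  pairs. **Convention:** the average runs over *connected* pairs only;
  disconnected pairs are excluded rather than contributing 0. This makes
  fragmented remnants look "efficient" (surviving pairs are conditionally
  close), so it is not monotone under dilution; `all_pairs = TRUE` gives
  the common global-efficiency convention. Sources can be subsampled for
  large graphs.
* `molloy_reed_threshold()`:
  $p_c = \langle k\rangle/(\langle k^2\rangle - \langle k\rangle)$, from
  a degree sequence or an analytic distribution; errors when
  $\langle k^2\rangle \le \langle k\rangle$ (no giant component to
  destroy).

## Experiment grids and problem sizes

`run_grid()` sweeps a $(J_1, J_2)$ coupling grid: per realization,
generate $G_0$, run the distance-1 chain at $J_1$, then -- reusing that
network across the $J_2$ values -- the distance-2 chain at $J_2$, then
correlation and robustness measurements. Per-cell seeds are derived
deterministically from a master seed (`derive_seed()`), so any cell is
reproducible in isolation; failures are recorded per cell without
aborting the grid; `summarize_grid()` reports means, standard deviations
and $3\,\mathrm{SE}$ half-widths.

The **default profile is reduced-scale** ($N = 2000$, $200M$ proposal
sweeps, 20 realizations; `inst/configs/reduced_scale.yaml`): it runs in
minutes and recovers the qualitative structure of the full-size study
($N = 20000$, $10^4 M$ sweeps, 100 realizations;
`inst/configs/full_scale.yaml`, days of CPU time). Two reduced-scale
caveats are worth knowing: the attainable $r_1$ range of power-law
networks is asymmetric (the disassortative branch saturates well short of
$-\,$the assortative one), and stochastic thresholds carry finite-size
shifts of order a few percent.

## Numerical choices

* All randomness, including inside the compiled kernels, flows from R's
  RNG, so `set.seed()` (or any function's `seed` argument, applied via
  `withr::local_seed()` without disturbing the caller's RNG state)
  reproduces results exactly.
* Undefined statistics raise errors rather than returning `NaN`; inside
  a running chain a transient zero-variance state is treated as $r = 0$
  so the chain can leave it.
* Couplings are specified in units of $M$; `J_absolute` overrides.
* Tie-breaks (targeted attack) are uniform per run, never index-ordered.
* `full_recompute_every` bounds floating drift of the incremental sums;
  the audit mode exists so tests can assert the drift is effectively
  zero (the suite requires $< 10^{-6}$ over $10^4$ accepted moves).
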