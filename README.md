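# nncrn: correlated random networks and structural robustness

`nncrn` generates and analyses **l-th nearest-neighbour correlated random
networks (l-NNCRNs)**: maximum-entropy random graphs whose degree–degree
correlations at shortest-path distance 1 *and* 2 are controlled
independently by Metropolis–Hastings edge rewiring, together with a
percolation suite for measuring how those correlations change structural
robustness.

## The science in one paragraph

The assortativity coefficient `r1` — the Pearson correlation of the
degrees at the two ends of an edge — is known to shape a network's
resilience, but it does not pin down correlations at longer range. Define
`r_l` as the degree correlation over node pairs at shortest-path distance
exactly `l`. Part of `r2` is *extrinsic*: forced by the degree
distribution and `r1` alone (strongly assortative or disassortative
networks both push `r2` up). The rest is intrinsic, and to isolate it one
needs an ensemble in which `r2` varies while the degree sequence *and*
the full joint nearest-neighbour degree profile `P(k,k'|1)` — hence `r1`
— are held fixed as hard constraints. The package's distance-2 chain
samples exactly that ensemble: a degree-preserving double-edge swap in
which the two swapped edges are required to have equal source degrees,
accepted with probability `min(1, exp(J·Δr2))`. Sweeping the couplings
`(J1, J2)` and running bond/site percolation (random failure) and
degree-targeted attack over the resulting networks quantifies how
second-neighbour correlations shift percolation thresholds, the `f_1%`
collapse point, Schneider's `R`, k-core depth and efficiency — including
the double percolation transition (an extra low-retention susceptibility
peak) that appears when an assortative dense core and its periphery
collapse separately.

## Worked example

Make a Poisson network assortative at distance 1, then *disassortative
at distance 2 without touching `r1`*, and measure the robustness of the
result:

```r
library(nncrn)

g0 <- erdos_renyi_graph(2000, 5, seed = 1)
pearson_r_at_distance(g0, 1)
#> [1] 0.01944406

res1 <- generate_1nncrn(g0, J = 2, budget_sweeps = 200, seed = 2)
res1
#> Metropolis-Hastings rewiring (distance 1, J = 2 M, 1e+06 proposals)
#>   final r1 = 0.7777, r2 = 0.5638
#>   outcomes: applied 222841, rejected_lazy 498842, rejected_structural 4028, rejected_metropolis 274289

res2 <- generate_2nncrn(res1$graph, J = -2, budget_sweeps = 200, seed = 3)
res2
#> Metropolis-Hastings rewiring (distance 2, J = -2 M, 1e+06 proposals)
#>   final r1 = 0.7777, r2 = 0.4446
#>   outcomes: applied 363939, rejected_lazy 499426, rejected_structural 16096, rejected_metropolis 120539
```

`r1` is bit-for-bit unchanged, because the distance-2 chain conserves
the joint degree profile exactly (integer equality, verifiable):

```r
audit_constraints(res1$graph, res2$graph)
#> [1] TRUE
```

`r2` dropped from 0.564 to 0.445 — and the `J2 = 0` baseline shows the
starting value was purely extrinsic:

```r
ext <- estimate_r2ext(res1$graph, n_samples = 10, burnin_sweeps = 60,
                      spacing_sweeps = 5, seed = 4)
c(mean = ext$mean, sd = ext$sd)
#>   mean     sd
#> 0.5602 0.0027
```

Robustness under random edge failure, on the microcanonical
occupation grid:

```r
curve <- ensemble_curves(res2$graph, "random_edge", n_runs = 100, seed = 5)
robustness_summary(curve, x = 0.01, window = 21)
#> Robustness summary (random_edge, 100 runs)
#>   f_1% = 0.8950  (p_1% = 0.1050)
#>   R = 0.6557
#>   160 susceptibility peak(s); highest at p* = 0.1794, 0.1824, 0.188, 0.1888, 0.1968

k_core_profile(res2$graph)
#>   k size
#> 1 1 1982
#> 2 2 1903
#> 3 3 1534
#> 4 4  442
#> 5 5   42
#> 6 6   40
#> 7 7   18

efficiency(res2$graph)
#> Efficiency E = 0.2022 over 3910510 connected ordered pairs; l_max = 14
```

(The assortative rewiring has grown a 7-core out of a graph whose
uncorrelated version stops at the 4-core.)

Full coupling-grid experiments are driven by a config object:

```r
cfg <- experiment_config(J1_values = c(-2, 0, 2), J2_values = c(-2, 0, 2),
                         realizations = 20, master_seed = 1)
results <- run_grid(cfg)
summarize_grid(results)
```

A thin command-line front end with `generate`, `rewire`, `percolate`,
`metrics` and `grid` subcommands is installed under
`system.file("cli", "nncrn.R", package = "nncrn")`, with ready-made
reduced-scale and full-scale YAML profiles in
`system.file("configs", package = "nncrn")`.

## Conventions that matter

* **Sign of the coupling:** acceptance is `min(1, exp(+J·Δr))`, so
  positive `J` makes `r_l` positive; `flip_sign = TRUE` flips the
  exponent for comparison with presentations that write the rule with
  the opposite sign. `J` is quoted in units of the edge count `M`.
* **Pairs, not walks:** each unordered pair at distance `l` counts once,
  however many shortest paths join it. Undefined correlations (no pairs,
  or zero degree variance as in regular graphs) raise errors.
* **Percolation grid:** all curves are microcanonical in the occupation
  number; the targeted attack uses the static initial-degree order with
  uniform tie-breaks; `f_x` uses the supremum-over-grid convention
  (`f_x = 1` when the component never drops below `x·N`).
* **Efficiency** averages inverse distances over *connected* pairs by
  default (`all_pairs = TRUE` for the global-efficiency convention).

See `vignette("nncrn-methods")` for the complete methods description.

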