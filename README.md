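# rarepart

Variation partitioning of community matrices between environment and space,
and the sensitivity of that partition to rare versus common species.

## What it does

Community ecologists decompose the variance of a site-by-species abundance
matrix into four fractions via partial redundancy analysis (pRDA): pure
environment `[a]`, environment-space overlap `[b]`, pure space `[c]`, and
residual `[d]`. With `A`, `C`, `T` the Ezekiel-adjusted R² of the models
`Y ~ X`, `Y ~ W` and `Y ~ X ∪ W` (environmental block `X`, spatial
eigenvector block `W`):

```
[a] = T − C      [b] = A + C − T      [c] = T − A      [d] = 1 − T
```

`rarepart` implements this partition from first principles together with
the full surrounding chain used in stream-metacommunity studies:

- **Predictor reduction** — coefficient-of-variation screening (drop
  CV < 40% and CV > 80%), permutation forward selection with double
  stopping, and correlation-matrix PCA retaining ≥ 90% cumulative
  explanation.
- **Spatial filters** — PCNM eigenvectors of the truncated inter-site
  distance matrix (minimum-spanning-tree truncation, haversine or
  Euclidean distances).
- **Removal cascade** — species deleted one at a time, rarest-first or
  commonest-first, down to 50% of the original richness, with the
  partition re-estimated at every step and summarized as
  `ΔR² = R²(before) − R²(after)`.
- **Stratified null model** — ΔR² under random species removal (999
  replicates), with add-one permutation p-values.
- **Synthetic metacommunities** — a generator with known environmental and
  spatial structure, lognormal abundances and Gaussian niches, so every
  stage can be validated against ground truth.

## Worked example

```r
library(rarepart)

sim <- simulate_metacommunity(seed = 1)   # 120 sites, 60 species, 120 env vars
cfg <- run_config(seed = 1)               # hellinger, 40/80 CV, alpha .05, 999 perms
pp  <- varpart_pipeline(sim$community, sim$env, sim$coords, cfg)
pp$varpart
#> Two-component variation partitioning (pRDA)
#>   n = 120 sites, 3 env / 14 spatial predictors (effective rank)
#>   R2 (unadjusted): env 0.3814  space 0.6167  full 0.7402
#>              fraction adjusted
#>  [a] pure environment   0.1427
#>            [b] shared   0.1867
#>        [c] pure space   0.3675
#>          [d] residual   0.3031

rare <- run_cascade(pp$data$community, pp$X, pp$W, "remove_rare_first", cfg)
comm <- run_cascade(pp$data$community, pp$X, pp$W, "remove_common_first", cfg)
delta_r2(rare)   # -0.0290  : removing the 30 rarest barely moves the model
delta_r2(comm)   #  0.2359  : removing the 30 commonest guts it

nd <- null_distribution(pp$data$community, pp$X, pp$W, cfg,
                        observed = delta_r2(rare))
nd$p_value       # 0.505    : rare-species removal is indistinguishable from
                 #            random removal; common-species removal gives 0.001
```

A positive `ΔR²` (default component: total explained variance
`[a]+[b]+[c]`) means removal reduced what the model explains. `plot(rare)`
draws the per-step correlogram of all four fractions.

A thin command-line front end over the same functions lives at
`inst/scripts/rarepart-cli.R` (subcommands `simulate`, `varpart`,
`cascade`, `null`).

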