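# metapart

Tools for asking a central question of metacommunity ecology on river and
floodplain networks: **how much of the variation in community composition is
driven by local environmental conditions (species sorting), how much by
spatial structure (a fingerprint of dispersal limitation), and how much by
temporal dynamics** — and does the answer shift with the dispersal ability of
the organisms?

The package is aimed at community ecologists working with multi-taxon
surveys (plankton, invertebrates, fish, macrophytes) sampled repeatedly at
sites embedded in a channel network, where "distance between sites" can
legitimately mean either overland (Euclidean) distance or distance along the
watercourses an organism would actually have to travel.

## What it computes

**Spatial predictors.** From a site table and a channel-network edge list it
builds five between-site distance matrices — one overland matrix *D* and four
watercourse matrices *W* (one per hypothesized dispersal-route scenario,
since main rivers flow one way while lateral channels connect in both
directions) — and turns each into orthogonal spatial eigenfunctions:

* **MEM** (distance-based Moran's eigenvector maps): truncate the distance
  matrix at *t* (by default the longest edge of its minimum spanning tree,
  which guarantees connectivity), replace beyond-threshold entries by 4*t*,
  apply the principal-coordinates transform −½d², double-centre, and
  eigendecompose. Eigenvectors with Moran's *I* above its null expectation
  −1/(n−1) are retained as spatial predictors.
* **AEM** (asymmetric eigenvector maps): orient the network downstream,
  build the sites-by-edges matrix of directed paths from an upstream origin,
  column-centre and take the SVD, again keeping positively autocorrelated
  axes. These predictors "know" about flow direction; MEM does not.

**Variation partitioning.** The response is the Hellinger-transformed
community matrix; predictors are the environmental block **E** (log₁₀ except
pH, standardized, collinearity-screened at |r| ≤ 0.7), the spatial block
**S** (MEM or AEM axes), and the temporal block **T** (p − 1 period
dummies). Seven redundancy-analysis fits (E, S, T, E+S, E+T, S+T, E+S+T)
give Ezekiel-adjusted coefficients

    R²adj = 1 − (1 − R²)(n − 1)/(n − m − 1),

with *m* the numerical rank of the predictor block, and
inclusion–exclusion over these yields the eight components
**E, S, T, SE, TE, ST, STE, U** (pure environmental, pure spatial, pure
temporal, the shared fractions, and the unexplained remainder). They always
sum to 1; shared fractions may be negative. Pure fractions are tested with
Freedman–Lane residual permutation (999 permutations by default).

**Cross-group synthesis.** For each organism group the statistic *E − S*
measures whether environment or space dominates; Spearman rank correlation
(exact two-sided p by full enumeration for n ≤ 8) relates it to a
dispersal-ability ranking — phytoplankton (1) … aquatic macrophytes (7) —
with built-in alternative rank schemes for robustness.

**Synthetic metacommunities.** `dispersal_gradient_suite()` generates a
braided two-river network, spatially/temporally structured limnological
variables, and per-group Poisson-lognormal communities whose environmental
and spatial signal weights vary monotonically with dispersal rank, so the
entire pipeline can be validated against known ground truth.

## Worked example

```r
library(metapart)

suite <- dispersal_gradient_suite(n_groups = 7, n_sites = 20, n_periods = 4,
                                  n_taxa = 12, seed = 42)
vp <- varpart3(hellinger(suite$communities$sedentary_fish),
               suite$env_pred, suite$spatial, suite$temporal,
               n_perm = 999, seed = 42)
print(vp)
#> Three-way variation partition (n = 80, 999 permutations)
#>   E         0%
#>   S      31.0% *
#>   T       0.8%
#>   SE     27.7%
#>   TE      2.0%
#>   ST      1.4%
#>   STE    -4.0%
#>   U      40.7%
#> pure-fraction p-values: E = 0.367, S = 0.001, T = 0.060
```

The sedentary-fish-like group was generated with a strong spatial and weak
environmental weight, and the partition recovers exactly that: a large,
significant pure-spatial fraction (S = 31%, p = 0.001), a negligible pure
environmental fraction, and the rest shared or unexplained. Values under
0.5% print as "0"; stored fractions keep full precision.

The cross-group synthesis over all seven groups:

```r
res <- run_gradient(suite, n_perm = 0)
round(res$es, 3)
#>      phytoplankton         periphyton        zooplankton macroinvertebrates
#>              0.083              0.069             -0.032             -0.095
#>     migratory_fish     sedentary_fish        macrophytes
#>             -0.170             -0.306             -0.069
res$spearman
#> rho = -0.786, exact two-sided p = 0.048
```

*E − S* declines from the best dispersers (environment wins) to the worst
(space wins), giving the negative rank correlation the package is built to
detect.

`run_all(config, out_dir)` drives the same analysis from a YAML/list config
(file-based or synthetic inputs, any subset of the five distance sources
plus AEM) and writes per-group partition JSON/CSV, the *E − S* table, a
rank-scheme robustness table and a manifest; `report(out_dir)` renders the
display tables.

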