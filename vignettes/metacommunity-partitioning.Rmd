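---
title: "Partitioning environmental, spatial and temporal drivers of river-network metacommunities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning environmental, spatial and temporal drivers of river-network metacommunities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapart)
```

## The model

A metacommunity sampled at $n$ site-by-period observations is summarized by
a community matrix $Y$ (observations × taxa). After Hellinger
transformation — $y'_{ij} = \sqrt{y_{ij} / \sum_j y_{ij}}$, which makes
Euclidean geometry appropriate for species data and works identically for
abundances and presence/absence — the total variance of the centred $Y$ is
decomposed with respect to three predictor blocks:

* **E**, limnological variables measured per observation;
* **S**, spatial eigenfunctions, constant over time for a given site;
* **T**, indicator variables for sampling periods.

For any block set $X$, the redundancy-analysis statistic is
$R^2 = \mathrm{SS}(\hat Y)/\mathrm{SS}(Y)$, where $\hat Y$ is the
least-squares projection of the centred response on $[1, X]$, and the
Ezekiel adjustment
$R^2_{adj} = 1 - (1 - R^2)\,(n-1)/(n-m-1)$ removes the expected inflation
from fitting $m$ predictors. We take $m$ to be the *numerical rank* of the
centred block (singular values above $10^{-8}$ of the maximum), not its
column count: redundant codings (e.g. a full set of dummies plus an
intercept, or duplicated variables) then cannot bias the adjustment.

Fitting the seven models $E, S, T, ES, ET, ST, EST$ and applying
inclusion–exclusion to their adjusted $R^2$ yields the eight components
$E, S, T, SE, TE, ST, STE$ and $U = 1 - R^2_{adj}(EST)$. The decomposition
sums to one *by construction*, a property asserted to $10^{-10}$ in the
tests; shared components can legitimately be negative (adjusted-$R^2$
arithmetic), and $U$ can exceed 1 when all-noise predictor sets produce
negative adjusted $R^2$. Reported values are never truncated; only the
printed display maps $|{\rm value}| < 0.5\%$ to "0".

The interpretation driving the cross-group analysis: a large pure **E**
indicates species sorting by local conditions; a large pure **S** is
consistent with dispersal limitation (though it can also reflect unmeasured
spatially structured environment — which is why the cross-group trend, not
any single partition, carries the inferential weight); pure **T** captures
temporal turnover shared across sites.

## Spatial predictors

**Distances.** Sites live on a channel network with metre-valued edge
lengths. Overland distance is planar Euclidean (inputs must be projected
coordinates; latitude/longitude is rejected by design). Watercourse
distance is the undirected shortest path over the edges active in a given
dispersal-route scenario; four scenario tags (`s1`–`s4`) let the analyst
encode alternative hypotheses about which lateral channels carry dispersal.
Distances are deliberately symmetric even on one-way river segments —
directionality is expressed only through the AEM basis, so the MEM and AEM
predictors answer cleanly separated questions.

**MEM.** The truncation threshold $t$ defaults to the longest edge of the
minimum spanning tree of the distance matrix — the smallest $t$ for which
the neighbour graph is connected, the standard dbMEM default — and is
user-overridable. Beyond-threshold distances are replaced by $4t$,
following long-standing PCNM practice. The matrix $-\frac{1}{2}d^{*2}$ is
double-centred and eigendecomposed; axes with $|\lambda|$ below $10^{-9}$
of the maximum are discarded as numerical zeros. Eigenvectors are stored
unit-norm (scaling by $\sqrt\lambda$ would be immaterial in a regression
and unit norm keeps the orthogonality tests exact).

**Positive-autocorrelation selection.** Each eigenfunction gets a Moran's
$I$ with binary weights $w_{ij} = 1 \iff 0 < d_{ij} \le t$. We retain axes
with $I > E(I) = -1/(n-1)$, the expectation under no autocorrelation,
rather than $I > 0$: $E(I)$ is the statistically meaningful zero point, and
the choice affects borderline axes only. A `cut = "zero"` switch restores
the literal rule.

**AEM.** Main-river edges are oriented downstream, laterals per an explicit
orientation map; the oriented scenario subgraph must give each site a
unique directed path from the origin (default: the most upstream main-river
node). The sites-by-edges path-membership matrix is column-centred and
decomposed by SVD; left singular vectors are the eigenfunctions, with
squared singular values as eigenvalues and Moran's $I$ computed on the
symmetrized adjacency among sites. Edges are unweighted (presence on the
path); a length-decay weighting would be a natural extension hook. If a
scenario admits two routes to a site the constructor refuses and tells the
user to split the hypothesis into separate scenarios — route ambiguity is a
scientific statement, not something to resolve silently. One numerical
subtlety: when singular values are degenerate, the positively
autocorrelated *subset* of axes can depend on the arbitrary rotation within
the degenerate subspace, so the order-invariance guarantee applies to the
full basis (`select = FALSE`); the tests check exactly that.

## Data preparation

Environmental variables are $\log_{10}$-transformed except pH (already a
log scale), then standardized to zero mean and unit sample variance.
Standardization is a deliberate choice — limnological variables span four
orders of magnitude in scale, and while $R^2$-based partitioning is
invariant to column scaling, standardized predictors keep the collinearity
screen and any inspection of coefficients interpretable. Collinearity is
screened greedily: while any pair exceeds $|r| = 0.7$ (a common rule of
thumb; configurable), the member of the worst pair with the larger mean
$|r|$ against the remaining variables is dropped, ties broken toward the
later column; every removal is logged. Chlorophyll-a is removed as a
predictor for phytoplankton and periphyton responses, where it would be
circular (it is an algal-biomass proxy).

Temporal structure enters as $p-1$ dummies with the last period (canonical
sort order) as reference; the partition depends only on the column space,
so the reference choice is immaterial — asserted in the tests by comparing
treatment coding, one-hot coding and an invertible recombination.

Observations are (site, period) pairs, canonically ordered period-major;
unbalanced designs are allowed, and observations lacking an environmental
or community record are dropped with a warning. Spatial eigenfunctions are
replicated across periods within a site — connectivity is treated as
time-invariant, which is the main simplification relative to flood-pulse
systems (see Limitations). A rare-taxon filter (taxa occurring at exactly
one site, pooled over periods) supports sensitivity re-runs; the main
analysis keeps all taxa.

## Permutation inference

Pure fractions are tested by Freedman–Lane residual permutation: fit the
conditioning blocks, permute the residual rows, rebuild a pseudo-response,
and recompute the pseudo-$F$
$\bigl((\mathrm{SS}_{full}-\mathrm{SS}_{red})/m_x\bigr) /
\bigl(\mathrm{SS}_{res}/(n-m_x-m_z-1)\bigr)$, with
$p = (1 + \#\{F^* \ge F_{obs}\})/(1 + n_{perm})$. The default
$n_{perm} = 999$ gives a minimum attainable $p$ of $1/1000$. Freedman–Lane
is the standard choice for conditioned canonical analysis; a raw
row-permutation scheme is available as an option. Permutations are
unrestricted across observations (a within-period restriction is a
reasonable alternative for strongly seasonal designs and can be emulated
via the `scheme` hook in future versions). One master seed drives
everything; the three pure-fraction tests use fixed offsets from it, so
results are bit-reproducible.

The type-I calibration test generates pure-noise responses (30
observations, 5 taxa) over real E/S/T blocks and checks that the rejection
rate at $\alpha = 0.05$ over 500 replicates of 199 permutations stays
within the binomial band 3–7%.

## The cross-group dispersal analysis

Per group, $E - S$ contrasts species sorting against spatial structure.
Spearman's $\rho$ between $E - S$ and a dispersal-ability ranking is
computed on average-tie ranks; for $n \le 8$ groups without ties the
two-sided $p$ is exact, by enumerating all $n!$ pairings and counting
$|\rho^*| \ge |\rho|$ (for a perfectly monotone vector over 7 groups this
gives $p = 2/5040$); otherwise a seeded Monte-Carlo approximation with
99,999 draws is used. Two-sided $p$-values are reported throughout because
the sign of the relationship is the question, not an assumption.

Because any dispersal ranking is coarse — the two microalgal groups in
particular can hardly be ordered — `rank_schemes()` generates the default
ranking, all adjacent-pair swaps, and a microalgae-tied variant, and
`rank_robustness()` crosses them with every spatial-predictor scenario,
flagging the result robust only when $\rho$ keeps its sign in every cell.
These schemes are our own reconstruction of the natural perturbation space
of such a ranking.

## The synthetic generator

The generator emulates the sampling design the package targets: up to 36
sites on two roughly parallel river stems joined by lateral channels, up to
8 periods, ~12 limnological variables (partly spatially and temporally
structured), and 7 organism groups. Scenario tags differ in which laterals
are open (`s1` all, `s2` downstream only, `s3` upstream only — a tree,
suitable for AEM — and `s4` both extremes), so watercourse scenarios are
nested and the monotonicity of shortest paths under edge addition is
testable. Edge lengths exceed the straight chord by a meander factor of
1.1–1.4, so watercourse ≥ overland distance holds edge-wise by
construction.

Communities follow a Poisson-lognormal model: a latent matrix
$L = w_{env} Z_E B_E + w_{spa} Z_S B_S + w_{tmp} Z_T B_T + \sigma N$ with
each signal component standardized to unit latent variance, and counts
drawn as $\mathrm{Poisson}(\bar a\, e^{L - \bar L})$ with a target mean
abundance of 5. Species responses are linear on the log-rate scale,
matching the linear-response assumption of redundancy analysis —
deliberately, so that recovery tests probe the pipeline rather than
model mismatch; a unimodal-niche generator would be the natural extension
for studying that mismatch. One group is emitted as presence/absence to
mirror macrophyte surveys. Defaults: $\sigma = 0.5$ (signal-to-noise
typical of a strong field gradient), 20 taxa per group, shared temporal
weight 0.2 in the gradient suite, and environmental mixing weights of 0.5
(spatial) and 0.3 (temporal), reflecting that real limnological gradients
are themselves spatially and temporally structured.

What passing recovery tests do *not* show: that the method resolves the
generating weights under unimodal responses, strong zero-inflation,
observation-process noise, or time-varying connectivity — none of which
the generator produces. They show that when the data-generating process
matches the model's assumptions, the partition attributes variance to the
correct source and the permutation tests are calibrated.

Validation problem sizes (chosen to exercise every code path while keeping
the full suite under a minute): identity and oracle checks at $n \le 20$
observations and $\le 10$ network nodes against brute-force enumeration,
dense eigendecomposition and per-column OLS; type-I calibration at 30
observations × 500 replicates; recovery at 64 observations × 50
replicates; the dispersal gradient at 20 sites × 4 periods × 7 groups × 20
replicate worlds; the watercourse-vs-overland contrast at 20 sites × 20
replicate worlds (pure-S with watercourse-MEM predictors beats overland in
≥ 80% of worlds when the truth is watercourse-structured).

## Numerical choices

* Rank and basis tolerances: singular values $> 10^{-8}$ of the maximum
  (predictor rank), eigenvalues $> 10^{-9}$ of the maximum (MEM/AEM null
  axes).
* Permutation $p$ uses $\ge$ with the observed statistic counted once
  (never $p = 0$).
* Distance matrices are symmetrized ($\tfrac12(D + D^\top)$) before graph
  construction to absorb floating-point asymmetry from shortest-path
  algorithms.
* Degenerate inputs fail loudly with named offenders: non-positive values
  sent to the log transform, all-zero community rows, constant vectors in
  Moran's $I$ or Spearman, saturated models ($n \le m + 1$), disconnected
  scenario subgraphs (with component membership), unreachable or ambiguous
  AEM routes.
* Collinearity tie-break (equal mean $|r|$): drop the later column —
  arbitrary but deterministic and logged.

## Limitations

* Connectivity is static; flood-pulse systems rewire seasonally, and a
  time-varying edge set (hence time-varying spatial predictors) is out of
  scope.
* Watercourse distances are graph distances on the user's edge list, not
  measurements along digitized channel geometry; junction nodes allow the
  edge list to approximate real geometry as finely as desired.
* Sites must be network nodes; there is no snapping of off-channel sites.
* No forward selection of eigenfunctions or environmental variables:
  selection is by the Moran's-$I$ sign rule and the collinearity screen
  only, keeping the predictor sets hypothesis-driven rather than
  data-dredged.
* The partition quantifies association, not process: pure **S** is
  evidence for dispersal limitation only jointly with the cross-group
  trend in $E - S$.
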