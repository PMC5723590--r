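---
title: "Scale-dependent beta diversity: models, choices and limits"
author: "betagrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale-dependent beta diversity: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betagrain)
```

## The question the package answers

In a fully stem-mapped forest plot of fixed extent, how much do sampling
units differ in tree species composition — beta diversity — and does the
answer, and its ecological interpretation, depend on the size of the
sampling unit (the *grain*)? Two deterministic assembly processes are
usually invoked at local scales: *environmental filtering* (habitat
conditions select species, so units with similar soils and topography
share species) and *dispersal limitation* (restricted propagule movement
makes nearby units similar regardless of habitat). betagrain implements
the full inference chain that separates the two, at several grains, in
one reproducible pipeline.

## Beta diversity as total community variance

At each grain size the plot is tiled into square grains (half-open
footprints, remainder strips at the high-coordinate edges discarded, so
every stem belongs to exactly one grain or to no grain). Counting living
stems per grain and species gives the abundance table
$X = [x_{ij}]$. Each row is Hellinger-transformed,

$$y_{ij} = \sqrt{x_{ij} \Big/ \sum_k x_{ik}},$$

so that Euclidean geometry on $Y$ behaves well for community data and
the table can enter linear ordination directly. Beta diversity is the
total variance of $Y$:

$$SS_{Total} = \sum_i \sum_j (y_{ij} - \bar y_j)^2, \qquad
  BD_{Total} = \frac{SS_{Total}}{n - 1},$$

which for Hellinger data lies in $[0, 1]$. The per-grain terms
$SS_i = \sum_j (y_{ij} - \bar y_j)^2$ give the local contributions
$LCBD_i = SS_i / SS_{Total}$, which sum to one and flag compositionally
unique grains. `ssTotal()` computes the column-centering formula and
the pairwise-distance identity $\frac{1}{n}\sum_{i<h} D_{ih}^2$ side by
side and asserts their agreement, so a centering bug cannot pass
silently.

Empty grains (possible in sparse synthetic communities, effectively
impossible at field stem densities) are dropped with a warning before
transformation, because $y_{ij}$ is undefined on a zero row; a flag
turns this into an error instead.

## Spatial predictors

Spatial structure is modelled by PCNM eigenfunctions: with site
distances $D$, distances beyond a truncation $t$ are replaced by $4t$,
the matrix $-\tfrac12 D^{*2}$ is Gower-centered and
eigendecomposed, and eigenvectors are kept when their eigenvalue
exceeds $10^{-8}\lambda_{max}$ *and* their Moran's I (binary
within-$t$ weights) exceeds the permutation-null expectation
$-1/(n-1)$ — positive spatial autocorrelation is what a dispersal
signal looks like. Defaults follow the classical construction: $t$ is
the longest edge of the minimum spanning tree (the smallest truncation
that keeps the neighbour graph connected) and the $4t$ replacement is
the conventional constant; neither is dictated by the data, so both are
parameters. Eigenvector signs are fixed by making the
largest-magnitude loading positive, which makes outputs identical
across linear-algebra backends.

## Ordination, selection, partitioning

RDA here is multivariate least squares of the centered $Y$ on
standardized predictors; $R^2 = SS_{fit}/SS_{Total}$, corrected as
$R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-m-1)$. Significance comes from
permutation: rows of $Y$ for simple tests, residuals of $Y$ on the
conditioning set (permutation of residuals under the reduced model) for
partial ones, with the add-one estimator
$p = (1 + \#\{F^* \ge F\})/(1 + n_{perm})$.

Predictors are screened by forward selection with the double stopping
criterion: a global test of all candidates gates the procedure, the
adjusted $R^2$ of the full candidate model is a ceiling that the
selected model may not exceed, and each step admits the candidate with
the largest added $R^2$ only if its partial permutation test passes.
The source only fixes the 5% permutation criterion; the ceiling rule
comes from the procedure's standard formulation and can be switched
off (`adjR2Ceiling = FALSE`).

One property of the ceiling deserves a warning. The adjusted $R^2$ of
the true predictor subset and of the full candidate model are both
unbiased estimators of the *same* population quantity, so in a
candidate pool of "true variables plus pure noise" the last informative
variable overshoots the ceiling with probability close to one half and
gets rejected. This is not an implementation artifact — the R
ecosystem's reference stepwise-RDA routine behaves identically on the
same data — but it means the default selection is deliberately
conservative about the final variable, trading a little power for a
guarantee against overfitting past the global model. Recovery
simulations that ask "are all true variables found?" should therefore
read the \code{adjR2Ceiling = FALSE} behaviour; the pipeline default
keeps the ceiling on. Environmental covariates are z-scored
before selection; PCNM vectors enter as produced. Ties in added $R^2$
are broken by candidate order, making selection deterministic given the
seed.

Environmental and spatial candidates are selected *separately*, not
pooled: the two sets play asymmetric roles in the partition, and
pooling would let a strong spatial signal crowd out marginal
environmental covariates before the partition ever sees them.

Variation partitioning combines three models,
$ab = R^2_{adj}(E)$, $bc = R^2_{adj}(S)$, $abc = R^2_{adj}(E \cup S)$,
into $a = abc - bc$, $c = abc - ab$, $b = ab + bc - abc$,
$d = 1 - abc$, which sum to one exactly. The environmental effect is
read as $[a+b]$ and the spatial effect as the pure fraction $[c]$.
$[b]$ can be negative on the adjusted scale (a suppressor artifact);
it is reported as computed and only floored at zero for display in the
bar figure, where the raw value is annotated. Tested components are
$[a+b]$, $[c]$ (partial on $E$), $[a]$ (partial on $S$) and the joint
model; $[b]$ is not independently testable and never gets a p-value.

## The synthetic-data generator

The field data behind this class of study are rarely deposited, so the
package carries its own ground truth. `generateEnvironment()` draws
each soil variable and elevation as a stationary Gaussian random field
with exponential correlation $C(d) = e^{-d/\phi}$ (Cholesky on a 10 m
grid, bilinear interpolation between nodes). What matters downstream is
the correlogram, not the simulation algorithm; the tests check the
decay, not the factorization. Default marginals are plausible
temperate-forest values (e.g. pH 5.5 ± 0.4, rootable depth 70 ± 25 cm
clamped to the physical 10–130 cm band, elevation with a gentle
deterministic trend so slopes and aspects are non-degenerate);
correlation ranges of 50–100 m put several habitat patches inside a
260 × 200 m plot, which is what makes filtering recoverable at 20–50 m
grains.

`generateCommunity()` places a fixed total number of stems. Species
abundances follow a lognormal rank-abundance draw. Each species' cell
intensity is the mixture
$(1-w)\,\lambda_{env} + w\,\lambda_{clust}$: a log-linear niche
response on the standardized surfaces (coefficients drawn once per
seed, response scaled to sd `nicheStrength`) versus a Thomas cluster
density (Gaussian kernels of sd `clusterSD` around species-specific
Poisson parents of intensity `clusterRate`). Stems are jittered
uniformly within cells, so `nicheStrength = 0, mixtureWeight = 0` is
*exact* complete spatial randomness — the property the chi-square
calibration test uses. dbh is exponential with mean 8 cm shifted to the
1 cm census minimum; it is carried for realism but unused by the
abundance-based analysis.

The canonical `scenario()` parameterizations are fixed once: 40
species and 16,000 stems on 260 × 200 m (the order of magnitude of a
fully censused 5.2-ha temperate plot, which spans roughly 22–64 species
and 12,000–29,000 stems across communities); `pure_env` uses
`nicheStrength = 2, w = 0`; `pure_dispersal` uses `w = 1` with
`clusterSD = 12` m and about 26 parents per species; `mixed` sits at
`nicheStrength = 1.2, w = 0.5`. A niche sd of 2 on the log scale gives
strong but not deterministic habitat sorting; 12 m clusters are small
relative to the 20 m grain, which is what makes dispersal limitation
visible as positive spatial autocorrelation at the finest grain.

What the generator does *not* emulate: demography between censuses,
interspecific interactions, topography-dependent dispersal, and
observation error in coordinates or identifications. Passing the
recovery tests therefore shows that the inference chain attributes
*these* processes correctly under known truth — not that any field
community is governed by them.

## Environment upscaling and topography

Soil is sampled per 20 × 20 m base grain (the package stores the
per-grain averaged value; within-grain core replication is out of
scope). Two routes carry it to coarser grains: `block_mean` (average of
base samples whose centres fall inside the target grain — exact mass
conservation on nesting designs, the default because it is
assumption-free and reproducible) and `kriging` (first-order trend
surface, exponential variogram with nugget fitted to the empirical
semivariogram by Cressie-weighted least squares, ordinary kriging of
the residuals, trend added back). The kriging route is a documented
in-package implementation, configurable rather than fixed, and the
tests require it to beat block means at point prediction on smooth
surfaces. Topography per grain follows large-plot conventions: mean of
the four vertex elevations; slope as the mean slope of the four
triangular planes obtained by dropping each vertex in turn; aspect as
the downslope bearing of the least-squares plane (degrees clockwise
from north, flat grains encoded 0 with a flag); convexity as the grain
mean elevation minus the mean of its up-to-8 neighbours. Vertices of
coarser designs are bilinearly interpolated from the measured base
vertex grid.

## Numerical and design choices

* Grain membership is half-open, anchored at the plot origin; remainder
  strips go to the high-coordinate edges. Any anchoring yields the same
  grain counts; this one is deterministic.
* All permutation p-values use the add-one estimator, so the smallest
  attainable p is $1/(1+n_{perm})$; the function default is
  `nPerm = 999`. Simulation-heavy tests and examples use 199 (level
  granularity $1/200$), which changes nothing about the direction of
  any comparison.
* Degenerate F statistics (zero residual variance, e.g. a perfect
  predictor) report $p = 1/(1+n_{perm})$ with a flag rather than NaN.
* Sub-seeds for grain sizes and scenario components are derived by a
  fixed integer hash of (master seed, key), so streams are decoupled
  but every number in a report is a pure function of the config.
* Collinear predictors raise an error naming the offending columns;
  constant columns are silently dropped (they carry no information
  beyond the intercept).
* Problem sizes in the test suite: recovery checks run 20 seeds of the
  full 5.2-ha scenarios at 199 permutations; calibration checks use 500
  small-matrix simulations. These sizes give binomial standard errors
  well below the margins being asserted.

## Known limitations

* The RDA is transformation-based (Hellinger); distance-based RDA on
  arbitrary dissimilarities and CCA are out of scope, as are canonical
  axes and biplots — the pipeline needs only explained variance.
* LCBD values are mapped, not tested; per-grain significance would need
  a species-permutation null that the pipeline does not implement.
* The variogram model is fixed to exponential-with-nugget; on fields
  with strong anisotropy the kriging route will be mis-specified
  (block means remain safe).
* With 20 grains (50 m design) the permutation tests are honest but
  weak; the driver warns below 10 grains and the widest designs should
  be read with that in mind.

## A worked run

```{r, eval = FALSE}
cfg <- runConfig(scenario = "mixed", seed = 1, nPerm = 199,
                 outDir = "betagrain-out")
report <- runAll(cfg)
report            # BD per grain size, environment vs space fractions
renderFigures(report, "betagrain-out/figures")
```

The same chain is exposed piecewise — `scenario()`,
`aggregateCommunity()`, `hellingerTransform()`, `betaDiversity()`,
`pcnm()`, `forwardSelect()`, `varpart()` — and as a thin command-line
wrapper in `inst/scripts/betagrain-cli.R`.
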