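# betagrain

Scale-dependent beta diversity and its causes in stem-mapped forest
plots.

## What it is for

Community ecologists working with fully mapped forest plots (every
stem ≥ 1 cm dbh with coordinates and a species label) routinely ask two
questions: how much does tree species composition vary across the plot
(*beta diversity*), and is that variation driven by the environment
(*environmental filtering*) or by space itself (*dispersal
limitation*)? Both answers depend on the size of the sampling unit.
betagrain runs the whole inference chain at several square grain sizes
inside a fixed plot extent, so the scale dependence itself becomes the
result. The same machinery applies to any site-by-species abundance
table with coordinates — the method set is identical to the
beta-diversity toolkit used in microbiome and metagenomic ecology.

## The statistics at its core

* **Beta diversity as total variance.** The grains-by-species table
  `X` is Hellinger-transformed, `y_ij = sqrt(x_ij / Σ_k x_ik)`, and
  beta diversity is `BD_Total = SS_Total / (n − 1)` with
  `SS_Total = Σ_ij (y_ij − ȳ_j)²`; per-grain shares
  `LCBD_i = SS_i / SS_Total` flag compositionally unique grains.
* **PCNM spatial eigenfunctions.** Eigenvectors of the Gower-centered,
  truncated distance matrix among grain centroids, screened by
  positive Moran's I — an orthogonal basis of spatial patterns from
  broad to fine scale.
* **RDA variation partitioning.** Redundancy analysis of `Y` on
  forward-selected environmental covariates (six soil variables plus
  mean elevation, slope, aspect, convexity) and on forward-selected
  PCNM vectors, combined into adjusted-R² fractions: pure environment
  [a], spatially structured environment [b], pure space [c],
  unexplained [d]. Environment is read as [a+b], space as [c];
  significance comes from permutation tests (residual permutation for
  partial components), selection uses the double stopping criterion.
* **Synthetic ground truth.** A generator places stems by a tunable
  mixture of log-linear niche response to Gaussian-random-field
  environments and Thomas-process clustering, so environmental
  filtering and dispersal limitation exist in known amounts and the
  pipeline's attribution can be validated end to end.

## A worked example

```r
library(betagrain)

cfg <- runConfig(scenario = "mixed", seed = 1, nPerm = 199)
report <- runAll(cfg)
report
```

```
StudyReport
  beta diversity by grain size:
 grain_size n_grains covered_area_ha n_species ss_total bd_total
         20      130            5.20        40   33.974   0.2634
         30       48            4.32        40    7.659   0.1630
         40       30            4.80        40    3.708   0.1279
         50       20            5.00        40    1.875   0.0987
  environment [a+b] vs space [c] (adjusted R2):
 grain_size env_ab space_c
         20 0.2744 0.25532
         30 0.3317 0.16185
         40 0.3353 0.11148
         50 0.3713 0.08684
```

Read: on a synthetic community where both processes act (`"mixed"`),
beta diversity falls monotonically as grains grow from 20 to 50 m
(larger units capture more of the community, so they look more alike),
the environmental fraction [a+b] grows with grain size, and the pure
spatial fraction [c] is strongest at the finest grain — the classic
signature of filtering acting at coarse grains and dispersal limitation
at fine ones. `renderFigures(report, "figs")` draws the BD-vs-grain
curve, shaded LCBD maps, and the grouped partition bars with
significance stars.

Every stage is also exposed on its own (`scenario()`,
`aggregateCommunity()`, `hellingerTransform()`, `betaDiversity()`,
`pcnm()`, `forwardSelect()`, `varpart()`, `scaleSeriesVarpart()`), and
`inst/scripts/betagrain-cli.R` wraps them as shell subcommands
(`simulate`, `aggregate`, `betadiv`, `pcnm`, `varpart`, `run-all`).

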