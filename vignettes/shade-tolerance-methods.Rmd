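---
title: "Evaluating shade tolerance in soybean germplasm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating shade tolerance in soybean germplasm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadetol)
```

## The problem

In maize–soybean strip intercropping, the taller maize canopy shades the
soybean rows. Soybean reacts with the shade-avoidance syndrome — stem
elongation and higher basal pods at the expense of branching, pod set,
and seed yield. Breeding for intercropping therefore needs a way to
score hundreds of genotypes for how well they *hold* their performance
under canopy shade, not just how well they perform in monoculture.

`shadetol` implements the full evaluation workflow for such trials: a
panel of genotypes grown under a monoculture control (`CK`) and an
intercrop shade treatment at one or more locations, in a split-plot
design within randomized complete blocks, scored for six agronomic
traits — plant height (PH, cm), basal pod height (BPH, cm), node number
per plant (NNP), branch number (BN), pod number per plant (PNP), and
seed yield per plant (SYP, g).

## The linear model and its ANOVA

Each trait is analyzed per location with the split-plot model

$$Y_{ijk} = \mu + R_i + C_j + \delta_{ij} + G_k + (CG)_{jk} + \epsilon_{ijk}$$

where $R_i$ is the random replication (block) effect, $C_j$ the fixed
cropping-system (whole-plot) effect, $\delta_{ij}$ the whole-plot error
shared by every genotype in a replicate × system main plot, $G_k$ the
genotype (subplot) effect, $(CG)_{jk}$ the system × genotype
interaction, and $\epsilon_{ijk}$ the subplot error.

`fit_split_plot()` produces the sequential (Type I) decomposition on
the ordered model and tests each term in its own stratum: the cropping
system against the whole-plot error mean square (with $(r-1)(c-1)$
denominator df — only 2 when there are 3 blocks and 2 systems, which is
why whole-plot power is intrinsically low), genotype and the
interaction against the subplot error. Degrees of freedom always sum to
$N-1$ and sums of squares are additive; both are asserted by the test
suite on every fit. Unbalanced panels are fitted with sequential sums
of squares and a warning rather than an error, because ragged germplasm
panels are the norm. `two_way_anova()` is the companion
location × treatment fixed-effects analysis run on replicate-averaged
genotype means, with genotypes acting as the replication units.

A REML mixed-model fit is deliberately out of scope: the workflow
treats the model as a classical ANOVA with error strata, which is exact
for balanced data and transparent about what each F-test uses as its
denominator.

Normality and variance homogeneity are checked with Shapiro–Wilk and
Levene's tests (`assumption_checks()`); following standard practice for
these trials the checks are reported, never used to gate an analysis.

## Tolerance indices and classification

The per-trait tolerance index is the ratio

$$\mathrm{TI} = \frac{\text{trait value under shade}}{\text{trait value under control}},$$

computed on replicate-averaged genotype means (computing per-replicate
ratios first and averaging afterwards is available through the panel
profiler's inputs, but ratios of means are the default because plot
means of 10 plants are the unit every downstream analysis uses). TIs
are winsorized at a cap of 2.0 — reported TI ranges in this literature
top out at exactly 2.000 — and the cap is configurable. Edge rules: a
zero control mean with positive shade value maps to the cap (complete
recovery of a trait absent under control), 0/0 is missing.

The overall tolerance index is the unweighted arithmetic mean of the
available trait TIs, the simplest aggregator consistent with panel
means reported near 1.03; it is pluggable (per-trait weights) because
no standard definition exists. The yield-stability index defaults to
the SYP ratio, exposed under its own name so an alternative stability
measure can be swapped in; both functions record their definition in an
attribute so outputs are self-describing.

Classification uses four categories with left-open/right-closed
intervals so they tile the positive line without overlap:

| category  | interval        |
|-----------|-----------------|
| sensitive | (0, 0.681]      |
| moderate  | (0.681, 0.850]  |
| tolerant  | (0.850, 1.000]  |
| enhanced  | (1.000, ∞)      |

Classification is applied to the overall TI by default; which index to
classify on is a parameter (`classify_on`) because a trait-specific
classification is equally defensible.

## Paired correlation, path analysis, PCA

`paired_correlation()` gives the Pearson r and least-squares line of
shade genotype means on control genotype means per trait and location —
the genotype-ranking-stability view of G×E.

`path_analysis()` is classical Wright path analysis of SYP on the five
architectural predictors: all variables standardized, direct effects
solving $R_{xx}\,p = r_{xy}$, indirect effect of predictor $i$ via $j$
equal to $r_{xx}[i,j]\,p_j$, and total determination
$R^2 = \sum_i p_i\,r_{xy}[i]$. The direct effects are identical to
standardized partial-regression coefficients, so significance comes
from the t-tests of the equivalent multiple regression. A predictor
correlation matrix with condition number above 1e10 aborts with the
most-correlated pair named. The location stratum is an explicit
parameter (per location or pooled) since path models can defensibly be
fitted either way; the pipeline pools locations per treatment.

`pca_traits()` runs PCA on the correlation matrix (z-scored traits) by
default because the six traits live on incommensurate scales;
covariance-matrix PCA is a flag. Signs are fixed deterministically —
the largest-magnitude loading of each component is made positive — so
repeated runs and independent implementations agree. Constant columns
are dropped with a warning.

## Quartile transitions, clustering, importance

`quartile_transition()` ranks genotypes by SYP within each treatment
independently and assigns quartiles by rank position (Q4 = top 25%,
ties broken by genotype-id order so results are deterministic).
*Elite-stable* genotypes sit in Q4 under both systems; *shade-adaptive*
genotypes rise from Q1–Q3 under control to Q4 under shade. Because the
assignment is rank-based, labels are invariant to any increasing
transformation of the trait. Every summary prints its denominator
explicitly (genotypes scored at that location) — percentages without
their denominator are not comparable across panels.

`cluster_tolerance_space()` standardizes the six trait TIs, projects
onto the two leading principal components, and partitions with k-means
(k = 3 by default). Seeding uses multi-start Lloyd (`nstart = 25`)
under the caller's seed, the `stats::kmeans`-native equivalent of
k-means++-style initialization: with 25 starts on two components the
global optimum is found reliably and a fixed seed reproduces the
partition bit-for-bit. `cluster_k_scan()` reports the within-SS curve
over k as a diagnostic, never as an automatic selector.

`importance_regression()` fits a random forest of the target index on
the six trait TIs with a seeded 80/20 held-out split and reports
normalized impurity importances plus held-out and in-sample R².
Defaults: 500 trees, unlimited depth, and `mtry` equal to all six
features (bagged regression trees — the common regression-forest
default, which keeps a planted single-feature signal concentrated on
that feature). Note a structural caveat: if the target is the overall
TI, which *is* the mean of the six features, the regression is
near-tautological and R² approaches 1 on clean data; the held-out R²
is therefore mainly informative for alternative targets, and the
validation suite exercises planted-signal and pure-noise targets
instead.

## The synthetic trial generator

`simulate_panel()` draws complete replicate-level panels from the
split-plot model above, one trait at a time:

* stratum means $\mu + C_j$ per (location, treatment, trait), supplied
  directly; the calibrated defaults in `default_sim_config()` are the
  published location × treatment means of a 460-genotype two-site
  trial (HLJ and NM, control and intercrop shade);
* $R_i \sim N(0, \sigma_R^2)$ per location × block and
  $\delta_{ij} \sim N(0, \sigma_\delta^2)$ per block × system main
  plot, shared by all genotypes of that main plot;
* genotype-level effects with a controllable control–shade dependence:
  either a shared main effect plus independent interaction
  ($\sigma_G$, $\sigma_{CG}$), or — when `ck_shade_corr` is set — a
  bivariate normal pair of per-treatment genotype expectations with
  common SD $\sigma_G$ and the requested correlation (the correlation
  parameterization wins when both are set);
* subplot error $\epsilon_{ijk} \sim N(0, \sigma_\epsilon^2)$ per plot;
* truncation of negative draws at 0.

Default variance components (trait units) were chosen once, before any
validation run, to give between-genotype CVs of roughly 15–30% — what a
globally diverse germplasm panel shows for these traits — with plot
error SDs a small fraction of the genotype SD because each plot value
is already a mean of 10 plants:

| trait | genotype SD | subplot SD | whole-plot SD | block SD | CK–shade corr |
|-------|------------:|-----------:|--------------:|---------:|--------------:|
| PH    | 30          | 6          | 3             | 3        | 0.887         |
| BPH   | 4.5         | 1.0        | 0.5           | 0.5      | 0.687         |
| NNP   | 2.8         | 0.8        | 0.5           | 0.5      | 0.697         |
| BN    | 0.65        | 0.25       | 0.08          | 0.08     | 0.656         |
| PNP   | 18          | 5          | 2             | 2        | 0.485         |
| SYP   | 0.35        | 0.12       | 0.05          | 0.05     | 0.622         |

The per-trait correlations default to the values observed at the HLJ
site of the reference trial. A delta-method cross-check supports the
scale of the genotype SDs: a PH TI dispersion of ~0.13 at a CK mean of
118.6 cm and ratio 1.075 back-calculates to a genotype SD near 30 cm.

What the generator does **not** emulate — and hence what passing tests
do and do not say about real data:

* no spatial field trends or neighbor competition; plots are
  exchangeable within a main plot;
* genotype effects are drawn independently per location (each site is
  analyzed separately, so no cross-site genetic correlation is
  imposed); simulated cross-site repeatability is therefore zero,
  unlike real panels;
* plant-to-plant sampling within a plot is not modeled; the subplot
  error absorbs it, which is adequate because every analysis consumes
  plot or genotype means;
* truncation at 0 (rather than resampling) slightly inflates the means
  and deflates the correlations of low-mean traits (BN, and SYP at the
  low-yielding site). The validation suite accounts for this by
  comparing stratum means against the exact truncated-normal
  expectation $\mu\Phi(\mu/\sigma) + \sigma\phi(\mu/\sigma)$ rather
  than the nominal mean.

Determinism contract: every stochastic operation takes an explicit
seed; an identical configuration and seed reproduce byte-identical
panels, summaries, and reports.

## Numerical choices

* TI cap 2.0, configurable; capping happens after the ratio, so scale
  invariance holds exactly below the cap.
* Percent change and the uncapped TI satisfy
  $\text{percent} = (\mathrm{TI}-1)\times 100$ exactly; the suite
  asserts the identity across modules.
* Cohen's d uses the classical pooled-SD form; the Hedges small-sample
  correction is an option, off by default. Zero pooled SD yields a
  missing value, not an error.
* p-values are floored at 1e-300 before serialization.
* Category boundaries are right-closed; `classify_tolerance()` is
  monotone by construction.
* Path analysis refuses predictor matrices with condition number
  above 1e10.
* Shapiro–Wilk is limited to 5000 observations; larger inputs are
  tested on a deterministic subsample with a warning.

## Validation problem sizes

The test suite validates at the sizes that make each property
informative while keeping a full run comfortably interactive: type-I
error of the whole-plot F over 500 simulated null trials at 60
genotypes; effect-size and correlation recovery over 100 simulated
460-genotype panels; path-coefficient oracle equivalence on 100 random
datasets of 20–50 records; clustering and importance recovery on
planted-structure tolerance matrices of 120–460 records. The type-I
simulation uses the model's complete null (no system effect and no
system × genotype component): with a genotype-level CK–shade
correlation below 1 the whole-plot F is anti-conservative by design of
the test, not by defect of the implementation, since the random
interaction inflates the treatment mean square but not the whole-plot
error stratum.

## Known limitations

* The overall tolerance and yield-stability indices have no canonical
  definitions in this literature; both defaults are documented,
  recorded in output metadata, and pluggable.
* The split-plot whole-plot test has only $(r-1)(c-1)$ denominator df;
  with three blocks its power is low and its size is sensitive to any
  unmodeled genotype × system variance (see above).
* Classification thresholds are fixed constants, not re-estimated from
  the panel; panels with very different TI distributions may warrant
  re-derived thresholds.
* The generator's defaults describe one published two-site trial;
  transferring them to other environments is a calibration exercise,
  not a default.
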