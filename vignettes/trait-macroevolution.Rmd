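---
title: "Modelling body-size macroevolution on fossil-bearing phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling body-size macroevolution on fossil-bearing phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termevol)
```

## The scientific problem

Termites have long been thought to have undergone a unidirectional reduction
in body size since the origin of their eusociality. Testing that idea
requires comparing directional and non-directional models of continuous
trait evolution on a dated phylogeny — and, critically, the answer changes
depending on whether fossil species are placed on the tree as tips that end
before the present. `termevol` implements the full analysis stack for this
question: Gaussian trait-evolution models on non-ultrametric trees,
small-sample AIC model comparison replicated over genus subsamples,
phylogenetic regressions and variance tests for social-complexity
covariates, and two-state ancestral-state reconstruction by stochastic
mapping. Head width (in mm) is the body-size proxy throughout, as is
standard in termite taxonomy; all model fitting happens on its natural
logarithm.

## The candidate models

Write $C$ for the phylogenetic covariance matrix ($C_{ij}$ = shared
root-to-tip path length of tips $i$ and $j$; $C_{ii} = T_i$, the depth of
tip $i$), $x$ for the vector of tip values (ln mm). Every candidate model is
an exact multivariate normal $x \sim N(m, V)$:

| model     | mean $m_i$          | covariance $V$                          | shape parameter |
|-----------|---------------------|------------------------------------------|-----------------|
| BM        | $z_0$               | $\sigma^2 C$                             | —               |
| trend     | $z_0 + \mu T_i$     | $\sigma^2 C$                             | $\mu$           |
| OU        | $z_0$               | $\tfrac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}}(1 - e^{-2\alpha C_{ij}})$ | $\alpha$ |
| lambda    | $z_0$               | $\sigma^2 C_\lambda$ (off-diagonals scaled) | $\lambda$    |
| kappa     | $z_0$               | $\sigma^2 C$ of the tree with $b \mapsto b^\kappa$ | $\kappa$ |
| delta     | $z_0$               | $\sigma^2 C^{\circ\delta}\,T_{max}^{1-\delta}$ | $\delta$  |
| trend_BM  | $z_0 + \mu \tau_i$  | $\sigma^2 C$                             | $\mu$           |

with $d_{ij} = T_i + T_j - 2C_{ij}$ the patristic distance and
$C^{\circ\delta}$ the elementwise power (the delta transform acts on node
depths, and every entry of $C$ is the depth of a most recent common
ancestor, so the matrix form is exact). The early-burst model is outside the
package's scope: on non-ultrametric trees of the size considered here it is
not reliably fittable and its role overlaps with delta.

`trend_BM` is the clade-mixed model: a regime painting labels every branch
either `trend` or `bm`, and $\tau_i$ is the summed length of `trend`
branches on the root-to-tip path of tip $i$. In the motivating analysis the
`bm` regime is the crown group of the higher termites (Termitidae) — lower
termites shrink directionally, higher termites diversify without direction.
Two conventions were genuinely open:

* **Stem branch.** By default the designated clade's stem branch stays in
  the `trend` regime: the directional size change runs *up to* the origin of
  the clade. `paint_clade(..., stem_in_bm = TRUE)` flips the convention.
* **Rate sharing.** The mixed model shares one $\sigma^2$ across regimes, so
  it carries a single extra parameter ($\mu$) over BM and is counted at
  $k = 3$ like the other one-shape-parameter models. A two-rate variant
  would change the parameter count and the AICc ranking; it is deliberately
  not offered because the model's purpose is to isolate the directional
  component.

Two identifiability facts shape the defaults. On an ultrametric tree
$T_i$ is constant, so the plain trend model is confounded with the root
state; `fit_model` signals this, and `fit_all_models` drops `trend` from
ultrametric comparisons by default (set `drop_trend_if_ultrametric = FALSE`
to keep it flagged instead). `trend_BM` remains identifiable on ultrametric
trees because $\tau_i$ varies with clade membership — that is precisely why
a clade-mixed trend can be fitted to modern-only data when a plain trend
cannot.

The OU model is parameterized with the root fixed at the single optimum
(one mean parameter), mirroring the common single-optimum behaviour of
trait-model fitters; $V$ uses `expm1` so the $\alpha \to 0$ limit recovers
BM to better than $10^{-6}$ relative error. The delta transform rescales the
tree to its original maximum depth, keeping $\sigma^2$ comparable across
$\delta$ values.

## Fitting and model comparison

For every model $V = \sigma^2 W(\text{shape})$, so the mean parameters and
the rate profile out analytically: $\hat\beta$ is the GLS estimate under
$W$, $\hat\sigma^2 = r^\top W^{-1} r / n$, and the profiled log-likelihood
is a function of the single bounded shape parameter. `fit_model` therefore
searches one dimension with a deterministic coarse grid (25 points by
default) refined by golden-section optimization around the best cell, rather
than a multi-start quasi-Newton run on $(\ln\sigma^2, \text{shape})$: the
profile is exact, the search space is one-dimensional and bounded, and the
result is bit-reproducible without any randomness. Bounds are
$\lambda, \kappa \in [0, 1]$, $\delta \in (0, 3]$, and $\alpha$ on a log
scale from $10^{-8}$ to $500 / T_{max}$ (these match common defaults in the
field's fitters; the original bounds used for the published analysis are not
stated anywhere, so they are configurable through `bounds`).

Model support is summarized by AICc,
$-2\ln L + 2k + 2k(k+1)/(n-k-1)$, with $k = 2$ for BM and $k = 3$
otherwise, and by Akaike weights. With $n \le k + 1$ the correction is
undefined and the fit reports `NA` rather than failing — the likelihood and
parameter estimates are still exact (the two-tip closed form is used as a
test oracle).

**Genus subsampling.** Species within a genus vary; the analysis design
absorbs that by replication: each replicate draws one species per modern
genus uniformly at random (fossil species, being species-level tips, are
always carried through), refits every model, and recomputes weights.
`replicate_fit` reports per-model means and standard deviations over
replicates — weights are averaged per replicate, never computed from mean
AICc, because the weight transform is nonlinear. Replicates are seeded
(`seed + 7919 r`), making the whole summary reproducible to the bit.

## Social-complexity statistics

PGLS (`pgls_fit`, `pgls_best`) is GLS regression whose error covariance is
the phylogenetic covariance under one of the BM, lambda, kappa or delta
transforms, with the transform parameter profiled by maximum likelihood
*inside* the regression — the caper-style design — rather than imported from
the trait-model fits. The four transforms are compared by
$AIC = -2\ln L + 2k$ ($k$ = coefficients + residual variance + one for a
non-BM transform parameter), ties broken toward BM. Coefficient standard
errors use the unbiased residual variance $r^\top W^{-1} r/(n - p)$; the
$F$ statistic tests all non-intercept terms jointly against the
intercept-only model under the same covariance. With an identity-structured
covariance, estimates, $t$, and $F$ reproduce ordinary least squares
exactly — this is one of the package's hard test oracles, alongside
agreement with `nlme::gls` under `ape::corPagel` on ultrametric trees.

Bartlett's homogeneity-of-variance test is used for group comparisons of
size variability. It does not account for phylogenetic non-independence;
there is no established phylogenetic equivalent, so the wrapper emits a
mandatory warning instead of pretending otherwise. Whether published
variance comparisons of this kind are computed on raw mm or ln mm is often
unstated; analyses here default to the ln scale for consistency with the
trait models, and the reproduction pipeline computes both so either
convention can be checked. Colony sizes span orders of magnitude and are
regressed on a log10 scale.

Caste disparity is the proportional index $(a - b)/b$ (e.g. imago vs
worker); per-level intercept tests refit the PGLS twice with each level of a
binary factor as the baseline, which leaves fitted values unchanged and
reads each level's mean against zero.

## Ancestral states of the worker caste

The binary worker-type character (true workers vs pseudergates) is modelled
with a two-state Mk chain. For two states the closed-form transition
probabilities make the pruning likelihood exact and fast; the default is the
equal-rates model with a uniform root prior — the published analysis names
only the mapping tool and the number of maps, so the simplest symmetric
choice is the default and both the asymmetric rates and the stationary root
prior are exposed. Stochastic mapping samples node states from their joint
conditional distribution (pruning + pre-order sampling) and then samples
each branch history conditional on its endpoints by rejection sampling,
falling back to uniformization (jump count drawn conditional on endpoints,
jump times as uniform order statistics, states as a discrete Markov bridge)
after a bounded number of rejections — exactness with guaranteed
termination. Node-state frequencies over maps estimate posterior ancestral
probabilities; on small trees they are tested against exact marginals by
brute-force enumeration.

## The synthetic-data generator

`simulate_bd_tree` runs a forward-time constant-rate birth–death process
from two crown lineages, stops just before the event after the extant count
first reaches its target (so terminal branches have positive length), and
retains each extinct lineage as a fossil tip with a configurable
probability. `simulate_trait` draws tip values exactly from the model's
multivariate normal via a Cholesky factor — no branch-wise discretization,
and every model shares one code path through `model_mean_cov`.
`simulate_species_table` expands genus-level tips into species records with
ln-scale within-genus noise, derives worker and soldier widths from imago
widths through proportional-disparity offsets, and evolves worker type
(2-state) and nesting type (3-state) along the tree.

Default conditions mirror the shape of the motivating dataset: on the order
of 113 modern genus-level tips plus ~25 fossil tips, imago ln head width
generated with root `exp(z0)` ≈ 2.31 mm, within-genus standard deviation
0.1 ln units, mean imago–worker disparity 0.3, and about three measured
species per genus. The rate $\sigma^2 = 0.05$ per unit tree time was chosen
once so that across-species variance of ln head width lands in the realistic
few-tenths range for a tree a few coalescent units deep.

What the generator deliberately does **not** emulate: measurement error and
curation heterogeneity across literature sources, fossil age uncertainty
(fossil tips end exactly at their simulated extinction times),
non-independence between social characters and body size (they are simulated
independently unless the user couples them), and diversified or biased taxon
sampling. Green tests on synthetic data therefore demonstrate correctness of
the estimators under the models' own assumptions — not robustness to those
real-data complications.

## Numerical choices and degenerate inputs

* Covariances are symmetrized and factorized by Cholesky; a failure reports
  the smallest eigenvalue and advises jittering near-zero branch lengths
  (zero-length branches are allowed, but identical root-to-tip paths make
  $C$ singular by construction).
* $0^\kappa$ is defined as 0 so zero-length branches survive the kappa
  transform.
* Exponentials inside the OU covariance are clamped at $e^{-745}$ to avoid
  underflow-to-NaN on extremely deep trees.
* Monomorphic discrete data yield $\hat q = 0$ with a flag rather than an
  error; a zero-variance group makes the Bartlett statistic infinite, also
  flagged.
* Model-selection ties are broken toward fewer parameters, then
  lexicographic model name.
* Curation follows the priority mean > mid-range > holotype within each
  literature source, averages across sources, and uses the largest subcaste
  for polymorphic castes (`use_largest = FALSE` switches to the smallest;
  published results are reported to be robust to that choice). Whether a
  historical source included eyes in an imago measurement cannot be
  validated computationally; the optional `measurement_basis` column simply
  records provenance.

## Problem sizes used by the test-suite and acceptance script

The package's own verification uses sizes chosen to exercise the statistics
meaningfully while staying desk-scale: exactness oracles on 5–8-tip trees;
parameter recovery on ~150-tip fossil-bearing trees with 50 replicates per
generating model; Bartlett type-I calibration with 10<sup>4</sup> null
simulations; stochastic-mapping convergence with 10<sup>4</sup> maps against
6-tip enumerations; and the end-to-end script on a ~138-tip study-shaped
dataset with 30 genus-subsampling replicates and 100 stochastic maps. The
full published analysis (140 matched tips, 100 replicates, seven models) is
implemented by `reproduce_study()` and runs against a local copy of the
original supplementary data files, which are third-party material and not
distributed with the package.

## The pipeline interface

`run_config` + `run_model_comparison` / `run_social_stats` / `run_asr` are
the programmatic orchestration layer: they validate inputs, filter by caste
and fossil status, route every stage through one seed, and write TSV/JSON
reports when an output directory is configured. This package is an analysis
library rather than a shell tool, so these functions (with
`scripts/acceptance.R` as a worked non-interactive driver) *are* its
command-line story; wrapping them in a thin `Rscript` argument parser is
straightforward where a shell entry point is wanted.

## Known limitations

* Measurement-error variance terms (a per-tip nugget) are not modelled;
  within-genus variation is handled by subsampling replication instead, and
  iid noise will bias $\hat\kappa$ and $\hat\lambda$ downward — visibly so
  in the synthetic round trip, and presumably equally in the real analysis
  this package re-implements.
* The mixed trend model supports exactly two regimes defined by one clade.
* The discrete module is intentionally two-state; the 3-state nesting
  character is simulated but not fitted.
* AICc-based selection among several boundary-nested one-parameter models
  overfits at a non-vanishing rate (roughly a third of BM-generated datasets
  are assigned a richer best model at any tree size); mean Akaike weights
  across replicates are the more stable summary, which is how results are
  reported here.
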