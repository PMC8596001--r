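# termevol

Phylogenetic comparative analysis of termite body-size evolution: did
termites shrink directionally as their societies evolved, or did body size
diversify along with speciation?

`termevol` is an R package for researchers fitting continuous
trait-evolution models on dated phylogenies that carry **fossil tips** —
tips that end before the present, which is exactly the situation where
directional (trend) models become identifiable and where conclusions about
directional size change can flip. It was built around the termite head-width
question but every component is general: any continuous trait, any rooted
tree with branch lengths.

## What it computes

**Trait-evolution models.** Seven exact Gaussian models of ln trait
evolution on a (possibly non-ultrametric) tree with phylogenetic covariance
`C` (shared root-to-tip path lengths):

- `BM` — unbiased Brownian motion: `x ~ N(z0·1, σ²C)`
- `trend` — BM with drift: mean `z0 + μ·Tᵢ` (tip depth `Tᵢ`); identifiable
  only with non-contemporaneous tips
- `OU` — single-optimum Ornstein–Uhlenbeck,
  `V_ij = σ²/(2α)·e^(−α d_ij)·(1 − e^(−2α C_ij))`
- `lambda`, `kappa`, `delta` — Pagel's branch-length transforms
- `trend_BM` — the clade-mixed model: a regime painting assigns each branch
  to a `trend` or `bm` regime (e.g. directional size reduction in lower
  termites, free diversification in higher termites); mean
  `z0 + μ·τᵢ` with `τᵢ` the trend-regime exposure of tip `i`

Mean parameters and the rate profile out analytically, leaving a
one-dimensional bounded ML search per model. Models are compared with AICc
and Akaike weights, replicated over random one-species-per-genus subsamples
(`replicate_fit`), reporting means ± sd across replicates.

**Comparative statistics.** PGLS under ML-profiled branch-length transforms
with AIC selection (`pgls_fit`, `pgls_best`), Bartlett variance tests (with
a mandatory phylogenetic-caveat warning), proportional caste-disparity
indices `(a − b)/b`, per-level intercept tests, and pairwise caste
correlations.

**Ancestral states.** Two-state Mk likelihood (closed-form transition
probabilities + pruning), ML rate estimation, and stochastic character
mapping with rejection sampling and a uniformization fallback
(`stochastic_map`), yielding posterior node-state frequencies.

**Synthetic data.** A seeded generator for fossil-bearing birth–death trees
(`simulate_bd_tree`), exact multivariate-normal trait draws under any of the
seven models (`simulate_trait`), and genus-structured species tables with
caste disparities and social annotations (`simulate_species_table`), so the
entire pipeline is testable without any external data.

## Worked example

```r
library(termevol)

# a fossil-bearing tree: 60 extant genus-level tips, extinct lineages
# retained as fossil tips with probability 0.3
tree <- simulate_bd_tree(birth = 1, death = 0.45, n_extant = 60,
                         fossil_p = 0.3, seed = 11)

# genus-level imago ln head widths under a kappa process
x <- simulate_trait(tree, model_spec("kappa", sigma2 = 0.05,
                                     z0 = log(2.31), kappa = 0.2), seed = 12)

# expand to a species-level table and run the replicated comparison
tab <- simulate_species_table(tree, x, species_per_genus = 3, seed = 13)
fs  <- replicate_fit(tab$records[tab$records$caste == "imago", ], tree,
                     n_rep = 20, seed = 14,
                     models = c("BM", "OU", "lambda", "kappa", "delta", "trend"))
print(fs)
```

```
Replicated model comparison over 20 genus subsamples 
   model mean_AICc sd_AICc mean_weight sd_weight mean_root_mm sd_root_mm
1  kappa     41.33   5.324   9.553e-01 3.632e-02        1.722    0.02323
2 lambda     47.97   5.155   4.471e-02 3.631e-02        1.872    0.01980
3     OU     73.19   9.497   1.182e-05 4.001e-05        2.319    0.11753
4  delta     85.25  13.207   2.606e-07 8.895e-07        2.153    0.04393
5     BM     93.07  16.587   6.898e-08 2.525e-07        1.860    0.01879
6  trend     94.96  16.675   2.949e-08 1.086e-07        2.750    0.16339
```

Reading this: the generating `kappa` model carries essentially all the
Akaike weight (mean 0.955 across the 20 genus subsamples), the directional
`trend` model gets none, and `mean_root_mm` is the back-transformed root
(ancestral) head width estimate under each model. The shrinkage of the
fitted `kappa` parameter (0.027 vs the generating 0.2) is the expected
effect of within-genus sampling noise, which mimics speciational change —
one reason the analysis replicates over subsamples instead of trusting any
single draw.

Downstream stages work from the same objects:

```r
cfg <- run_config(tree, tab$records, caste = "imago", n_rep = 20, seed = 14)
run_social_stats(cfg)   # PGLS + Bartlett + disparity battery
run_asr(cfg)            # Mk fit + 100 stochastic maps
```

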