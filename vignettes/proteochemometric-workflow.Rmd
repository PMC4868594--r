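---
title: "Proteochemometric modeling of compound–protein inhibition with pcmfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteochemometric modeling of compound–protein inhibition with pcmfit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why proteochemometrics

A conventional quantitative structure–activity relationship (QSAR) model
relates the structure of a series of compounds to their activity against
*one* protein. When the assay panel spans several protein variants — for
example, amino-acid substitutions of the aromatase enzyme CYP19A1 tested
against a set of steroidal and non-steroidal inhibitors — a QSAR per
variant wastes the information shared across the panel, and a QSAR per
compound cannot generalize to new molecules.

Proteochemometric (PCM) modeling instead treats each *compound–variant
pair* as one observation. The design matrix concatenates three kinds of
descriptor blocks:

* **C** — compound descriptors: counts of substructure-fingerprint
  (SMARTS) features for each molecule;
* **P** — protein descriptors: three-component z-scales (summarizing
  hydrophobicity, steric bulk and polarity of the amino acid) at each
  varied sequence position;
* **cross-terms** — element-wise products of descriptor pairs, capturing
  *selectivity*: compound–protein products (C×P) encode how a chemical
  feature's effect depends on the protein context, while within-block
  products (C×C, P×P) encode intramolecular and intraprotein interactions.

With $|C|$ compound and $|P|$ protein descriptors surviving the filters,
the cross-blocks have $|C| \cdot |P|$ (C×P) and $N(N-1)/2$ (within-block)
columns. The thirteen canonical block combinations run from the
compound-only model 1 (C) through the pure selectivity model 3 (C×P)
and the additive-plus-cross model 7 (C, P, C×P) to the full model 13
(C, P, C×P, C×C, P×P); `model_blocks()` lists them all.

## Data model

Three tables define a study:

* `compound_table()` — `id`, `smiles` (optionally `name`); read from a
  `.smi` file with `read_compounds()`. Compounds pass through
  `curate_compounds()`, which canonicalizes SMILES, strips counter-ions
  and rejects unparseable or metal-containing structures with a logged
  reason.
* `variant_table()` — `variant_id` plus one column of one-letter
  amino-acid codes per varied position (`aromatase_positions()` gives the
  default thirteen); read with `read_variants()`.
* `activity_table()` — `compound_id`, `variant_id`, `pic50`.
  `to_pic50()` converts IC50 values in molar, micromolar or nanomolar
  units.

```{r data, eval = FALSE}
library(pcmfit)

compounds <- read_compounds(system.file("extdata",
  "synthetic_inhibitors.smi", package = "pcmfit"))
variants  <- read_variants(system.file("extdata",
  "synthetic_variants.csv", package = "pcmfit"))

## The bundled panel is a labelled synthetic stand-in; activities with a
## known ground truth are simulated on top of it.
act <- generate_activities(compounds, variants, seed = 7)$activities
```

## Descriptor blocks and filtering

`build_blocks()` performs the full encoding. Within the C and P blocks —
*before* any cross-terms are formed — two unsupervised filters are
applied:

1. **near-zero variance** (`near_zero_variance_filter()`): a column is
   dropped when its variance is below `1e-8` or the frequency ratio of
   its two most common values exceeds 95/5;
2. **correlation** (`correlation_filter()`): while any absolute pairwise
   correlation exceeds the cutoff (default 0.7), the member of the worst
   pair with the larger mean absolute correlation is dropped.

Cross-terms are then built from the survivors, so every product column is
interpretable in terms of retained descriptors. Cross-term columns are
named `SubFPC12_p133z2` (C×P) or `a_b` (within-block, original column
names joined by `_`).

```{r blocks, eval = FALSE}
blocks <- build_blocks(act, compounds, variants)
sapply(blocks, ncol)
design <- assemble_design(7L, blocks)   # model 7: C + P + CxP
```

## Fitting and validation protocol

`pcm()` is the one-call interface. Its protocol:

1. encode and filter the blocks, assemble the requested model design;
2. split records 80/20 with `kmeans_split()` — records are clustered in
   standardized descriptor space into `round(0.8 n)` clusters and the
   record nearest each center forms the internal (training) set, so
   training coverage spans the occupied descriptor space;
3. tune the learner by 10-fold cross-validation on the internal set
   (`tune_and_fit()`): the grid point with the lowest pooled
   cross-validated RMSE wins and its out-of-fold metrics are reported as
   `Q2_CV` / `RMSE_CV`;
4. refit the winner on all internal records (`R2_Tr`, `RMSE_Tr`) and
   predict the untouched external records (`Q2_Ext`, `RMSE_Ext`).

Five learner families are available: `"random_forest"` (ranger, 500
trees, impurity importance), `"pls"`, `"ridge"`, `"svm_rbf"` and a
closed-form `"bayesian_linear"` (Gaussian-prior posterior mean via SVD).

```{r fit, eval = FALSE}
fit <- pcm(act, compounds, variants, model = 3,
           learner = "random_forest", seed = 7)
print(fit)
summary(fit)        # adds tuned parameters, reliability gap, importances
plot(fit)           # observed vs predicted, external set highlighted
```

The fitted object supports the usual idioms: `predict()` (optionally on
new compound–variant pairs, encoded with the stored dictionary and
filter state), `fitted()`, `residuals()`, and `coef()` for the linear
families (coefficients returned on the raw descriptor scale).

## Beyond the single split

* `pcm_crossvalidate(fit, scheme)` — `"cv10"` random folds, or grouped
  `"loco"` / `"lopo"` folds that hold out every record of one compound
  or one variant, measuring true extrapolation to unseen entities.
* `pcm_yscramble(fit, rounds = 50)` — refits the identical protocol on
  permuted responses; a sound model's real `Q2_CV` must separate cleanly
  from the scrambled distribution.
* `pcm_repeat(fit, repeats)` — repeats the whole
  partition/tune/fit/test pipeline over independent seeds and aggregates
  every metric as mean ± sd; for random forests it also collects
  per-partition impurity importances, summarized by
  `importance_aggregate()`.
* `reliability_check(R2, Q2)` — flags a fit whose goodness of fit
  outruns its predictivity by more than the accepted margin.

## Exploration

`pcm_pca()` gives a deterministic-sign principal component analysis of
any descriptor block, and `horns_parallel()` applies Horn's parallel
analysis: component $k$ is retained while its eigenvalue exceeds the
95th percentile of eigenvalues from permuted data, stopping at the first
failure. This gives a principled, simulation-based answer to "how many
real dimensions does this block contain?".

## Synthetic ground truth

`simulate_pcm_data()` generates a complete study — compounds drawn from
curated inhibitor-like scaffolds, a variant panel over the thirteen
aromatase positions, and activities from a planted sparse linear model
(`pIC50 = 6.5 +` effects on two C, two P and three C×P features `+`
Gaussian noise, `sd = 0.3`) — with the ground truth (`$truth`) recording
the chosen features, coefficients and noiseless response. Because the
planted effects are guaranteed to survive the default filters, the
generator supports exact end-to-end verification: a noiseless simulation
is recovered perfectly by a linear fit, and the planted C×P feature
should dominate aggregated random-forest importance.

```{r sim, eval = FALSE}
sim <- simulate_pcm_data(seed = 1)
fit <- pcm(sim$activities, sim$compounds, sim$variants,
           model = 3, learner = "random_forest", seed = 1)
rp  <- pcm_repeat(fit, repeats = 20, tune = FALSE)
importance_aggregate(rp$importance, top_k = 5)
sim$truth$effect_features$CxP   # the planted selectivity features
```
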