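---
title: "Wavelength selection and origin discrimination for NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelength selection and origin discrimination for NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirselect)
```

## The problem

Dried sclerotia of *Wolfiporia cocos* are traded as a medicinal material
whose constituent profile — and therapeutic value — depends on where the
fungus was grown. The peel (FLP) and the inner part (BFL) of the sclerotium
differ chemically and are modeled separately. Near-infrared (NIR)
diffuse-reflectance spectra of powdered samples carry that geographic
signature in heavily overlapping overtone and combination bands, so the
analytical question is twofold: *which wavenumbers carry origin
information*, and *how well does a classifier built on them assign samples
to their region*.

`nirselect` implements the full workflow: spectral pretreatment, outlier
screening, representative train/validation splitting, four complementary
wavelength-selection algorithms fused by consensus voting, PLS-DA
evaluation under the Galtier membership rule, and a stepwise-screened
Fisher linear discriminant model validated by leave-one-out.

## The data model

A `spectra_set` holds an absorbance matrix (samples by wavenumbers), a
uniform descending wavenumber grid, and per-sample metadata (`sample_id`,
`tissue`, `region_class` 1–5, `set_membership`). All variable indexing in
the package is by wavenumber value, not column position, so selections
survive band cropping.

The emulated instrument scans 10000 to 4000 cm⁻¹. The working band
7501.74–4088.35 cm⁻¹ contains exactly 886 variables, which fixes the grid
spacing at (7501.74 − 4088.35)/885 = 3.8569 cm⁻¹ (3.857 to printed
precision); `instrument_grid()` anchors the grid so both band edges are
exact members. Grid uniformity is enforced to 10⁻⁶ cm⁻¹, and CSV headers
are written with six decimals so a written grid re-reads as uniform.

## Pretreatment

The default chain applies, in order: Norris gap-segment smoothing
(segment 5, gap 5 — common instrument-software defaults), mean centering,
per-variable autoscaling, and a Savitzky–Golay second derivative
(window 11, polynomial order 2 — exact for quadratics and far better
behaved under noise than finite differences). The chain is order-sensitive
and stateless; every parameter is config-exposed. Whether the Norris step
should contribute its own gap derivative is ambiguous in practice; the
default keeps it smoothing-only and leaves differentiation to the
Savitzky–Golay step, but `norris_filter(derivative = TRUE)` provides the
other reading.

`sdd_band_select()` operationalizes standard-deviation band selection as
the longest contiguous run of variables whose SD reaches a quantile of the
SD distribution (default quantile 0.25, minimum run 50 points); the fixed
study window is also available directly through `band_crop()`.

## Outlier screening and splitting

`iterative_outlier_removal()` reconstructs "modular group iterative
singular sample diagnosis" as iterative PCA screening: with k = 5
components, a sample is removed when its Hotelling T² (score space) exceeds
the k(n−1)/(n−k)·F limit or its Q residual (reconstruction space) exceeds
the Jackson–Mudholkar limit, worst-first, one per refit, at α = 0.99 —
conservative and directly testable against planted outliers. Removal of
more than 20% of samples aborts with diagnostics. The published stability
coefficients (4.26/7.82 at 95%/99%) cannot be reverse-engineered without
the n and k behind them and are not reproduced.

`kennard_stone_split()` is the classic maximin algorithm on Euclidean
distance with validation size `round(n/3)` (the 2:1 convention; the source
study's own counts imply inconsistent rounding, so one convention is fixed
and documented). A deterministic repair pass then swaps nearest cross-set
pairs until both sets contain all five regions — with at least two
training samples per class where possible, because the discriminant stage
and its leave-one-out validation need within-class scatter.

## PLS-DA and the membership rule

Class codes 1–5 enter a single-response NIPALS PLS regression (`pls_fit`),
matching the published tables where predicted values span the code range;
one regression vector `b` then drives both prediction and the
coefficient-based selectors. Five latent variables are used throughout (the
Kaiser-retained dimension of the study data; `pca_kaiser()` implements the
eigenvalue ≥ 1 rule on correlation-scale PCA). Cross-validation is
ten-fold, stratified by class, with the fold assignment derived from an
explicit seed.

The Galtier rule flags each validation sample from its predicted value
`y_pre` and deviation `y_dev`: *suspicious* when `y_dev` reaches the
suspicion threshold, *uncredited* when `y_pre` falls below the smallest
class code by more than the uncredited margin, otherwise *ok*. The
published statement of the rule is internally garbled, and its printed
tables are consistent with a suspicion cutoff of 0.45 for the BFL table
but 0.50 for the FLP table (both values appear in the published text), and
with an uncredited margin between 0.57 and 0.62 rather than the stated
0.55. The implementation therefore exposes both limits as parameters
(defaults 0.45/0.55, the published values); the fixture replay in the test
suite applies each table's own consistent parameters and reproduces every
printed flag and all ten column accuracies. The rule is one-sided: the
printed tables credit high predictions, so only low predictions can be
denied membership.

For fresh data the deviation is estimated by a fold jackknife
(`predict_with_deviation`): refit the PLS model on each fold's complement
and report half the range of the fold-model predictions per sample. The
original software's estimator is undocumented, so the verdict operation
deliberately accepts `(y_pre, y_dev)` from any source.

## The four selectors

**CARS** (`cars_select`): 100 replicate runs of 50 Monte-Carlo iterations.
Iteration *i* keeps a fraction `r_i = a·exp(−k·i)` of the variables with
`r_1 = 1` and `r_50 = 2/p`; within an iteration a PLS model fitted on a
random 80% sample subset ranks variables by |b|, a forced cut keeps the
top `r_i·p`, and a weighted bootstrap on |b| competes the survivors. Each
iteration's subset is scored by ten-fold RMSECV; one fold assignment
serves the whole call so the running minimum is not fold luck. The answer
is the minimum-RMSECV subset (ties: fewer variables, then lowest run), and
the per-variable frequency over run winners is reported.

**MC-UVE** (`mcuve_select`): 500 subset refits yield a coefficient
distribution per variable; the reliability index RI = mean/sd ranks them,
variables are added in rank order, and the global RMSECV minimum fixes the
retained count and the RI threshold. The subset fraction is 0.8, matching
CARS's stated 80%. The forward curve is evaluated up to a 150-variable
prefix — the minimum of coefficient-ranked prefixes occurs early, so the
tail adds cost without information.

**SPA** (subwindow permutation analysis, `spa_select`): 1000 runs each
draw ⌈0.8·n⌉ samples and Q = 10 variables, fit a PLS submodel and record
the prediction error on the unsampled samples. Variables are drawn from a
shuffled round-robin queue so inclusion counts stay balanced and no
variable goes unsampled. Each variable's inclusion vs exclusion error
distributions are compared by a one-sided rank-sum test;
COSS = −log₁₀(P), and COSS > 2 selects. The rank-sum construction is a
documented reconstruction; the test choice is config-exposed.

**LPG** (`lpg_select`): a PCA of the spectra projects every variable into
the PC1–PC2 loading plane; collinear variables fall on straight stretches
of the wavenumber-ordered polyline and informative ones sit at its
vertices. A variable is selected when it lies on the convex hull of the
standardized loading cloud, or when its turning angle exceeds 90° *and*
its loading radius exceeds the median. Both defaults were set from the
measured geometry of this loading plane: genuine band vertices turn by
110–180° while the median grid angle is near 30°, so a small angle
threshold floods the selection with noise corners; and near-origin points
turn sharply only because their loadings are noise — the radius gate is
the standard "distance from the origin measures contribution" reading of
loading plots.

**Consensus** (`consensus_vote`): variables chosen by at least two of the
four methods ("more than twice" is read inclusively; `min_votes` is
exposed) become the common variables for discriminant modeling.

## Stepwise screening and the Fisher model

`stepwise_select()` is classic Wilks'-lambda stepwise discriminant
screening with partial-F entry/removal thresholds 3.84/2.71 (the
conventional defaults of the statistical software the workflow emulates).
`fisher_fit()` builds per-class linear classification functions
coef = W⁻¹μ_c, constant = −½μ_cᵀW⁻¹μ_c + log(prior) with pooled
within-class covariance W; priors are equal despite unbalanced classes
because the published function form carries no prior term (configurable).
Under equal priors the score argmax equals nearest-centroid assignment in
Mahalanobis distance, which the tests verify against a brute-force oracle
and the reference LDA implementation. A singular W (second-derivative
spectra can be collinear) is ridged by 10⁻⁸·tr(W)/p, with an absolute
floor, and logged. Ties in classification resolve to the lowest class
code. `loo_cross_validate()` refits without each sample; a class reduced
to a single member during a refit keeps its centroid and simply
contributes nothing to the pooled covariance.

## The synthetic study generator

`default_study_config()` encodes the study conditions: 60 samples per
tissue in five region classes of 19/12/5/10/14, the full instrument grid,
and i.i.d. measurement noise of 0.005 absorbance units. Absorbance is

> per-sample random quadratic baseline + Σ bands + noise,

with Gaussian bands on the absorbance scale. Six informative bands sit at
tissue-specific marker wavenumbers (disjoint between tissues) with
per-class amplitudes spanning linear, step and saturating patterns — the
shapes differ so the six bands are not mutually redundant for class-code
prediction, the way distinct constituents respond differently to
geography. Ten shared (class-invariant) bands mix broad water/C–H
envelopes with four narrow matrix features that survive derivative
pretreatment, giving the full-spectrum model realistic uninformative
structure to contend with. Informative bands use σ = 7 cm⁻¹: the study
reports adjacent grid points 3.86 cm⁻¹ apart as distinct markers, so
characteristic features must be near grid-sharp, and this width keeps the
entire second-derivative signature (center plus side lobes at σ√3) within
the ±2-grid-step tolerance used to score a "hit" on a planted band.

Two per-sample random effects make the within-class variability realistic:
baseline coefficients jitter with SD 0.02 absorbance units (powder
scatter), and every band amplitude jitters multiplicatively with SD 5%
(within-region concentration variability, a typical NIR constituent CV).
Without the amplitude jitter the class code would be an almost exact
deterministic function of the spectrum and the full-spectrum model would
be unbeatable — the opposite of real spectra. The FLP configuration sits
on a higher baseline (offset 0.55 vs 0.40), the gross color/scatter
difference between peel and inner tissue, which is what separates the
pooled tissues in the leading PCA score plane. Planted outliers multiply a
sample's baseline perturbation and noise by `outlier_scale` (default 10).

What the generator does *not* emulate: wavelength-dependent or correlated
measurement noise, instrument line-shape convolution, scattering physics
(no MSC/SNV is needed or provided), drift between replicate scans, and the
dense forest of weak overlapping bands of real biological NIR spectra.
Passing tests therefore demonstrate that the algorithms recover localized
class information planted under realistic noise and background — not that
they would attain any particular accuracy on real spectra.

## Known limitations

* On this generator, the RMSECV improvement of selected-variable models
  over the full spectrum is driven by supervised selection (the selectors
  minimize cross-validated error on the training folds, as the field's
  workflow does). The unsupervised LPG subset does **not** reliably beat
  the full-spectrum model here: measured oracle subsets (the true band
  centers, or all in-band variables) only tie the full model, and a
  geometric selector necessarily also keeps class-invariant structure. The
  consensus-variable model, which is what the pipeline carries forward,
  beats the full-spectrum model on every tested seed.
* The published stability coefficients, selected-variable counts, Fisher
  coefficients and confusion tables are data-dependent properties of
  unreleased spectra and are not reproduction targets; the package
  reproduces the decision *rules* and the qualitative pipeline behavior.
* Stepwise Wilks screening inherits the usual caveats of stepwise
  procedures (greedy, order-dependent near ties).

## Problem sizes used in the tests

The acceptance suite replays the transcribed decision tables (19 + 18
samples × 5 variable sets), runs the four selectors over 20 seeds of the
default 60-sample study configuration, and validates pipeline behavior
(outlier recovery, permuted-label chance level, resubstitution optimism,
byte-identical reruns) on the same conditions. Unit tests use reduced
Monte-Carlo budgets (tens of runs) on small planted-band fixtures; the
defaults everywhere remain the study-scale values (100 CARS runs, 500
MC-UVE draws, 1000 SPA runs).

## A minimal session

```{r example, eval = FALSE}
sim <- generate_dataset(default_study_config("BFL", seed = 1))
run <- run_pipeline(sim$spectra, pipeline_config(seed = 1),
                    out_dir = "bfl_run")
run$evaluation            # per-variable-set RMSECV, R2, RMSEP, accuracy
tidy(run$fisher)          # per-class coefficients keyed by wavenumber
run$loo$confusion         # leave-one-out confusion table
annotate_bands(run$stepwise$retained)
```
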