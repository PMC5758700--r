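# nirselect

Chemometric wavelength selection and geographic-origin discrimination for
near-infrared (NIR) spectra of *Wolfiporia cocos* sclerotium tissue — the
peel (fu-ling-pi, FLP) and the inner part (bai-fu-ling, BFL) — modeled as
independent datasets of five Yunnan region classes.

NIR spectra of powdered samples contain the origin signature spread over
hundreds of heavily overlapping variables. The package implements a
complete, tested pipeline to find the characteristic wavenumbers and build
a discriminant model on them:

1. **Pretreatment** — Norris gap-segment smoothing, mean centering,
   autoscaling, Savitzky–Golay second derivative; standard-deviation (SDD)
   band selection, with the study's working band 7501.74–4088.35 cm⁻¹
   (886 variables) available directly.
2. **QC** — iterative PCA outlier screening by Hotelling T² (limit
   k(n−1)/(n−k)·F₍α;k,n−k₎) and Jackson–Mudholkar Q residual.
3. **Splitting** — Kennard–Stone maximin 2:1 train/validation partition
   with class-coverage repair.
4. **Wavelength selection** — four algorithms plus consensus voting:
   * CARS: Monte-Carlo competitive adaptive reweighted sampling with the
     exponential retention schedule r_i = a·e^(−k·i), r₁ = 1,
     r₅₀ = 2/p;
   * MC-UVE: reliability index RI = mean(b)/sd(b) over 500 subset refits,
     forward addition to the RMSECV minimum;
   * SPA (subwindow permutation analysis): COSS = −log₁₀(P) from rank-sum
     comparison of submodel error distributions, COSS > 2 selects;
   * LPG (latent projective graph): convex-hull and turning-angle vertex
     detection in the PC1–PC2 loading plane;
   * consensus: variables selected by ≥ 2 methods.
5. **Evaluation** — PLS-DA on class codes (NIPALS, 5 latent variables,
   stratified 10-fold CV) with the Galtier membership rule on
   (Y_pre, Y_dev): suspicious when Y_dev ≥ 0.45, uncredited when Y_pre
   falls more than 0.55 below the smallest class code.
6. **Discriminant modeling** — stepwise Wilks'-Λ screening (partial-F
   3.84/2.71) into Fisher linear classification functions
   (coef = W⁻¹μ_c, constant = −½μ_cᵀW⁻¹μ_c + log prior), validated by
   leave-one-out.

A synthetic spectra generator plants known class-discriminating absorption
bands under realistic baseline, concentration and measurement noise, so
every stage is testable against ground truth without access to the
original spectra. All results are tibbles; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`s.

## Worked example

```r
library(nirselect)

sim <- generate_dataset(default_study_config("BFL", seed = 1))
sim$spectra
#> <spectra_set> 60 samples x 1555 wavenumbers (9997.18 to 4003.50 cm^-1)
#> tissue: BFL  classes: 1 2 3 4 5

run <- run_pipeline(sim$spectra, pipeline_config(seed = 1), out_dir = "bfl_run")
run
#> <nir_run> BFL: 10 retained variable(s), LOO accuracy 100.00%

run$evaluation
#>   variable_set n_variables rmsecv    r2 rmsep accuracy
#> 1         full         886  0.254 1.000 0.179      100
#> 2         cars          45  0.115 0.998 0.215      100
#> 3        mcuve         149  0.149 0.997 0.190      100
#> 4          spa          48  0.192 0.995 0.213      100
#> 5          lpg          88  0.342 0.993 0.271      100
#> 6    consensus          75  0.161 0.997 0.201      100
```

Reading the table: each row is one variable set; `rmsecv` is the ten-fold
cross-validated error of the PLS class-code regression on identical folds
(the consensus model, 75 variables, reaches 0.161 against 0.254 for the
full 886-variable spectrum), `rmsep` the error on the held-out validation
set, and `accuracy` the percentage of validation samples credited to their
true region by the Galtier rule.

The stepwise/Fisher stage then retains 10 of the 75 consensus variables
and classifies perfectly in leave-one-out (100.00%) and at 95% on the
independent validation set (`run$resubstitution_accuracy`,
`run$loo$accuracy`, `run$validation_accuracy`). Because the pipeline works
on second-derivative spectra, retained variables often sit on a band's
derivative side lobe a few cm⁻¹ from the catalogued center;
`annotate_bands(run$stepwise$retained, tolerance = 4)` maps them to the
shipped spectra–structure assignment table (23 characteristic wavenumbers,
e.g. 4439.33 cm⁻¹ → "combination of O-H and C-O stretch in glucose").

`hit_rate(consensus, sim)` scores any selection against the planted
ground-truth bands (a hit is a selected variable within ±2 grid steps of
a planted center).

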