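# mozzage

Age grading of mosquitoes from near-infrared (NIR) spectra, and the
population-level inference that makes those individual estimates useful for
vector surveillance.

## The problem

Mosquito age is the single most informative entomological quantity for
judging whether adult-killing interventions (treated bednets, residual
sprays) are working: pathogens such as *Plasmodium* need a long extrinsic
incubation period inside the mosquito, so only the older part of a vector
population transmits disease. Near-infrared spectroscopy offers a fast,
non-destructive, reagent-free age estimate — a spectrometer records the
absorbance of a mosquito's head and thorax over roughly 350–2500 nm, and a
regression model maps the spectrum to an age in days. Individual estimates
are noisy and, with naive chemometrics, biased (young mosquitoes
over-predicted, old ones under-predicted). This package implements a
pipeline that reduces both problems and then propagates the remaining
measurement error into estimates of the *population mean age*, which is the
quantity a control programme actually needs.

## What is implemented

**Individual level — interval PLS with bias correction.** Spectra are
binned into non-overlapping wavelength windows (*Anopheles*: 350–708,
709–1066, 1067–1424 nm; *Aedes*: 709–1066, 1067–1424 nm). Each window gets
a single-response PLS regression (SIMPLS, mean-centred columns) whose
component count is chosen by 25-repetition bootstrap cross-validation
(out-of-bag RMSE, cap 20; a wide 350–1850 nm model is capped at 40). Data
are split 49/21/30 into inner-train / validation / test; the per-window
predictions on the validation set are combined by a generalised additive
model (one penalised cubic spline per base model), and a monotone spline
map of true-on-predicted age — fitted on the same validation set — removes
the systematic bias. RMSE is the accuracy metric throughout.

**Measurement model.** A heteroscedastic Bayesian linear regression acts as
a surrogate for "spectrometer + pipeline":

    predicted_age ~ Normal(alpha + beta * age, (sigma0 + sigma1 * age)^2)

fitted by penalised maximum likelihood with a Gaussian (Laplace) posterior
approximation. An unbiased pipeline has `alpha = 0`, `beta = 1`.

**Population level.** Under constant recruitment and age-independent
mortality the population age structure is exponential and the mean-age MLE
is the sample mean. Monte-Carlo machinery provides: credible intervals for
the estimated mean age; a decomposition of interval width into sampling
versus NIRS-measurement components; the minimum per-group sample size to
distinguish two populations; and the RMSE-versus-training-size relation

    RMSE(n) = a + b / sqrt(n)

fitted to learning-curve medians, which converts a training-set size into a
measurement SD for the surrogate.

**Synthetic data.** `generate_study()` builds spectra with a smooth
baseline, age-informative bands, per-study offsets/gains, per-mosquito
age-equivalent confounds and noise, so every stage is testable without
laboratory data. `generate_reference_studies()` mirrors the published
twelve-study summary table (4,549 mosquitoes) exactly in its metadata and
age-bin counts.

## Worked example

```r
library(mozzage)

ds <- generate_study(synth_spec_study_a(
  n = 400, grid = wavelength_grid(350, 2500, 5), seed = 42
))
pipe <- fit_pipeline(ds, genus = "anopheles", split = split_spec(seed = 7),
                     cv = cv_config(n_bootstrap = 10, seed = 8))
pipe
#> <age_pipeline> genus anopheles: 3 interval models + wide model, trained on 196 rows (validation 84)
#>   validation RMSE: raw 1.75, bias-corrected 1.75 days
tidy(pipe)
#> # A tibble: 4 x 4
#>   model      low_nm high_nm ncomp
#>   <chr>       <dbl>   <dbl> <int>
#> 1 interval_1    350     708     5
#> 2 interval_2    709    1066     2
#> 3 interval_3   1067    1424     3
#> 4 wide          350    1850     5
rmse(predict_age(pipe, pipe$test), pipe$test$age_days)
#> [1] 2.368285
```

Each interval model kept only a few latent components; the bias-corrected
test RMSE of about 2.4 days is typical for a 400-mosquito training study.
At the population level, with a 500-mosquito training set, a 5-day-old
population and 100 mosquitoes scanned:

```r
sur <- surrogate_from_training_size(power_law(0.44, 34.81), 500)
decompose_uncertainty(5, 100, sur, replicates = 30000, seed = 11)
#> # A tibble: 1 x 7
#>   mean_age n_sampled total_width sampling_width nirs_share measure floor_bias
#>      <dbl>     <int>       <dbl>          <dbl>      <dbl> <chr>        <dbl>
#> 1        5       100        2.10           1.95     0.0741 width            0
```

so NIRS measurement error accounts for only ~7% of the uncertainty in the
estimated mean age — sampling variability dominates. And

```r
min_sample_size_to_distinguish(5, 7,
  surrogate_from_training_size(power_law(0.44, 34.81), 430),
  replicates = 8000, seed = 12)
#> [1] 160
```

about 160 mosquitoes per group suffice to separate populations whose mean
ages differ by two days.

A thin command-line wrapper over these functions lives at
`inst/cli/mozzage.R` (subcommands `summarize`, `synth`, `train`, `predict`,
`population`).

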