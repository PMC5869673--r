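---
title: "Methods: interval-PLS age grading and population-level inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval-PLS age grading and population-level inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models: what is fitted,
under which assumptions, which knobs matter, and where design choices were
genuinely open. Nothing here reports an empirical number that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The individual-level model

### Interval PLS

A mosquito's NIR spectrum is a vector of unitless absorbances on a shared
wavelength grid, canonically 350–2500 nm at 1 nm (2151 highly collinear
columns). Ordinary least squares is hopeless at this aspect ratio;
partial least squares (PLS) projects the spectra onto a small number of
latent components chosen to covary with age and regresses on those.

The package implements single-response PLS with the SIMPLS algorithm,
mean-centring columns and the response. Variance scaling is **off** by
default (`fit_pls(scale = FALSE)`): classical NIR chemometrics centres
only, and absorbance columns share a physical unit, so unit-variance
scaling would inflate noisy edge wavelengths. The flag exists because the
convention in historical software is not documented anywhere we can check.
A full-rank fit with as many components as columns reproduces ordinary
least squares exactly; the test suite asserts this identity on a 30 x 5
problem, which pins the algebra to an independent oracle.

Rather than one model on the whole spectrum, the spectrum is cut into
non-overlapping windows and each window gets its own PLS model
("interval PLS"). The windows that proved most informative for mosquito
age are shipped as presets (`ipls_intervals()`): 350–708, 709–1066 and
1067–1424 nm for *Anopheles*; 709–1066 and 1067–1424 nm for *Aedes*. A
transparent alternative, `search_intervals()`, tiles the grid with
358 nm candidate windows and keeps the `k` with the lowest
cross-validated RMSE. Overlapping candidates are not allowed: the
downstream stacker assumes base models see disjoint evidence, and
whether the original interval searches permitted overlap is unknowable,
so the stricter convention is enforced.

### Component selection

The number of latent components per model is chosen by bootstrap
cross-validation (`cv_config()`): 25 repetitions by default; each
repetition fits on a with-replacement resample of the training rows and
scores component counts 0, 1, ..., cap on the out-of-bag rows; the count
with the lowest mean out-of-bag RMSE wins, ties going to fewer
components (less overfitting at equal evidence). Caps are 20 components
for interval models and 40 for the wide 350–1850 nm model — the wide
spectrum genuinely supports more structure, and in validation it helps
most for older mosquitoes. "Bootstrapped sampling" admits several
readings; out-of-bag scoring was chosen because it gives every
repetition a disjoint validation fold without a second nested split.

### Stacking and bias correction

The data are split 49/21/30 (inner-train / validation / test): 30% of
the data is the untouched test set, and the remaining 70% is split again
70/30. Base PLS models are fitted on inner-train rows only. Their
predictions *on the validation rows* become the inputs of a generalised
additive model (`fit_stacker()`): one penalised cubic regression spline
per base model, smoothness by GCV, basis dimension 8 per term (adapted
downward when the validation set is small). Fitting the stacker on the
base models' own training rows would reward overfitted base models;
the split makes the pipeline a pure function of train + validation rows,
and a test asserts that scrambling the test partition changes nothing.

Raw stacked predictions show the classic calibration failure of
regression to the mean: young mosquitoes over-predicted, old
under-predicted, and the imbalance of training ages (most studies have
far more young mosquitoes) makes it worse at the old end. The corrector
(`fit_bias_correction()`) fits a spline of true age on raw prediction on
the validation set, evaluates it on a 201-point grid, forces
monotonicity by isotonic regression, and interpolates linearly. A
non-monotone age map would be uninterpretable, hence the isotonic
projection. Outside the fitted range the map extends linearly with the
end-grid slopes — cubic splines extrapolate wildly, and a documented
linear extension is the least surprising behaviour. Corrected ages are
floored at 0 days; there is no upper clip. Degenerate input (constant
raw predictions) yields an identity corrector with a warning rather than
an error, so that pathological refits inside Monte-Carlo loops fail
soft.

The bias-corrected estimator trades a little RMSE for calibration; both
the corrected and the uncorrected ("accuracy-only") predictions are
available from one fitted pipeline via `predict_age(correct =)`.

## 2. Accuracy metrics and the learning curve

RMSE in days is the error metric everywhere. `learning_curve()` holds
out one fixed test set, then for each training size draws subsamples
*without replacement* from the remaining pool, refits the entire
pipeline, and records test RMSE; medians and quartiles summarise the
replicates. Drawing without replacement isolates the effect of training
size; the fixed test set removes test-sampling noise from the contrast.

The median RMSE as a function of training size n is summarised by

\[ \mathrm{RMSE}(n) = a + b\,n^{-1/2}, \]

fitted by Gaussian maximum likelihood, which for this model is least
squares on the transformed predictor \(n^{-1/2}\). The square-root decay
is a central-limit-theorem consequence of prediction error being
dominated by sampling variation in the training data. The exponent is
implemented as −1/2 (error *decreasing* in n): a positive exponent would
make error grow with training size, contradicting every observed
learning curve. Both coefficients are constrained non-negative so the
fitted curve is monotone decreasing; the noise model for the likelihood
is additive Gaussian on the median RMSE — the simplest declared choice,
since nothing stronger can be justified.

## 3. The surrogate measurement model

Simulating population-level inference through the full pipeline would
require generating spectra for every simulated mosquito. Instead a
surrogate stands in for "spectrometer + pipeline": a Bayesian linear
regression with heteroscedastic noise,

\[ \hat{a} \sim \mathcal{N}\!\left(\alpha + \beta a,\; (\sigma_0 + \sigma_1 a)^2\right), \]

fitted to (true age, pipeline prediction) pairs. A linear scale in age
is the simplest form consistent with the widening prediction funnel seen
in validation scatter; no functional form stronger than "spread grows
with age" is identifiable from a few hundred pairs. Priors are weakly
informative and overridable (`surrogate_priors()`): \(\alpha \sim
\mathcal{N}(0, 5^2)\) days, \(\beta \sim \mathcal{N}(1, 1^2)\),
half-Normal(2.5) on both \(\sigma_0\) and \(\sigma_1\); the half-Normal
support encodes that measurement spread cannot decrease with age in this
parameterisation.

Estimation is penalised maximum likelihood (the posterior mode) in the
transformed space \((\alpha, \beta, \log\sigma_0, \log\sigma_1)\), with a
Gaussian (Laplace) approximation around the mode providing posterior
draws. At the sample sizes where the surrogate is used (hundreds to
thousands of pairs) the posterior is effectively Gaussian, the
approximation is exact for practical purposes, and the fit is
deterministic given a seed — properties an MCMC sampler would not give
at this cost. The acceptance suite verifies calibration directly: across
100 simulated refits at n = 2000, each generating parameter falls inside
its central 95% interval at least 90 times. When a fit lands on the
\(\sigma \to 0\) boundary (an exact predictor), the Hessian is singular
in the log-scale directions and a pseudo-inverse supplies the
(essentially zero-spread) covariance.

`simulate_predictions()` floors simulated ages at 0 by default, because
a predicted age below zero is not a reportable measurement. Flooring
truncates the noise distribution at young ages and therefore lifts the
mean slightly; wherever strict unbiasedness matters (the unbiasedness
checks, the uncertainty decomposition) the unfloored mode is used and
the flooring-induced bias is reported when it exceeds 0.05 days.

`surrogate_from_training_size()` closes the loop between the two layers:
it builds the unbiased homoscedastic surrogate whose SD is the power-law
RMSE at a given training-set size.

## 4. Population-level inference

The population model is deliberately minimal: constant recruitment and
age-independent mortality, hence an exponential age distribution whose
mean (the life expectancy) is estimated by the sample mean. Senescence
is explicitly out of scope; accounting for age-dependent mortality would
change the distribution family and the estimator.

- `estimate_mean_age()` returns the sample mean with a percentile
  interval of the estimator's Monte-Carlo sampling distribution: a
  parametric bootstrap from the fitted exponential, passing every draw
  through the surrogate when one is supplied. A nonparametric
  resampling interval is available as an option; it is the right tool
  when the exponential assumption is in doubt, and it degenerates to
  zero width on constant input.
- `decompose_uncertainty()` computes the 95% interval width of the
  estimator twice over replicate populations — once on true ages, once
  after surrogate noise — and reports the NIRS share
  (total − sampling)/total. The interval-width ratio is the default
  because the bands one would plot against sample size are interval
  widths; the variance ratio is provided as an alternative and is
  roughly twice as large at these settings, so the choice must be (and
  is) explicit. Both arms share the same underlying age draws, so a
  zero-noise surrogate gives a share of exactly 0. Flooring is off by
  default here: truncating the noise at zero shrinks the noised arm's
  spread and understates the measurement share (by roughly half at a
  5-day mean with a ~2-day SD).
- `min_sample_size_to_distinguish()` grid-searches the per-group sample
  size at which two populations' Monte-Carlo 95% bands for the
  estimated mean separate. Band non-overlap is the default criterion —
  it is what "the shaded intervals stop overlapping" means on a plot of
  interval against sample size; a per-replicate two-sample z-test
  criterion with a power target is the configurable alternative and is
  substantially more conservative.
- `proportion_old()` reports the fraction of mosquitoes at or past the
  conventional 7-day threshold, for comparison only: under an exact
  exponential with mean \(\mu\) the true value is \(e^{-7/\mu}\), and
  unlike the mean its estimate is biased under symmetric measurement
  noise (the test suite demonstrates both facts).

## 5. The synthetic-data generator

`synth_spec()`/`generate_study()` emulate the structure that matters to
the algorithms, not mosquito biochemistry:

- a smooth baseline (three broad Gaussian bumps plus a gentle slope) —
  spectra must be smooth and collinear for interval methods to behave
  realistically;
- age-informative bands: a Gaussian profile confined to a wavelength
  window times an age response, linear by default with an optional
  saturating form (`half_age * age / (half_age + age)`);
- per-mosquito **age-equivalent confounds**: a random coefficient on
  each band's profile, in units of days. This is the generator's model
  of biochemical individuality that is spectrally indistinguishable
  from an age shift, and it sets the floor on attainable accuracy;
- study-level offset curves and gains (inter-study variability: models
  do not transfer across studies), per-mosquito offset/gain, white
  noise, and extra detector noise below 400 nm and above 1850 nm.

The study-A-like preset (`synth_spec_study_a()`) draws ages from the
published per-bin counts of the largest study (871 mosquitoes, many more
young than old), uses one linear band at 500–1100 nm (confound SD
2.2 days) and one saturating band at 1100–1424 nm (confound SD
3.5 days). The confound scales were fixed, before any end-to-end
measurement, so that the information-theoretic floor of the generator
sits near 1.9 days — the few-day individual-level error scale reported
for laboratory NIRS age grading; the saturating band gives the naive
linear model a genuine reason to under-predict old mosquitoes, which is
the bias the corrector exists to fix. `generate_reference_studies()`
replicates the full twelve-study metadata table (4,549 rows) with
study-specific offsets.

What the generator does **not** emulate: real absorbance band
chemistry, instrument drift within a study, preservation-method effects
on the spectrum (the labels are carried but have no spectral effect),
and non-Gaussian outliers. Passing tests therefore show that the
machinery is correct and well-calibrated under a faithful structural
model — not that any particular accuracy number will be achieved on new
laboratory data.

Two published headline numbers are structurally out of the generator's
reach, and their checks are expected to stay red on synthetic data: the
full-spectrum baseline error (the stand-in's linear-plus-saturating
signal is easier for a single linear PLS than real spectra are for
legacy processing) and the learning-curve coefficient pair (a near-zero
asymptote with steep decay implies an error floor far below the
few-day confound floor that the individual-level error scale requires).
A single synthetic dataset cannot satisfy both at once; the package
reports what it computes.

## 6. Numerical conventions and problem sizes

- Grids: any internally consistent wavelength grid is accepted; the
  loader infers the step from the header rather than assuming 1 nm.
  Non-monotone wavelength columns are an error unless `fix = "sort"`.
- Splits: test size is `round(n * test_frac)`; the remaining pool is
  floored for train with the remainder to validation (100 rows at the
  defaults give 49/21/30). Stratification by age quintile is on by
  default with largest-remainder allocation, so every partition spans
  the age range and the corrector never extrapolates over unsupported
  ages during fitting.
- Ties in component selection resolve toward fewer components;
  near-zero deflated directions terminate the SIMPLS loop early.
- All Monte-Carlo functions take an explicit seed and restore the
  caller's RNG state (`withr::with_seed`); identical seeds give
  byte-identical results.
- The test suite runs on deliberately scaled problems chosen as a
  sensible developer workflow: coarse grids (5–50 nm steps) and a few
  hundred mosquitoes for unit tests; the full 1 nm grid with all twelve
  stand-in studies (4,549 spectra) and a 25-replicate learning curve
  for the end-to-end checks; 10^4–10^5 replicate Monte-Carlo loops for
  the statistical properties.

## 7. Known limitations

- Models do not transfer across studies — a pipeline trained on one
  study's spectra has no validity claim on another instrument,
  population or preservation method, and the synthetic experiments
  reproduce exactly that failure.
- The exponential age structure ignores senescence and trap bias; both
  would bias the mean-age estimate in the field.
- The surrogate's linear mean and linear noise scale are conventions;
  strongly nonlinear residual bias after correction would violate them,
  and refitting with the provided priors is the intended remedy.
- The bias corrector is only defined over the validation set's
  prediction range plus a linear extension; populations far older than
  anything in training are extrapolations and flagged as such by the
  recorded age range.
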