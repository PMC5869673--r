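Package: mozzage
Title: Mosquito Age Grading from Near-Infrared Spectra and Population-Level Age Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating the age of individual mosquitoes from
    near-infrared (NIR) absorbance spectra and for turning those estimates
    into population-level surveillance quantities. Implements an interval
    partial-least-squares (iPLS) pipeline with bootstrap cross-validated
    component selection, spline-based stacking of per-interval predictions,
    and a monotone bias correction that removes the systematic
    over-prediction of young and under-prediction of old mosquitoes.
    A heteroscedastic surrogate error model stands in for the combined
    spectrometer-plus-pipeline measurement process, enabling Monte-Carlo
    inference on the mean age of exponentially age-structured populations:
    credible intervals for mean age, decomposition of uncertainty into
    sampling versus measurement components, and sample-size calculations
    for distinguishing populations. A synthetic spectra generator with a
    known age signal, study effects and noise makes every step testable
    without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
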