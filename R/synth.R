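#' Published per-study age-group counts for the multi-study NIRS age dataset
#'
#' Summary of the twelve laboratory studies (A--L) of paired age/NIR-spectra
#' data on *Anopheles gambiae s.l.*, *An. arabiensis* and *Aedes aegypti*
#' mosquitoes: species, sex, preservation method and the number of
#' mosquitoes per age group (\eqn{\le 5}, (5,10], (10,15], (15,20], >20
#' days). These counts drive [generate_reference_studies()], which emulates
#' the published dataset's size and age imbalance.
#'
#' @return Tibble with columns `study`, `species`, `sex`, `preservation`
#'   and one column per age bin, plus `total`.
#' @export
published_study_counts <- function() {
  tibble::tribble(
    ~study, ~species, ~sex, ~preservation, ~b1, ~b2, ~b3, ~b4, ~b5,
    "A", "An. arabiensis", "female", "fresh", 196L, 302L, 100L, 101L, 172L,
    "B", "An. arabiensis", "female", "silica gel", 103L, 168L, 103L, 51L, 0L,
    "C", "An. arabiensis", "female", "fresh", 99L, 50L, 95L, 69L, 0L,
    "D", "An. arabiensis", "male", "fresh", 100L, 50L, 72L, 67L, 0L,
    "E", "An. gambiae s.s.", "female", "fresh", 208L, 305L, 0L, 102L, 93L,
    "F", "An. gambiae s.s.", "female", "fresh", 100L, 50L, 93L, 90L, 0L,
    "G", "An. gambiae s.s.", "female", "fresh", 100L, 50L, 86L, 94L, 0L,
    "H", "An. gambiae s.s.", "male", "fresh", 100L, 50L, 67L, 77L, 0L,
    "I", "An. gambiae s.s.", "male", "fresh", 100L, 50L, 76L, 13L, 0L,
    "J", "An. gambiae s.l.", "female", "RNAlater", 91L, 162L, 42L, 0L, 0L,
    "K", "Ae. aegypti", "male", "RNAlater", 46L, 43L, 46L, 50L, 42L,
    "L", "Ae. aegypti", "female", "RNAlater", 41L, 45L, 46L, 43L, 50L
  ) |>
    dplyr::rename(
      `<=5` = "b1", `(5,10]` = "b2", `(10,15]` = "b3",
      `(15,20]` = "b4", `>20` = "b5"
    ) |>
    dplyr::mutate(
      total = .data$`<=5` + .data$`(5,10]` + .data$`(10,15]` +
        .data$`(15,20]` + .data$`>20`
    )
}

#' Describe one age-informative wavelength band
#'
#' A band contributes `profile(wl) * response(age)` absorbance units to
#' every spectrum, where the profile is a Gaussian bump confined to
#' `[low_nm, high_nm]` with maximum `peak`, and the response is either
#' linear in age or saturating (`half_age * age / (half_age + age)`, in
#' day-equivalents so `peak` is always absorbance per day at young ages).
#' `confound_sd` adds a per-mosquito random coefficient on the same
#' profile, in day-equivalents: biochemical variation between individuals
#' that is spectrally indistinguishable from an age shift and therefore
#' sets the floor on attainable prediction accuracy.
#'
#' @param low_nm,high_nm Band support (nm), inclusive.
#' @param peak Maximum absorbance change per day of age (AU/day).
#' @param shape `"linear"` (default) or `"saturating"`.
#' @param center_nm,width_nm Gaussian profile centre and SD (nm).
#' @param half_age Saturation scale in days (saturating shape only).
#' @param confound_sd Per-mosquito age-equivalent confound SD (days).
#' @return An object of class `signal_band`.
#' @export
signal_band <- function(low_nm, high_nm, peak = 0.002,
                        shape = c("linear", "saturating"),
                        center_nm = (low_nm + high_nm) / 2,
                        width_nm = (high_nm - low_nm) / 4,
                        half_age = 8, confound_sd = 0) {
  shape <- match.arg(shape)
  if (!(low_nm <= high_nm)) stop("grid error: low_nm must be <= high_nm")
  structure(
    list(
      low_nm = low_nm, high_nm = high_nm, peak = peak, shape = shape,
      center_nm = center_nm, width_nm = width_nm, half_age = half_age,
      confound_sd = confound_sd
    ),
    class = "signal_band"
  )
}

band_profile <- function(band, wl) {
  prof <- exp(-(wl - band$center_nm)^2 / (2 * band$width_nm^2))
  prof[wl < band$low_nm | wl > band$high_nm] <- 0
  band$peak * prof
}

band_response <- function(band, age) {
  if (band$shape == "linear") {
    age
  } else {
    band$half_age * age / (band$half_age + age)
  }
}

#' Specify a synthetic spectral study
#'
#' Encodes everything needed to generate one study's worth of synthetic
#' spectra: a smooth baseline (three broad Gaussian bumps plus a gentle
#' slope), age-informative bands ([signal_band()]), a smooth study-specific
#' offset curve and gain emulating inter-study variability, per-mosquito
#' offset/gain/confound variation, white noise, and extra detector noise at
#' the spectral edges (< 400 nm and > 1850 nm).
#'
#' @param n Number of mosquitoes.
#' @param grid A [wavelength_grid()].
#' @param ages How to draw true ages: a numeric vector of length `n`, a
#'   single number (exponential mean in days), or a list
#'   `list(edges =, counts =)` drawing ages uniformly within bins.
#' @param bands List of [signal_band()] objects.
#' @param study,species,sex,preservation Metadata labels.
#' @param study_offset_sd Amplitude (AU) of the smooth study offset curve;
#'   `0` disables it.
#' @param study_gain_sd SD of the study-level multiplicative gain about 1.
#' @param mosquito_offset_sd,mosquito_gain_sd Per-mosquito additive offset
#'   (AU) and multiplicative gain SDs.
#' @param noise_sd Per-wavelength white noise SD (AU).
#' @param edge_noise_sd Additional white noise SD outside 400--1850 nm.
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   dataset.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n = 400,
                       grid = wavelength_grid(350, 2500, 1),
                       ages = 8,
                       bands = list(signal_band(500, 1100, peak = 0.002,
                                                confound_sd = 0)),
                       study = "S1", species = "An. gambiae s.s.",
                       sex = "female", preservation = "fresh",
                       study_offset_sd = 0.05, study_gain_sd = 0.03,
                       mosquito_offset_sd = 0.01, mosquito_gain_sd = 0.01,
                       noise_sd = 0.005, edge_noise_sd = 0.03,
                       seed = 1L) {
  if (noise_sd < 0 || edge_noise_sd < 0) stop("noise SDs must be >= 0")
  for (b in bands) {
    if (b$high_nm < grid$start_nm || b$low_nm > grid$stop_nm) {
      stop("grid error: signal band [", b$low_nm, ", ", b$high_nm,
           "] lies outside the grid")
    }
  }
  structure(
    list(
      n = n, grid = grid, ages = ages, bands = bands, study = study,
      species = species, sex = sex, preservation = preservation,
      study_offset_sd = study_offset_sd, study_gain_sd = study_gain_sd,
      mosquito_offset_sd = mosquito_offset_sd,
      mosquito_gain_sd = mosquito_gain_sd,
      noise_sd = noise_sd, edge_noise_sd = edge_noise_sd,
      seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
}

#' Study-A-like synthetic specification
#'
#' Preset emulating the largest published study (study A: 871 female
#' *An. arabiensis*, fresh): ages drawn from the published age-bin counts
#' (more young than old mosquitoes), a linear age band in the 500--1100 nm
#' region, a saturating band in 1100--1424 nm, and per-mosquito
#' age-equivalent confounds sized so that individual-level prediction error
#' lands in the few-day range reported for laboratory NIRS age grading.
#'
#' @inheritParams synth_spec
#' @export
synth_spec_study_a <- function(n = 871, grid = wavelength_grid(350, 2500, 1),
                               seed = 1L, study = "A",
                               species = "An. arabiensis", sex = "female",
                               preservation = "fresh") {
  counts <- c(196, 302, 100, 101, 172)
  synth_spec(
    n = n, grid = grid,
    ages = list(edges = c(0, 5, 10, 15, 20, 25),
                counts = counts * n / sum(counts)),
    bands = list(
      signal_band(500, 1100, peak = 0.002, shape = "linear",
                  center_nm = 800, width_nm = 150, confound_sd = 2.2),
      signal_band(1100, 1424, peak = 0.0018, shape = "saturating",
                  center_nm = 1250, width_nm = 90, half_age = 8,
                  confound_sd = 3.5)
    ),
    study = study, species = species, sex = sex,
    preservation = preservation,
    study_offset_sd = 0.05, study_gain_sd = 0.03,
    mosquito_offset_sd = 0.01, mosquito_gain_sd = 0.01,
    noise_sd = 0.005, edge_noise_sd = 0.05,
    seed = seed
  )
}

draw_ages <- function(spec) {
  a <- spec$ages
  if (is.numeric(a) && length(a) == spec$n && spec$n > 1) {
    return(as.numeric(a))
  }
  if (is.numeric(a) && length(a) == 1) {
    return(stats::rexp(spec$n, rate = 1 / a))
  }
  if (is.list(a) && !is.null(a$edges)) {
    edges <- a$edges
    counts <- a$counts
    k <- length(counts)
    bin <- sample(seq_len(k), spec$n, replace = TRUE, prob = counts)
    stats::runif(spec$n, min = edges[bin], max = edges[bin + 1])
  } else {
    stop("unsupported `ages` specification")
  }
}

smooth_bump_curve <- function(wl, n_bumps, amp) {
  centers <- stats::runif(n_bumps, min(wl), max(wl))
  widths <- stats::runif(n_bumps, diff(range(wl)) / 12, diff(range(wl)) / 5)
  heights <- stats::rnorm(n_bumps, 0, amp)
  curve <- numeric(length(wl))
  for (j in seq_len(n_bumps)) {
    curve <- curve + heights[j] * exp(-(wl - centers[j])^2 / (2 * widths[j]^2))
  }
  curve
}

default_baseline <- function(wl) {
  0.4 * exp(-(wl - 700)^2 / (2 * 300^2)) +
    0.6 * exp(-(wl - 1450)^2 / (2 * 200^2)) +
    0.8 * exp(-(wl - 1940)^2 / (2 * 150^2)) +
    0.2 + 1e-4 * (wl - min(wl))
}

#' Generate one synthetic study
#'
#' Builds `absorbance = baseline + sum(band profile x age response)
#' + confounds + study offset + noise`, records the true age per mosquito,
#' and returns the result in the same wide-tibble dialect that
#' [read_spectra()] produces. Deterministic for a given spec and seed.
#'
#' @param spec A [synth_spec()].
#' @return A spectral table (wide tibble).
#' @export
generate_study <- function(spec) {
  wl <- spec$grid$wavelengths
  p <- length(wl)
  withr::with_seed(spec$seed, {
    ages <- draw_ages(spec)
    n <- length(ages)
    base <- default_baseline(wl)
    offset <- if (spec$study_offset_sd > 0) {
      smooth_bump_curve(wl, 3, spec$study_offset_sd)
    } else {
      numeric(p)
    }
    gain <- if (spec$study_gain_sd > 0) {
      stats::rnorm(1, 1, spec$study_gain_sd)
    } else {
      1
    }
    signal <- matrix(0, n, p)
    for (b in spec$bands) {
      prof <- band_profile(b, wl)
      resp <- band_response(b, ages)
      if (b$confound_sd > 0) {
        resp <- resp + stats::rnorm(n, 0, b$confound_sd)
      }
      signal <- signal + outer(resp, prof)
    }
    m_gain <- 1 + stats::rnorm(n, 0, spec$mosquito_gain_sd)
    m_offset <- stats::rnorm(n, 0, spec$mosquito_offset_sd)
    A <- (matrix(base, n, p, byrow = TRUE) + signal) * gain * m_gain +
      matrix(offset, n, p, byrow = TRUE) + m_offset
    A <- A + matrix(stats::rnorm(n * p, 0, spec$noise_sd), n, p)
    edge <- wl < 400 | wl > 1850
    if (spec$edge_noise_sd > 0 && any(edge)) {
      A[, edge] <- A[, edge] +
        matrix(stats::rnorm(n * sum(edge), 0, spec$edge_noise_sd), n, sum(edge))
    }
    colnames(A) <- as.character(wl)
    dplyr::bind_cols(
      tibble::tibble(
        study = spec$study, species = spec$species, sex = spec$sex,
        preservation = spec$preservation, age_days = ages
      ),
      tibble::as_tibble(A)
    )
  })
}

#' Generate and concatenate several synthetic studies
#'
#' @param specs List of [synth_spec()] objects sharing one wavelength grid.
#' @return A spectral table with per-study metadata preserved.
#' @export
generate_multistudy <- function(specs) {
  if (length(specs) < 1) stop("need at least one spec")
  g0 <- specs[[1]]$grid$wavelengths
  for (s in specs[-1]) {
    if (!identical(s$grid$wavelengths, g0)) {
      stop("grid error: all specs must share the same wavelength grid")
    }
  }
  dplyr::bind_rows(lapply(specs, generate_study))
}

#' Synthetic stand-in for the published multi-study dataset
#'
#' Generates twelve synthetic studies whose labels, species, sex,
#' preservation methods and per-age-bin counts match
#' [published_study_counts()] exactly (4,549 mosquitoes in total), with
#' study-specific offset curves emulating inter-study variability. The
#' spectra themselves are synthetic; only the metadata structure is taken
#' from the published summary table.
#'
#' @param seed Integer seed.
#' @param grid A [wavelength_grid()].
#' @return A spectral table with 4,549 rows.
#' @export
generate_reference_studies <- function(seed = 1L,
                                       grid = wavelength_grid(350, 2500, 1)) {
  cat_tbl <- published_study_counts()
  edges <- c(0, 5, 10, 15, 20, 25)
  bin_cols <- c("<=5", "(5,10]", "(10,15]", "(15,20]", ">20")
  specs <- withr::with_seed(seed, {
    lapply(seq_len(nrow(cat_tbl)), function(i) {
      row <- cat_tbl[i, ]
      counts <- as.integer(row[, bin_cols])
      # exact per-bin counts: ages drawn uniformly within each bin
      ages <- unlist(lapply(seq_along(counts), function(b) {
        if (counts[b] == 0) return(numeric(0))
        stats::runif(counts[b], edges[b], edges[b + 1])
      }))
      base <- synth_spec_study_a(
        n = row$total, grid = grid, seed = seed + i,
        study = row$study, species = row$species, sex = row$sex,
        preservation = row$preservation
      )
      base$ages <- ages
      base
    })
  })
  generate_multistudy(specs)
}
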