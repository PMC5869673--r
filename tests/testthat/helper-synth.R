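# Shared fixtures: small synthetic datasets built in code. Coarse grids
# keep the matrix algebra cheap; counting and splitting logic never depends
# on the grid step.

coarse_grid <- function(step = 10) {
  wavelength_grid(350, 350 + floor((2500 - 350) / step) * step, step)
}

# minimal hand-built table in the wide dialect
toy_spectra <- function(n = 3, wl = c(400, 500, 600, 700, 800), seed = 1) {
  withr::with_seed(seed, {
    ab <- matrix(round(runif(n * length(wl), 0.1, 0.9), 6), n, length(wl))
    colnames(ab) <- as.character(wl)
    dplyr::bind_cols(
      tibble::tibble(
        study = "T", species = "An. gambiae s.s.", sex = "female",
        preservation = "fresh", age_days = seq_len(n) + 1
      ),
      tibble::as_tibble(ab)
    )
  })
}

# one-band synthetic study with configurable noise, for pipeline tests
signal_ds <- function(n = 300, seed = 1, step = 10, noise_sd = 0.005,
                      confound_sd = 2, ages = 8) {
  generate_study(synth_spec(
    n = n, grid = coarse_grid(step), ages = ages,
    bands = list(
      signal_band(500, 1100, peak = 0.002, center_nm = 800, width_nm = 150,
                  confound_sd = confound_sd),
      signal_band(1100, 1424, peak = 0.0018, shape = "saturating",
                  center_nm = 1250, width_nm = 90, confound_sd = 3)
    ),
    noise_sd = noise_sd, seed = seed
  ))
}
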