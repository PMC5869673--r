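#' Optimal wavelength-interval presets by genus
#'
#' The interval-PLS analysis of the multi-study mosquito age dataset found
#' these non-overlapping wavelength windows most predictive of age:
#' three windows for *Anopheles* (350--708, 709--1066, 1067--1424 nm) and
#' two for *Aedes* (709--1066, 1067--1424 nm). Each interval gets its own
#' PLS model; a wide-spectrum model (350--1850 nm) is added at the
#' stacking stage.
#'
#' @param genus `"anopheles"` or `"aedes"`.
#' @return Tibble with columns `low_nm`, `high_nm` (inclusive bounds).
#' @export
ipls_intervals <- function(genus = c("anopheles", "aedes")) {
  genus <- match.arg(genus)
  if (genus == "anopheles") {
    tibble::tibble(low_nm = c(350, 709, 1067), high_nm = c(708, 1066, 1424))
  } else {
    tibble::tibble(low_nm = c(709, 1067), high_nm = c(1066, 1424))
  }
}

#' Wide-spectrum interval used alongside the per-window models
#' @return Tibble with one row (350--1850 nm).
#' @export
wide_interval <- function() {
  tibble::tibble(low_nm = 350, high_nm = 1850)
}

#' Map wavelength intervals to spectra column indices
#'
#' @param wavelengths Numeric vector of grid wavelengths (nm), strictly
#'   increasing, or a [wavelength_grid()].
#' @param intervals Tibble with `low_nm`/`high_nm` columns (inclusive).
#' @return List of integer index vectors, one per interval, disjoint.
#' @export
bin_intervals <- function(wavelengths, intervals) {
  if (inherits(wavelengths, "wavelength_grid")) {
    wavelengths <- wavelengths$wavelengths
  }
  iv <- dplyr::arrange(tibble::as_tibble(intervals), .data$low_nm)
  if (any(iv$low_nm > iv$high_nm)) {
    stop("configuration error: interval with low_nm > high_nm")
  }
  if (nrow(iv) > 1 && any(iv$low_nm[-1] <= iv$high_nm[-nrow(iv)])) {
    stop("configuration error: intervals overlap")
  }
  out <- lapply(seq_len(nrow(iv)), function(i) {
    idx <- which(wavelengths >= iv$low_nm[i] & wavelengths <= iv$high_nm[i])
    if (length(idx) == 0) {
      stop(
        "grid error: interval [", iv$low_nm[i], ", ", iv$high_nm[i],
        "] does not intersect the grid"
      )
    }
    idx
  })
  out
}

#' Score candidate wavelength intervals and keep the most predictive
#'
#' Transparent grid search over candidate windows: each candidate gets its
#' own bootstrap-CV'd PLS model ([fit_pls()]) on the training data, and the
#' `k_keep` candidates with the lowest cross-validated RMSE are returned in
#' wavelength order. With `preset` set, the published optimal intervals are
#' returned without searching.
#'
#' @param train Training spectral table.
#' @param candidates Tibble of candidate intervals (`low_nm`, `high_nm`);
#'   by default the grid is tiled with consecutive windows of
#'   `window_nm` nm.
#' @param cv A [cv_config()] used to score each candidate.
#' @param k_keep How many intervals to keep.
#' @param window_nm Width of the default candidate windows (nm).
#' @param preset Optional `"anopheles"` or `"aedes"` shortcut.
#' @return Tibble of the kept intervals with their CV RMSE, sorted by
#'   `low_nm`; the full scored candidate list is attached as
#'   `attr(, "scores")`.
#' @export
search_intervals <- function(train, candidates = NULL, cv = cv_config(),
                             k_keep = 3, window_nm = 358, preset = NULL) {
  if (!is.null(preset)) {
    out <- ipls_intervals(preset)
    out$cv_rmse <- NA_real_
    return(out)
  }
  wl <- spectra_wavelengths(train)
  if (is.null(candidates)) {
    lows <- seq(min(wl), max(wl), by = window_nm)
    candidates <- tibble::tibble(
      low_nm = lows,
      high_nm = pmin(lows + window_nm - 1, max(wl))
    )
    # drop a trailing sliver narrower than ~15% of a window
    keep <- (candidates$high_nm - candidates$low_nm) >= 0.15 * window_nm
    candidates <- candidates[keep, ]
  }
  candidates <- tibble::as_tibble(candidates)
  if (nrow(candidates) < 2) stop("configuration error: need >= 2 candidates")
  if (k_keep > nrow(candidates)) {
    stop("configuration error: k_keep exceeds the number of candidates")
  }
  if (nrow(train) == 0) stop("size error: empty training set")
  idx <- bin_intervals(wl, candidates)
  X <- spectra_matrix(train)
  y <- train$age_days
  scores <- purrr::map_dbl(idx, function(cols) {
    fit <- fit_pls(X[, cols, drop = FALSE], y, cv = cv)
    min(fit$cv_rmse, na.rm = TRUE)
  })
  candidates$cv_rmse <- scores
  kept <- candidates |>
    dplyr::slice_min(.data$cv_rmse, n = k_keep, with_ties = FALSE) |>
    dplyr::arrange(.data$low_nm)
  attr(kept, "scores") <- candidates
  kept
}
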