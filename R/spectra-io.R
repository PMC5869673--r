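#' Construct a wavelength grid
#'
#' A wavelength grid describes the shared abscissa of a spectral table:
#' an evenly spaced sequence of wavelengths in nanometres. The canonical
#' grid for ASD-type field spectrometers is 350--2500 nm at 1 nm
#' (2151 points), but any internally consistent grid is accepted.
#'
#' @param start_nm First wavelength (nm).
#' @param stop_nm Last wavelength (nm); must exceed `start_nm`.
#' @param step_nm Wavelength increment (nm); `(stop_nm - start_nm)/step_nm`
#'   must be a whole number.
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and the expanded `wavelengths` vector.
#' @examples
#' g <- wavelength_grid(350, 2500, 1)
#' length(g$wavelengths) # 2151
#' @export
wavelength_grid <- function(start_nm, stop_nm, step_nm = 1) {
  if (!(start_nm < stop_nm)) stop("grid error: start_nm must be < stop_nm")
  if (!(step_nm > 0)) stop("grid error: step_nm must be positive")
  len <- (stop_nm - start_nm) / step_nm
  if (abs(len - round(len)) > 1e-8) {
    stop("grid error: (stop_nm - start_nm)/step_nm is not a whole number")
  }
  structure(
    list(
      start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
      wavelengths = seq(start_nm, stop_nm, by = step_nm)
    ),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
    x$start_nm, x$stop_nm, x$step_nm, length(x$wavelengths)
  ))
  invisible(x)
}

# Metadata columns every spectral table must carry, in canonical order.
spectra_meta_cols <- c("study", "species", "sex", "preservation", "age_days")

is_wavelength_name <- function(nm) {
  suppressWarnings(!is.na(as.numeric(nm)))
}

#' Wavelengths of a spectral table
#'
#' Spectral tables are wide tibbles: metadata columns (`study`, `species`,
#' `sex`, `preservation`, `age_days`) followed by one numeric absorbance
#' column per wavelength, named by the wavelength in nm.
#'
#' @param ds A spectral table (wide tibble).
#' @return Numeric vector of wavelengths (nm), in column order.
#' @export
spectra_wavelengths <- function(ds) {
  nm <- setdiff(names(ds), spectra_meta_cols)
  wl <- nm[is_wavelength_name(nm)]
  as.numeric(wl)
}

#' Absorbance matrix of a spectral table
#'
#' @param ds A spectral table.
#' @return Numeric matrix, rows = mosquitoes, columns = wavelengths;
#'   column names are the wavelengths in nm.
#' @export
spectra_matrix <- function(ds) {
  wl <- spectra_wavelengths(ds)
  m <- as.matrix(ds[, as.character(wl), drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Per-mosquito metadata of a spectral table
#'
#' @param ds A spectral table.
#' @return Tibble of the metadata columns only.
#' @export
spectra_meta <- function(ds) {
  tibble::as_tibble(ds[, intersect(spectra_meta_cols, names(ds)), drop = FALSE])
}

#' Validate a wide spectral table
#'
#' Checks the table dialect: all metadata columns present, at least one
#' numeric wavelength column, wavelengths strictly increasing (or sorted on
#' request), and no missing absorbance values.
#'
#' @param df A data frame in the wide dialect.
#' @param fix `"error"` (default) to reject non-monotone wavelength columns,
#'   `"sort"` to reorder them.
#' @return The validated table as a tibble, wavelength columns in
#'   increasing order.
#' @export
as_spectra <- function(df, fix = c("error", "sort")) {
  fix <- match.arg(fix)
  df <- tibble::as_tibble(df)
  missing_meta <- setdiff(spectra_meta_cols, names(df))
  if (length(missing_meta) > 0) {
    stop(
      "metadata error: missing column(s): ",
      paste(missing_meta, collapse = ", ")
    )
  }
  other <- setdiff(names(df), spectra_meta_cols)
  bad <- other[!is_wavelength_name(other)]
  if (length(bad) > 0) {
    stop(
      "format error: non-numeric wavelength column label(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  if (length(other) == 0) stop("format error: no wavelength columns found")
  wl <- as.numeric(other)
  if (any(duplicated(wl))) stop("grid error: duplicated wavelength columns")
  if (is.unsorted(wl, strictly = TRUE)) {
    if (fix == "error") {
      stop("grid error: wavelength columns are not strictly increasing")
    }
    other <- other[order(wl)]
  }
  df <- df[, c(spectra_meta_cols, other)]
  absorb <- df[, other, drop = FALSE]
  na_rows <- which(rowSums(is.na(absorb)) > 0)
  if (length(na_rows) > 0) {
    stop(
      "missing absorbance values in row(s): ",
      paste(utils::head(na_rows, 10), collapse = ", ")
    )
  }
  if (any(!is.finite(df$age_days)) || any(df$age_days < 0)) {
    stop("metadata error: age_days must be finite and non-negative")
  }
  df
}

#' Read a wide-CSV spectral table
#'
#' The dialect is a wide CSV: first the metadata columns `study`, `species`,
#' `sex`, `preservation`, `age_days`, then one column per wavelength with a
#' numeric label in nm and unitless absorbance values.
#'
#' @param path Path to the CSV file.
#' @inheritParams as_spectra
#' @return A validated spectral table (tibble).
#' @export
read_spectra <- function(path, fix = c("error", "sort")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- withCallingHandlers(
    readr::read_csv(
      path,
      col_types = readr::cols(
        study = "c", species = "c", sex = "c", preservation = "c",
        .default = "d"
      ),
      show_col_types = FALSE, progress = FALSE
    ),
    # a missing metadata column is reported as a metadata error below, not
    # as a parser mismatch
    vroom_mismatched_column_name = function(w) invokeRestart("muffleWarning")
  )
  as_spectra(df, fix = fix)
}

#' Write a spectral table as wide CSV
#'
#' @param ds A spectral table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  ds <- as_spectra(ds)
  readr::write_csv(ds, path, progress = FALSE)
  invisible(path)
}

#' Count mosquitoes per study and age group
#'
#' Age bins follow the left-open/right-closed convention used in published
#' summaries of multi-study NIRS age data: with the default edges
#' `c(5, 10, 15, 20)` the bins are \eqn{\le 5}, (5,10], (10,15], (15,20]
#' and >20 days. A `Total` row over all studies is appended.
#'
#' @param ds A spectral table (only `study` and `age_days` are used). An
#'   empty table yields an all-zero `Total` row.
#' @param bin_edges Strictly increasing interior bin boundaries (days).
#' @return Tibble with one row per study plus `Total`, one count column per
#'   bin, and a `total` column.
#' @export
age_group_counts <- function(ds, bin_edges = c(5, 10, 15, 20)) {
  if (length(bin_edges) < 1 || is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  breaks <- c(-Inf, bin_edges, Inf)
  labs <- c(
    paste0("<=", bin_edges[1]),
    if (length(bin_edges) > 1) {
      paste0("(", bin_edges[-length(bin_edges)], ",", bin_edges[-1], "]")
    },
    paste0(">", bin_edges[length(bin_edges)])
  )
  if (nrow(ds) == 0) {
    out <- tibble::tibble(study = "Total")
    for (l in labs) out[[l]] <- 0L
    out$total <- 0L
    return(out)
  }
  binned <- tibble::tibble(
    study = as.character(ds$study),
    bin = cut(ds$age_days, breaks = breaks, labels = labs, right = TRUE)
  )
  counts <- binned |>
    dplyr::count(.data$study, .data$bin, .drop = FALSE) |>
    tidyr::pivot_wider(
      names_from = "bin", values_from = "n", values_fill = 0L
    ) |>
    dplyr::arrange(.data$study)
  counts <- counts[, c("study", labs)]
  total_row <- dplyr::summarise(
    counts,
    study = "Total",
    dplyr::across(dplyr::all_of(labs), sum)
  )
  out <- dplyr::bind_rows(counts, total_row)
  out$total <- as.integer(rowSums(out[, labs]))
  out
}

#' Describe a train/validation/test split
#'
#' Defaults follow the within-study protocol for NIRS age models: 30% of
#' the data is held out as a test set and the remaining 70% is split again
#' 70/30 into an inner training set and a validation set, i.e. overall
#' fractions 0.49/0.21/0.30.
#'
#' @param train_frac,val_frac,test_frac Proportions in (0,1) summing to 1.
#' @param seed Integer seed making the split reproducible.
#' @param stratify If `TRUE` (default) the split is stratified by age
#'   quintile so every partition spans the observed age range.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.49, val_frac = 0.21, test_frac = 0.30,
                       seed = 1L, stratify = TRUE) {
  fr <- c(train_frac, val_frac, test_frac)
  if (any(fr <= 0) || any(fr >= 1)) stop("all fractions must be in (0, 1)")
  if (abs(sum(fr) - 1) > 1e-8) stop("fractions must sum to 1")
  structure(
    list(
      train_frac = train_frac, val_frac = val_frac, test_frac = test_frac,
      seed = as.integer(seed), stratify = isTRUE(stratify)
    ),
    class = "split_spec"
  )
}

# Realised partition sizes. Test first (round), then the remaining pool is
# divided with floor for train and the remainder to validation, so e.g.
# n = 100 with the defaults gives 49/21/30.
split_sizes <- function(n, spec) {
  n_test <- round(n * spec$test_frac)
  pool <- n - n_test
  n_train <- floor(pool * spec$train_frac / (spec$train_frac + spec$val_frac))
  n_val <- pool - n_train
  sizes <- c(train = n_train, validation = n_val, test = n_test)
  if (any(sizes == 0)) {
    stop("size error: a partition is empty after rounding (n = ", n, ")")
  }
  sizes
}

#' Split a spectral table into train, validation and test sets
#'
#' The same seed always yields the same partition. With stratification the
#' rows are blocked into age quintiles and each block is allocated to the
#' three partitions in proportion (largest-remainder rounding, exact totals).
#'
#' @param ds A spectral table.
#' @param spec A [split_spec()].
#' @return List with tibbles `train`, `validation`, `test` and an `indices`
#'   list of the corresponding row indices into `ds`.
#' @export
split_train_val_test <- function(ds, spec = split_spec()) {
  n <- nrow(ds)
  if (n == 0) stop("size error: empty dataset")
  sizes <- split_sizes(n, spec)
  labels <- c("train", "validation", "test")
  assign_lab <- withr::with_seed(spec$seed, {
    lab <- character(n)
    if (spec$stratify && n >= 10) {
      ord <- order(ds$age_days, stats::runif(n))
      n_strata <- 5L
      stratum <- cut(seq_len(n), breaks = n_strata, labels = FALSE)
      remaining <- sizes
      rem_n <- n
      for (s in seq_len(n_strata)) {
        rows <- ord[stratum == s]
        m <- length(rows)
        if (s == n_strata) {
          alloc <- remaining
        } else {
          ideal <- remaining * m / rem_n
          alloc <- floor(ideal)
          short <- m - sum(alloc)
          if (short > 0) {
            extra <- order(ideal - alloc, decreasing = TRUE)[seq_len(short)]
            alloc[extra] <- alloc[extra] + 1
          }
          alloc <- pmin(alloc, remaining)
          # any deficit from the pmin guard goes to the largest remaining pool
          while (sum(alloc) < m) {
            i <- which.max(remaining - alloc)
            alloc[i] <- alloc[i] + 1
          }
        }
        lab[rows] <- sample(rep(labels, alloc))
        remaining <- remaining - alloc
        rem_n <- rem_n - m
      }
    } else {
      lab <- sample(rep(labels, sizes))
    }
    lab
  })
  idx <- lapply(labels, function(l) which(assign_lab == l))
  names(idx) <- labels
  list(
    train = ds[idx$train, , drop = FALSE],
    validation = ds[idx$validation, , drop = FALSE],
    test = ds[idx$test, , drop = FALSE],
    indices = idx
  )
}
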