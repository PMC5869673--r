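test_that("wide-CSV round trip preserves the table exactly", {
  ds <- toy_spectra(n = 3, wl = c(410, 420, 430, 440, 450))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra(ds, path)
  back <- read_spectra(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
  # writing what was read reproduces the same file contents
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("shuffled wavelength columns are sorted or rejected per flag", {
  ds <- toy_spectra(n = 4)
  meta <- c("study", "species", "sex", "preservation", "age_days")
  shuffled <- ds[, c(meta, c("600", "400", "800", "500", "700"))]
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuffled, path)
  expect_error(read_spectra(path), "grid error")
  sorted <- read_spectra(path, fix = "sort")
  expect_equal(as.data.frame(sorted), as.data.frame(ds))
})

test_that("malformed tables are rejected with identifying messages", {
  ds <- toy_spectra(n = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(ds, !"species"), path)
  expect_error(read_spectra(path), "metadata error.*species")
  ds_na <- ds
  ds_na[2, "500"] <- NA
  expect_error(as_spectra(ds_na), "row.*2")
  ds_bad <- dplyr::rename(ds, absorbance_a = "400")
  expect_error(as_spectra(ds_bad), "format error")
})

test_that("age-group counting follows the left-open/right-closed convention", {
  ds <- toy_spectra(n = 5)
  ds$age_days <- c(1, 5, 6, 20, 21)
  counts <- age_group_counts(ds)
  total <- dplyr::filter(counts, study == "Total")
  expect_equal(
    unname(unlist(total[, c("<=5", "(5,10]", "(10,15]", "(15,20]", ">20")])),
    c(2, 1, 0, 1, 1)
  )
  expect_equal(total$total, 5L)
})

test_that("age-group counts conserve mass for arbitrary bin edges", {
  ds <- signal_ds(n = 120, seed = 3, step = 50)
  for (edges in list(c(5, 10, 15, 20), c(2, 7), c(1, 2, 3, 4, 5, 30))) {
    counts <- age_group_counts(ds, edges)
    expect_equal(dplyr::filter(counts, study == "Total")$total, nrow(ds))
    per_study <- dplyr::filter(counts, study != "Total")
    expect_equal(sum(per_study$total), nrow(ds))
  }
  empty <- age_group_counts(ds[0, ])
  expect_equal(empty$total, 0L)
})

test_that("splits realise the documented sizes and are deterministic", {
  ds <- signal_ds(n = 100, seed = 2, step = 100)
  sp <- split_spec(seed = 11)
  parts <- split_train_val_test(ds, sp)
  expect_equal(
    vapply(parts$indices, length, integer(1)),
    c(train = 49L, validation = 21L, test = 30L)
  )
  again <- split_train_val_test(ds, sp)
  expect_identical(parts$indices, again$indices)

  tiny <- split_train_val_test(
    ds[1:3, ], split_spec(1 / 3, 1 / 3, 1 / 3, seed = 5)
  )
  expect_equal(unname(vapply(tiny$indices, length, integer(1))), c(1L, 1L, 1L))
})

test_that("split partitions are disjoint and cover every row", {
  ds <- signal_ds(n = 87, seed = 4, step = 100)
  for (seed in sample.int(10000, 60)) {
    idx <- split_train_val_test(ds, split_spec(seed = seed))$indices
    all_idx <- sort(unname(unlist(idx)))
    expect_identical(all_idx, seq_len(nrow(ds)))
    expect_equal(
      length(intersect(idx$train, idx$validation)) +
        length(intersect(idx$train, idx$test)) +
        length(intersect(idx$validation, idx$test)),
      0L
    )
  }
})

test_that("stratified splits span the age range in every partition", {
  ds <- signal_ds(n = 200, seed = 9, step = 100)
  parts <- split_train_val_test(ds, split_spec(seed = 21))
  rng <- range(ds$age_days)
  for (part in parts[c("train", "validation", "test")]) {
    expect_lt(min(part$age_days), rng[1] + diff(rng) * 0.25)
    expect_gt(max(part$age_days), rng[2] - diff(rng) * 0.25)
  }
})
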