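test_that("write/read round-trip preserves spectra and LAI", {
  d <- toy_spectra(n = 4, seed = 2)
  sp <- withr::local_tempfile(fileext = ".csv")
  la <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, sp, la)
  back <- read_dataset(sp, la, vza = 0)
  expect_equal(back$sample_id, d$sample_id)
  expect_equal(back$lai, d$lai, tolerance = 1e-9)
  expect_equal(spectra_matrix(back), spectra_matrix(d), tolerance = 1e-9)
})

test_that("misaligned sample ids raise an error naming the culprit", {
  d <- toy_spectra(n = 4)
  sp <- withr::local_tempfile(fileext = ".csv")
  la <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, sp, la)
  lai_tbl <- readr::read_csv(la, show_col_types = FALSE)[1:3, ]
  readr::write_csv(lai_tbl, la)
  expect_error(read_dataset(sp, la), "T04")
})

test_that("non-numeric cells are reported with row and column", {
  sp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,400,401", "a,0.1,0.2", "b,oops,0.3"), sp)
  expect_error(read_spectra(sp), "row 2.*column '400'")
})

test_that("vza is parsed from the conventional filename", {
  d <- toy_spectra(n = 2, vza = -60)
  dir <- withr::local_tempdir()
  sp <- file.path(dir, "spectra_vza-60.csv")
  write_dataset(d, sp)
  expect_equal(unique(read_spectra(sp)$vza), -60)
})

test_that("resampling is exact at shared knots and idempotent", {
  # identity on the same grid
  d <- toy_spectra(n = 3, wl = seq(400, 900, 100))
  same <- resample_spectra(d, seq(400, 900, 100))
  expect_equal(spectra_matrix(same), spectra_matrix(d))

  # linear midpoint
  d2 <- flat_spectra(overrides = list(`700` = 0.2, `701` = 0.4))
  mid <- resample_spectra(d2, 700.5)
  expect_equal(unname(spectra_matrix(mid)[1, 1]), 0.3)

  # instrument-style 3.5-nm grid onto 1 nm: values at shared wavelengths
  # reproduce the source exactly
  wl_src <- seq(399.5, 900, by = 3.5)
  set.seed(9)
  d3 <- dplyr::bind_cols(
    tibble::tibble(sample_id = "a", vza = 0, lai = 3),
    tibble::as_tibble(matrix(runif(length(wl_src), 0.05, 0.5), 1,
                             dimnames = list(NULL, wl_src)))
  )
  fine <- resample_spectra(d3, canonical_grid())
  shared <- intersect(canonical_grid(), wl_src)
  expect_gt(length(shared), 50)
  expect_equal(spectra_matrix(fine)[, as.character(shared)],
               spectra_matrix(d3)[, as.character(shared)], tolerance = 1e-12)

  # idempotent on its own output grid
  again <- resample_spectra(fine, canonical_grid())
  expect_equal(spectra_matrix(again), spectra_matrix(fine))
})

test_that("resampling refuses to extrapolate", {
  d <- toy_spectra(wl = seq(450, 850, 50))
  expect_error(resample_spectra(d, seq(400, 900, 1)), "extends beyond")
})

test_that("band lookup is exact on the 1-nm grid and bounded at 2 nm", {
  d <- flat_spectra(overrides = list(`810` = 0.77))
  expect_equal(band_at(d, 810), 0.77)
  expect_equal(band_at(d, 810.4), 0.77)   # nearest rule
  expect_error(band_at(d, 320), "no band within 2 nm")
})

test_that("partition reproduces the 176/45 split with near-equal folds", {
  d <- generate_canopy(canopy_config(n_samples = 221, seed = 5), vzas = 0)
  p <- make_partition(d, n_train = 176, k = 5, seed = 42)
  expect_equal(sum(p$role == "train"), 176)
  expect_equal(sum(p$role == "test"), 45)
  expect_equal(sort(as.integer(table(p$fold))), c(35, 35, 35, 35, 36))
  expect_true(all(is.na(p$fold[p$role == "test"])))

  p2 <- make_partition(d, n_train = 176, k = 5, seed = 42)
  expect_identical(p, p2)
  expect_error(make_partition(d, n_train = 221), "must be smaller")
})

test_that("partition is disjoint and exhaustive for every seed", {
  d <- toy_spectra(n = 21)
  for (s in 1:100) {
    p <- make_partition(d, n_train = 15, k = 3, seed = s)
    expect_setequal(p$sample_id, d$sample_id)
    expect_equal(sum(p$role == "train") + sum(p$role == "test"), 21)
    expect_false(any(p$role == "train" & is.na(p$fold)))
  }
})
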