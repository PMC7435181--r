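test_that("index forms follow their defining arithmetic", {
  expect_equal(two_band_index("ND", 0.5, 0.1), 0.4 / 0.6)
  expect_equal(two_band_index("ND", 0.3, 0.3), 0)
  expect_equal(two_band_index("SR", 0.3, 0.3), 1)
  expect_equal(two_band_index("DVI", 0.3, 0.3), 0)
  expect_true(is.na(two_band_index("SR", 0.3, 0)))
})

test_that("vectorized surface equals the per-cell lm oracle", {
  d <- toy_spectra(n = 20, wl = seq(500, 950, 50), seed = 7)
  for (tp in c("ND", "SR", "DVI")) {
    s <- r2_surface(d, tp)
    o <- naive_surface(d, tp)
    expect_equal(s$r2, o, tolerance = 1e-10, label = tp)
    expect_true(all(is.na(diag(s$r2))), label = tp)
    expect_true(all(s$n_used[!is.na(s$r2)] == 20))
  }
})

test_that("ND and DVI surfaces are swap-symmetric, SR is not", {
  d <- toy_spectra(n = 15, wl = seq(500, 900, 50), seed = 8)
  for (tp in c("ND", "DVI")) {
    s <- r2_surface(d, tp)$r2
    expect_equal(s, t(s), label = tp)
  }
  sr <- r2_surface(d, "SR")$r2
  off <- abs(sr - t(sr))
  expect_gt(max(off, na.rm = TRUE), 1e-6)
})

test_that("a constant LAI yields an all-zero surface with a warning", {
  d <- toy_spectra(n = 10, wl = seq(500, 700, 50), lai = rep(3, 10))
  expect_warning(s <- r2_surface(d, "ND"), "constant")
  vals <- s$r2[!is.na(s$r2)]
  expect_true(all(vals == 0))
})

test_that("no pair beats the two-band saturated OLS fit", {
  d <- toy_spectra(n = 25, wl = seq(500, 800, 100), seed = 9)
  m <- spectra_matrix(d)
  for (tp in c("ND", "SR", "DVI")) {
    s <- r2_surface(d, tp)
    for (i in seq_len(ncol(m))) {
      for (j in seq_len(ncol(m))) {
        if (is.na(s$r2[i, j])) next
        cap <- summary(lm(d$lai ~ m[, i] + m[, j]))$r.squared
        expect_lte(s$r2[i, j], cap + 1e-10)
      }
    }
  }
})

test_that("optimum selection breaks ties toward short wavelengths", {
  wl <- c(700, 710, 750, 760)
  r2 <- matrix(0.1, 4, 4, dimnames = list(wl, wl))
  r2[1, 3] <- 0.9   # (700, 750)
  r2[2, 4] <- 0.9   # (710, 760)
  surf <- structure(list(index_type = "ND", vza = 0, wavelengths = wl, r2 = r2,
                         n_used = matrix(10L, 4, 4), n_cal = 10L),
                    class = "r2_surface")
  best <- select_optimum(surf)
  expect_equal(c(best$lambda1, best$lambda2), c(700, 750))

  single <- surf
  single$r2[] <- NA_real_
  single$r2[2, 3] <- 0.4
  best1 <- select_optimum(single)
  expect_equal(c(best1$lambda1, best1$lambda2), c(710, 750))

  none <- surf
  none$r2[] <- NA_real_
  expect_error(select_optimum(none), "no defined cells")
})

test_that("refit line at the winning pair matches a direct lm", {
  d <- toy_spectra(n = 30, wl = seq(500, 900, 100), seed = 10)
  s <- r2_surface(d, "DVI")
  best <- select_optimum(s, d)
  idx <- two_band_index("DVI", band_at(d, best$lambda1), band_at(d, best$lambda2))
  ref <- lm(d$lai ~ idx)
  expect_equal(best$slope, unname(coef(ref)[2]), tolerance = 1e-12)
  expect_equal(best$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
  expect_equal(best$r2, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("surface export round-trips through the long CSV format", {
  d <- toy_spectra(n = 12, wl = seq(500, 900, 50), seed = 12)
  s <- r2_surface(d, "ND")
  path <- withr::local_tempfile(fileext = ".csv")
  export_surface(s, path)
  expect_equal(readLines(path, n = 1), "lambda1,lambda2,r2")
  expect_lte(length(readLines(path)) - 1, length(s$wavelengths)^2)
  back <- read_surface(path, "ND", 0)
  expect_equal(back$r2, s$r2, tolerance = 1e-12)
})

test_that("the calibration subset drives the surface when a partition is given", {
  d <- toy_spectra(n = 20, wl = seq(500, 700, 100), seed = 13)
  p <- make_partition(d, n_train = 15, k = 3, seed = 1)
  s <- r2_surface(d, "ND", partition = p)
  expect_equal(s$n_cal, 15)
  manual <- r2_surface(d[d$sample_id %in% p$sample_id[p$role == "train"], ], "ND")
  expect_equal(s$r2, manual$r2)
})

test_that("nadir-optimal difference pairs concentrate in the red edge", {
  for (s in 1:5) {
    d <- generate_canopy(canopy_config(seed = s), vzas = 0)
    best <- select_optimum(r2_surface(d, "DVI", step = 5))
    expect_true(best$lambda1 >= 700 && best$lambda1 <= 780, label = paste("seed", s))
    expect_true(best$lambda2 >= 700 && best$lambda2 <= 780, label = paste("seed", s))
  }
})
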