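test_that("LAI draws match the configured truncated normal", {
  x <- sample_lai(10000, canopy_config(seed = 1))
  expect_true(all(x >= 1.25 & x <= 8.76))
  expect_lt(abs(mean(x) - 4.90), 0.1)
  expect_lt(abs(sd(x) - 1.63), 0.15)

  degenerate <- sample_lai(50, canopy_config(lai_sd = 0, seed = 1))
  expect_true(all(degenerate == 4.90))

  expect_error(canopy_config(lai_min = 9, lai_max = 8), "below lai_max")
})

test_that("gap fraction follows Beer-Lambert in LAI and view angle", {
  cfg <- canopy_config(k_ext = 0.5, clumping = 1)
  expect_equal(gap_fraction(2, 0, cfg), exp(-1))
  expect_equal(gap_fraction(0, 37, cfg), 1.0)
  lai <- c(0.5, 2, 5, 8)
  expect_true(all(gap_fraction(lai, 60, cfg) < gap_fraction(lai, 0, cfg)))
  # vegetation fraction increases with LAI and |vza|
  expect_true(all(diff(1 - gap_fraction(lai, 0, cfg)) > 0))
  expect_true(all((1 - gap_fraction(lai, 50, cfg)) > (1 - gap_fraction(lai, 20, cfg))))
  expect_error(gap_fraction(2, 90, cfg), "below 90")
})

test_that("chlorophyll deepens the red trough and shifts the red edge", {
  grid <- canonical_grid()
  r0 <- leaf_reflectance(0, grid = grid)
  r20 <- leaf_reflectance(20, grid = grid)
  r40 <- leaf_reflectance(40, grid = grid)
  at <- function(r, w) r[grid == w]

  # zero-absorption limit: no trough beyond the sigmoid baseline
  no_trough <- leaf_reflectance(0, leaf_params(trough_max = 0), grid)
  expect_equal(at(r0, 670), at(no_trough, 670))
  expect_lt(at(r40, 670), at(r20, 670))     # monotone absorption

  # red-edge inflection = argmax of the first difference in 690-750 nm
  inflection <- function(r) {
    win <- grid >= 690 & grid <= 750
    d <- diff(r)[win[-1]]
    grid[win][which.max(d)]
  }
  expect_gt(inflection(r40), inflection(r20))
  for (cab in c(0, 15, 40, 80)) {
    r <- leaf_reflectance(cab, grid = grid)
    expect_true(all(r >= 0.01 & r <= 0.99))
  }
})

test_that("canopy spectra hit the bare-soil and closed-canopy limits", {
  cfg <- canopy_config(noise_sd0 = 0, soil_brightness_sd = 0, leaf_nir_sd = 0)
  soil <- cfg$soil_intercept + cfg$soil_slope * (cfg$grid - 400)
  expect_equal(simulate_canopy(0, 40, 0, cfg, noise = FALSE), soil)

  closed <- simulate_canopy(50, 40, 0, cfg, noise = FALSE)
  leaf <- leaf_reflectance(40, cfg$leaf, cfg$grid)
  expect_true(all(abs(closed - leaf) / leaf < 0.01))

  a <- simulate_canopy(3, 40, 20, cfg)
  b <- simulate_canopy(3, 40, 20, cfg)
  expect_identical(a, b)   # noiseless path is deterministic
})

test_that("multi-angle generation shares state across angles", {
  cfg <- canopy_config(n_samples = 30, seed = 11)
  d <- generate_canopy(cfg)
  expect_equal(sort(unique(d$vza)), seq(-60, 60, 10))
  expect_equal(nrow(d), 30 * 13)
  lai_by_vza <- split(d$lai, d$vza)
  for (block in lai_by_vza) expect_identical(block, lai_by_vza[[1]])

  d2 <- generate_canopy(cfg)
  expect_identical(d, d2)   # same seed, bit-identical

  m <- spectra_matrix(d)
  expect_true(all(m >= 0 & m <= 1))
})

test_that("red-edge reflectance carries the LAI signal at nadir", {
  for (s in 1:10) {
    d <- generate_canopy(canopy_config(n_samples = 120, seed = s), vzas = 0)
    m <- spectra_matrix(d)
    wl <- as.numeric(colnames(m))
    cc <- abs(suppressWarnings(cor(m, d$lai)))
    expect_gt(mean(cc[wl >= 720 & wl <= 760]), mean(cc[wl >= 500 & wl <= 560]))
  }
})

test_that("backscatter is brighter than forward scatter at equal |vza|", {
  cfg <- canopy_config(noise_sd0 = 0, soil_brightness_sd = 0, leaf_nir_sd = 0)
  back <- simulate_canopy(4, 40, -50, cfg, noise = FALSE)
  fwd <- simulate_canopy(4, 40, +50, cfg, noise = FALSE)
  expect_gt(mean(back), mean(fwd))
})
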