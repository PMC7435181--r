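test_that("R-squared follows its defining sums of squares", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 4, 6)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  # validation-style predictions may push it negative; never clamped
  expect_lt(r_squared(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_error(r_squared(rep(2, 4), 1:4), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")

  set.seed(51)
  o <- rnorm(50); p <- rnorm(50)
  expect_equal(r_squared(o, p), naive_r2(o, p), tolerance = 1e-12)
})

test_that("RMSE follows its defining formula", {
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(0, 2), c(2, 2)), sqrt(2))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  set.seed(52)
  o <- rnorm(50); p <- rnorm(50)
  expect_equal(rmse(o, p), naive_rmse(o, p), tolerance = 1e-12)
})

test_that("simple linear fits match closed-form least squares", {
  f <- fit_linear(c(0, 1), c(1, 3))
  expect_equal(c(f$slope, f$intercept), c(2, 1))
  f2 <- fit_linear(c(0, 1, 2), c(0, 1, 3))
  expect_equal(f2$slope, 1.5)
  expect_equal(f2$intercept, -1 / 6)
  expect_equal(predict(f2, 2), 1.5 * 2 - 1 / 6)
  expect_error(fit_linear(rep(1, 5), 1:5), "constant")
})

test_that("decline versus nadir is a relative percentage", {
  profile <- tibble::tibble(
    method = "m", set = "validation",
    vza = c(-60, 0, 60), r2 = c(0.6, 0.8, 0.4), rmse = 1, n = 45
  )
  d <- decline_vs_nadir(profile)
  expect_equal(d$decline_pct[d$vza == 60], 50)
  expect_equal(d$decline_pct[d$vza == 0], 0)
  expect_equal(d$decline_pct[d$vza == -60], 25)

  flat <- dplyr::mutate(profile, r2 = 0.7)
  expect_true(all(decline_vs_nadir(flat)$decline_pct == 0))

  bad <- dplyr::mutate(profile, r2 = c(0.2, -0.1, 0.1))
  expect_true(all(is.na(decline_vs_nadir(bad)$decline_pct)))

  expect_error(decline_vs_nadir(profile[profile$vza != 0, ]), "nadir")
})

test_that("relative improvement reproduces its defining arithmetic", {
  expect_equal(relative_improvement(0.9, 0.45), 100)
  expect_equal(relative_improvement(0.5, 0.5), 0)
  expect_true(is.na(relative_improvement(0.5, 0)))
  a <- tibble::tibble(method = "plsr", vza = 0, set = "validation", r2 = 0.8)
  b <- tibble::tibble(method = "vi", vza = 60, set = "validation", r2 = 0.4)
  expect_error(relative_improvement(a, b), "different angles")
})

test_that("evaluation spans methods, angles and sets", {
  d <- generate_canopy(canopy_config(n_samples = 40, seed = 6),
                       vzas = c(-20, 0, 20))
  p <- make_partition(d, n_train = 30, k = 3, seed = 2)
  res <- evaluate_vza(d, p, methods = c("vi", "optimal_vi"), opt_step = 25)
  expect_equal(nrow(res), 2 * 3 * 2)
  expect_setequal(unique(res$vza), c(-20, 0, 20))
  expect_setequal(unique(res$set), c("calibration", "validation"))
  expect_true(all(res$n > 0))
  # determinism
  res2 <- evaluate_vza(d, p, methods = c("vi", "optimal_vi"), opt_step = 25)
  expect_equal(res, res2)
  # a requested angle that is absent is a completeness error
  expect_error(evaluate_vza(d, p, methods = "vi", vzas = c(0, 30)), "absent")
})

test_that("noise-free linear structure is recovered perfectly at every angle", {
  wl <- c(650, 700, 750, 800, 850)
  n <- 30
  set.seed(53)
  lai <- runif(n, 1.5, 8)
  blocks <- lapply(c(-60, 0, 60), function(v) {
    m <- matrix(0.3, n, length(wl), dimnames = list(NULL, wl))
    m[, "650"] <- 0.1 + lai / 20
    dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("P%02d", 1:n), vza = v, lai = lai),
      tibble::as_tibble(m)
    )
  })
  d <- dplyr::bind_rows(blocks)
  p <- make_partition(d, n_train = 22, k = 3, seed = 4)
  res <- evaluate_vza(d, p, methods = c("optimal_vi", "plsr"), opt_step = 50,
                      plsr_max = 3)
  expect_true(all(res$r2 > 0.999))
  expect_true(all(res$rmse < 0.01))
})
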