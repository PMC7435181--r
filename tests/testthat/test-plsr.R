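test_that("one component on one predictor collapses to simple OLS", {
  set.seed(21)
  x <- matrix(rnorm(30), 30, 1)
  y <- 2 + 1.5 * x[, 1] + rnorm(30, 0, 0.2)
  fit <- fit_plsr(x, y, ncomp = 1)
  ols <- lm(y ~ x[, 1])
  expect_equal(predict(fit, x), unname(fitted(ols)), tolerance = 1e-10)
})

test_that("full-component PLSR equals multivariate OLS", {
  set.seed(22)
  x <- matrix(rnorm(40), 10, 4)
  y <- rnorm(10)
  fit <- fit_plsr(x, y, ncomp = 4)
  ols <- lm(y ~ x)
  expect_equal(predict(fit, x), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("a response duplicated as predictor is fit exactly by one component", {
  set.seed(23)
  y <- rnorm(15, 5, 2)
  x <- cbind(y, y)
  fit <- fit_plsr(x, y, ncomp = 1)
  expect_equal(r_squared(y, predict(fit, x)), 1, tolerance = 1e-12)
})

test_that("score vectors are mutually orthogonal", {
  set.seed(24)
  x <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30)
  fit <- fit_plsr(x, y, ncomp = 8)
  g <- crossprod(fit$scores)
  off <- g - diag(diag(g))
  expect_lt(max(abs(off)), 1e-8)
})

test_that("regression-vector and sequential-score predictions agree", {
  set.seed(25)
  x <- matrix(rnorm(30 * 20), 30, 20)
  y <- rnorm(30)
  fit <- fit_plsr(x, y, ncomp = 5)
  xnew <- matrix(rnorm(8 * 20), 8, 20)
  expect_equal(predict(fit, xnew),
               angulai:::predict_plsr_scores(fit, xnew), tolerance = 1e-10)
  # and for every truncated component count
  for (a in 1:5) {
    expect_equal(predict(fit, xnew, ncomp = a),
                 angulai:::predict_plsr_scores(fit, xnew, ncomp = a),
                 tolerance = 1e-10)
  }
})

test_that("rank limits truncate the component count with a warning", {
  set.seed(26)
  scores <- matrix(rnorm(20 * 3), 20, 3)
  load <- matrix(rnorm(3 * 10), 3, 10)
  x <- scores %*% load               # exact rank 3
  y <- scores %*% c(1, -1, 0.5)
  expect_warning(fit <- fit_plsr(x, as.vector(y), ncomp = 6), "stopped after")
  expect_lte(fit$ncomp, 4)

  expect_warning(fit_plsr(matrix(rnorm(12), 6, 2), rnorm(6), ncomp = 5),
                 "reduced")
  expect_error(fit_plsr(matrix(rnorm(12), 6, 2), rep(1, 6), ncomp = 1),
               "zero variance")
})

test_that("loadings align to the wavelength grid and recover rank-1 structure", {
  d <- generate_canopy(canopy_config(n_samples = 40, seed = 2), vzas = 0)
  fit <- fit_plsr(d, ncomp = 3)
  lo <- plsr_loadings(fit)
  expect_equal(nrow(lo), 3 * 501)
  expect_equal(unique(lo$wavelength), canonical_grid())
  expect_error(plsr_loadings(fit, 9), "component must be")

  set.seed(27)
  t1 <- rnorm(25)
  p1 <- rnorm(12)
  x <- outer(t1, p1)
  fit1 <- fit_plsr(x, t1, ncomp = 1)
  sv <- svd(scale(x, scale = FALSE))$v[, 1]
  l1 <- fit1$loadings[, 1]
  cosine <- abs(sum(l1 * sv)) / sqrt(sum(l1^2) * sum(sv^2))
  expect_equal(cosine, 1, tolerance = 1e-8)
})

test_that("tidy and glance expose coefficients and training metrics", {
  d <- generate_canopy(canopy_config(n_samples = 40, seed = 3), vzas = 0)
  fit <- fit_plsr(d, ncomp = 4)
  td <- tidy(fit)
  expect_equal(nrow(td), 502)
  expect_equal(td$term[1], "(Intercept)")
  # tidy coefficients reproduce predictions on the original scale
  m <- spectra_matrix(d)
  manual <- td$estimate[1] + as.vector(m %*% td$estimate[-1])
  expect_equal(manual, predict(fit, d), tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$ncomp, 4)
  expect_gt(gl$r2, 0.5)
})

test_that("cross-validation recovers a known factor dimension", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(60 + s)
    n <- 80; p <- 50
    scores <- matrix(rnorm(n * 3), n, 3)
    load <- matrix(rnorm(3 * p), 3, p)
    x <- scores %*% load + matrix(rnorm(n * p, 0, 0.05), n, p)
    y <- as.vector(scores %*% c(1.5, 1.2, -1)) + rnorm(n, 0, 0.25)
    sel <- select_components(x, y, a_max = 8, folds = 5, seed = s)
    hits <- hits + (sel$chosen %in% 3:4)
    expect_equal(nrow(sel$curve), 8)
    if (s == 1) {
      one <- select_components(x, y, a_max = 1, folds = 5, seed = s)
      expect_equal(one$chosen, 1)
    }
  }
  expect_gte(hits, 3)
})

test_that("the CV RMSE curve rises again after its optimum on canopy data", {
  d <- generate_canopy(canopy_config(n_samples = 120, seed = 9), vzas = 0)
  p <- make_partition(d, n_train = 95, k = 5, seed = 3)
  cal <- d[d$sample_id %in% p$sample_id[p$role == "train"], ]
  folds <- p$fold[match(cal$sample_id, p$sample_id)]
  sel <- select_components(cal, a_max = 15, folds = folds)
  curve <- sel$curve$rmse_cv
  expect_gt(curve[length(curve)], min(curve))
  expect_lt(sel$chosen, 15)
  td <- tidy(sel)
  expect_equal(sum(td$chosen), 1)
})
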