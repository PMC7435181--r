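## Partial least squares regression via NIPALS ----------------------------
##
## Univariate-response NIPALS: X and y are mean-centered (optionally X is
## unit-variance scaled); each component takes the weight vector
## w = X'y / ||X'y||, scores t = Xw, loadings p = X't / t't and
## y-loading q = y't / t't, then deflates X and y. The regression vector
## is B = W (P'W)^{-1} q. Successive score vectors are orthogonal; with as
## many components as the predictor rank the fit coincides with ordinary
## least squares.

coerce_xy <- function(x, y) {
  if (is.data.frame(x)) {
    if (is.null(y)) {
      if (!"lai" %in% names(x)) stop("y missing and data has no lai column", call. = FALSE)
      y <- x$lai
    }
    x <- spectra_matrix(x)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(y) != nrow(x)) stop("x and y dimensions disagree", call. = FALSE)
  list(x = x, y = as.numeric(y))
}

#' Fit a PLSR model by NIPALS
#'
#' @param x Predictor matrix (samples x bands) or a spectra tibble (in
#'   which case `y` defaults to its `lai` column).
#' @param y Response vector.
#' @param ncomp Number of latent variables A.
#' @param scale Scale predictors to unit variance? Mean-centering is always
#'   applied; scaling is off by default since reflectance bands share
#'   units.
#' @return Object of class `plsr_fit` with weights, loadings, y-loadings,
#'   scores, the assembled regression vector and centering/scaling
#'   statistics. If `ncomp` exceeds the effective rank the component count
#'   is truncated with a warning.
#' @export
#' @examples
#' d <- generate_canopy(canopy_config(n_samples = 30), vzas = 0)
#' fit <- fit_plsr(d, ncomp = 3)
#' glance(fit)
fit_plsr <- function(x, y = NULL, ncomp = 10, scale = FALSE) {
  d <- coerce_xy(x, y)
  x <- d$x; y <- d$y
  n <- nrow(x); p <- ncol(x)
  if (ncomp < 1) stop("ncomp must be at least 1", call. = FALSE)
  if (sd(y) == 0) stop("response has zero variance", call. = FALSE)
  a_max <- min(n - 1, p)
  if (ncomp > a_max) {
    warning(sprintf("ncomp reduced from %d to %d (sample/band limit)", ncomp, a_max),
            call. = FALSE)
    ncomp <- a_max
  }
  x_mean <- colMeans(x)
  x_scale <- if (scale) pmax(apply(x, 2, sd), 1e-10) else rep(1, p)
  xc <- sweep(sweep(x, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  u <- y - y_mean

  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  used <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(xc, u)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t_a <- xc %*% w
    tt <- sum(t_a^2)
    if (tt < 1e-12) break
    p_a <- crossprod(xc, t_a) / tt
    q_a <- sum(u * t_a) / tt
    xc <- xc - t_a %*% t(p_a)
    u <- u - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    used <- a
  }
  if (used < ncomp) {
    warning(sprintf("NIPALS stopped after %d of %d components (rank exhausted)",
                    used, ncomp), call. = FALSE)
    W <- W[, seq_len(used), drop = FALSE]; P <- P[, seq_len(used), drop = FALSE]
    Tm <- Tm[, seq_len(used), drop = FALSE]; q <- q[seq_len(used)]
  }
  coefs <- W %*% solve(crossprod(P, W), q)
  wl <- suppressWarnings(as.numeric(colnames(x)))
  fit <- structure(list(ncomp = used, weights = W, loadings = P,
                        y_loadings = q, scores = Tm, coefficients = coefs,
                        x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                        wavelengths = wl, n = n, p = p, scale = scale),
                   class = "plsr_fit")
  fit$fitted <- predict(fit, x)
  fit$y <- y
  fit
}

plsr_coefs <- function(object, ncomp) {
  if (ncomp == object$ncomp) return(object$coefficients)
  W <- object$weights[, seq_len(ncomp), drop = FALSE]
  P <- object$loadings[, seq_len(ncomp), drop = FALSE]
  W %*% solve(crossprod(P, W), object$y_loadings[seq_len(ncomp)])
}

#' Predict from a PLSR fit
#'
#' @param object A `plsr_fit`.
#' @param newdata Predictor matrix or spectra tibble.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_fit <- function(object, newdata, ncomp = NULL, ...) {
  ncomp <- ncomp %||% object$ncomp
  if (ncomp < 1 || ncomp > object$ncomp) {
    stop(sprintf("ncomp must be in 1..%d", object$ncomp), call. = FALSE)
  }
  if (is.data.frame(newdata)) newdata <- spectra_matrix(newdata)
  xc <- sweep(sweep(as.matrix(newdata), 2, object$x_mean), 2, object$x_scale, "/")
  as.vector(xc %*% plsr_coefs(object, ncomp)) + object$y_mean
}

## Prediction by sequential score projection (deflating new data with the
## fitted loadings). Numerically equal to the regression-vector path; kept
## as an independent route for the test suite.
predict_plsr_scores <- function(object, newdata, ncomp = object$ncomp) {
  if (is.data.frame(newdata)) newdata <- spectra_matrix(newdata)
  xc <- sweep(sweep(as.matrix(newdata), 2, object$x_mean), 2, object$x_scale, "/")
  pred <- rep(object$y_mean, nrow(xc))
  for (a in seq_len(ncomp)) {
    t_a <- xc %*% object$weights[, a]
    pred <- pred + as.vector(t_a) * object$y_loadings[a]
    xc <- xc - t_a %*% t(object$loadings[, a])
  }
  pred
}

#' Per-wavelength loadings of a PLSR fit
#'
#' The loading spectrum of one (or every) latent variable, aligned to the
#' wavelength grid, ready for a loading plot or CSV export.
#'
#' @param object A `plsr_fit`.
#' @param component Component index, or `NULL` for all.
#' @return Tibble with columns `wavelength`, `component`, `loading`.
#' @export
plsr_loadings <- function(object, component = NULL) {
  comps <- component %||% seq_len(object$ncomp)
  if (any(comps < 1 | comps > object$ncomp)) {
    stop(sprintf("component must be in 1..%d", object$ncomp), call. = FALSE)
  }
  wl <- object$wavelengths
  if (all(is.na(wl))) wl <- seq_len(object$p)
  dplyr::bind_rows(lapply(comps, function(a) {
    tibble::tibble(wavelength = wl, component = as.integer(a),
                   loading = object$loadings[, a])
  }))
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("<plsr_fit> %d components, n = %d, %d bands%s\n",
              x$ncomp, x$n, x$p, if (x$scale) " (scaled)" else ""))
  invisible(x)
}

#' Tidy PLSR coefficients
#'
#' Regression coefficients on the original predictor scale, with the
#' intercept as the first row (broom convention).
#'
#' @param x A `plsr_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term` and `estimate`.
#' @method tidy plsr_fit
#' @export
tidy.plsr_fit <- function(x, ...) {
  beta <- as.vector(x$coefficients) / x$x_scale
  intercept <- x$y_mean - sum(x$x_mean * beta)
  term <- if (all(is.na(x$wavelengths))) paste0("x", seq_len(x$p)) else
    as.character(x$wavelengths)
  tibble::tibble(term = c("(Intercept)", term),
                 estimate = c(intercept, beta))
}

#' One-row summary of a PLSR fit
#'
#' @param x A `plsr_fit`.
#' @param ... Unused.
#' @return Tibble with `ncomp`, `n`, `p`, and training-set `r2` and
#'   `rmse`.
#' @method glance plsr_fit
#' @export
glance.plsr_fit <- function(x, ...) {
  tibble::tibble(ncomp = x$ncomp, n = x$n, p = x$p,
                 r2 = r_squared(x$y, x$fitted),
                 rmse = rmse(x$y, x$fitted))
}

#' Cross-validated choice of the number of latent variables
#'
#' Computes, for A = 1..`a_max`, the k-fold cross-validated RMSE in which
#' every calibration sample is predicted exactly once, and picks the A
#' with the smallest CV RMSE (ties go to the smallest A).
#'
#' @param x Predictor matrix or spectra tibble.
#' @param y Response (defaults to the tibble's `lai`).
#' @param a_max Largest candidate A (default 15).
#' @param folds Either a fold label per sample (as from
#'   [make_partition()]'s `fold` column) or a fold count k; a count is
#'   assigned randomly using `seed`.
#' @param scale Passed to [fit_plsr()].
#' @param seed Seed used only when `folds` is a count.
#' @return Object of class `plsr_selection`: tibble `curve` (`ncomp`,
#'   `rmse_cv`), `chosen`, `a_max`.
#' @export
select_components <- function(x, y = NULL, a_max = 15, folds = 5,
                              scale = FALSE, seed = 1) {
  d <- coerce_xy(x, y)
  x <- d$x; y <- d$y
  n <- nrow(x)
  if (a_max < 1) stop("a_max must be at least 1", call. = FALSE)
  if (length(folds) == 1) {
    folds <- with_seed(seed, sort(rep_len(seq_len(folds), n))[sample.int(n)])
  }
  if (length(folds) != n) stop("fold labels must match the sample count", call. = FALSE)
  min_train <- n - max(table(folds))          # smallest training set over folds
  a_max <- min(a_max, min_train - 1, ncol(x))
  preds <- matrix(NA_real_, n, a_max)
  for (f in sort(unique(folds))) {
    itr <- folds != f
    fit <- suppressWarnings(fit_plsr(x[itr, , drop = FALSE], y[itr],
                                     ncomp = a_max, scale = scale))
    for (a in seq_len(min(a_max, fit$ncomp))) {
      preds[!itr, a] <- predict(fit, x[!itr, , drop = FALSE], ncomp = a)
    }
  }
  rmse_cv <- apply(preds, 2, function(p) {
    ok <- !is.na(p)
    if (!any(ok)) return(NA_real_)   # A beyond the rank of every fold fit
    rmse(y[ok], p[ok])
  })
  curve <- tibble::tibble(ncomp = seq_len(a_max), rmse_cv = rmse_cv)
  structure(list(curve = curve, chosen = curve$ncomp[which.min(curve$rmse_cv)],
                 a_max = a_max),
            class = "plsr_selection")
}

#' @export
print.plsr_selection <- function(x, ...) {
  cat(sprintf("<plsr_selection> chosen A = %d (of 1..%d), CV RMSE = %.4f\n",
              x$chosen, x$a_max, min(x$curve$rmse_cv)))
  invisible(x)
}

#' Tidy a latent-variable selection
#'
#' @param x A `plsr_selection`.
#' @param ... Unused.
#' @return The CV RMSE curve with a logical `chosen` column.
#' @method tidy plsr_selection
#' @export
tidy.plsr_selection <- function(x, ...) {
  dplyr::mutate(x$curve, chosen = .data$ncomp == x$chosen)
}
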