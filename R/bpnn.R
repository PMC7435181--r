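## Single-hidden-layer back-propagation network ---------------------------
##
## A feedforward regressor with one ReLU hidden layer and a linear output,
## trained by full-batch Adam on mean-squared error. Features are
## standardized with training statistics (the response is standardized
## too, and predictions are mapped back). The hidden size is chosen by
## k-fold cross-validated RMSE over a grid, and the final model is the
## best of `repeats` random initializations, ranked by their own CV RMSE.

adam_train <- function(xs, ys, hidden, epochs, learn_rate, seed,
                       patience = 50, tol = 1e-6) {
  d <- ncol(xs); n <- nrow(xs)
  with_seed(seed, {
    w1 <- matrix(rnorm(d * hidden, 0, sqrt(2 / d)), d, hidden)
    b1 <- numeric(hidden)
    w2 <- matrix(rnorm(hidden, 0, sqrt(1 / hidden)), hidden, 1)
    b2 <- 0
    m <- list(w1 = w1 * 0, b1 = b1, w2 = w2 * 0, b2 = 0)
    v <- m
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    best <- Inf; wait <- 0L; step <- 0L; epochs_run <- 0L
    for (e in seq_len(epochs)) {
      h_pre <- sweep(xs %*% w1, 2, b1, "+")
      h <- pmax(h_pre, 0)
      yhat <- as.vector(h %*% w2) + b2
      err <- yhat - ys
      loss <- mean(err^2)
      if (!is.finite(loss)) return(NULL)
      g_out <- matrix(2 * err / n, ncol = 1)
      g_w2 <- crossprod(h, g_out)
      g_b2 <- sum(g_out)
      g_h <- (g_out %*% t(w2)) * (h_pre > 0)
      g_w1 <- crossprod(xs, g_h)
      g_b1 <- colSums(g_h)
      step <- step + 1L
      upd <- function(par, grad, mm, vv) {
        mm <- beta1 * mm + (1 - beta1) * grad
        vv <- beta2 * vv + (1 - beta2) * grad^2
        mh <- mm / (1 - beta1^step)
        vh <- vv / (1 - beta2^step)
        list(par = par - learn_rate * mh / (sqrt(vh) + eps), m = mm, v = vv)
      }
      u <- upd(w1, g_w1, m$w1, v$w1); w1 <- u$par; m$w1 <- u$m; v$w1 <- u$v
      u <- upd(b1, g_b1, m$b1, v$b1); b1 <- u$par; m$b1 <- u$m; v$b1 <- u$v
      u <- upd(w2, g_w2, m$w2, v$w2); w2 <- u$par; m$w2 <- u$m; v$w2 <- u$v
      u <- upd(b2, g_b2, m$b2, v$b2); b2 <- u$par; m$b2 <- u$m; v$b2 <- u$v
      epochs_run <- e
      if (loss < best - tol) { best <- loss; wait <- 0L } else wait <- wait + 1L
      if (wait >= patience) break
    }
    list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, loss = best, epochs_run = epochs_run)
  })
}

bpnn_forward <- function(net, xs) {
  h <- pmax(sweep(xs %*% net$w1, 2, net$b1, "+"), 0)
  as.vector(h %*% net$w2) + net$b2
}

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv < 1e-10] <- 1
  list(mu = mu, sd = sdv)
}

standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mu), 2, st$sd, "/")
}

bpnn_cv_rmse <- function(x, y, hidden, folds, epochs, learn_rate, seed,
                         patience, tol) {
  preds <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    itr <- folds != f
    st <- standardize_fit(x[itr, , drop = FALSE])
    xs <- standardize_apply(x[itr, , drop = FALSE], st)
    ymu <- mean(y[itr]); ysd <- max(sd(y[itr]), 1e-10)
    net <- NULL
    for (try in 0:4) {
      net <- adam_train(xs, (y[itr] - ymu) / ysd, hidden, epochs, learn_rate,
                        derive_seed(seed, f * 17 + try), patience, tol)
      if (!is.null(net)) break
      message(sprintf("bpnn: non-finite loss (fold %d), restarting with a new seed", f))
    }
    if (is.null(net)) stop("bpnn training diverged repeatedly", call. = FALSE)
    xt <- standardize_apply(x[!itr, , drop = FALSE], st)
    preds[!itr] <- bpnn_forward(net, xt) * ysd + ymu
  }
  rmse(y, preds)
}

#' Fit a back-propagation neural network regressor
#'
#' One ReLU hidden layer, linear output, full-batch Adam on MSE. The
#' hidden size is selected by k-fold cross-validated RMSE over `hidden`
#' (ties to the smallest size); `repeats` random initializations are then
#' run at the selected size. With `aggregate = "average"` (default) the
#' fitted model predicts with the mean of all repeat networks, which
#' suppresses initialization variance directly; with `aggregate = "best"`
#' the single repeat with the smallest cross-validated RMSE is retained.
#' Deterministic given `seed`.
#'
#' @param x Predictor matrix or spectra tibble (then `y` defaults to
#'   `lai`).
#' @param y Response vector.
#' @param hidden Candidate hidden-layer sizes; each must lie in
#'   \[1, 200\]. Default grid spans 5-200.
#' @param repeats Number of random initializations at the selected size.
#' @param aggregate `"average"` (ensemble mean over repeats) or `"best"`
#'   (single repeat with the lowest CV RMSE).
#' @param epochs Maximum training epochs.
#' @param learn_rate Adam step size (default 1e-2; full-batch gradients
#'   are low-noise, so a larger step than the minibatch convention
#'   converges in a desk-scale epoch budget).
#' @param folds Fold count, or a fold label per sample.
#' @param seed Integer seed.
#' @param patience Early-stopping patience (epochs without loss
#'   improvement).
#' @param tol Minimum loss improvement counted by early stopping.
#' @return Object of class `bpnn_fit` with the network weights,
#'   standardization statistics, the grid-search report (`grid_report`)
#'   and the per-repeat CV RMSE distribution (`repeat_report`).
#' @export
#' @examples
#' \donttest{
#' d <- generate_canopy(canopy_config(n_samples = 60), vzas = 0)
#' fit <- fit_bpnn(d, hidden = 10, repeats = 2, epochs = 100, seed = 1)
#' glance(fit)
#' }
fit_bpnn <- function(x, y = NULL, hidden = c(5, 10, 20, 50, 100, 200),
                     repeats = 20, aggregate = c("average", "best"),
                     epochs = 500, learn_rate = 1e-2,
                     folds = 5, seed = 1, patience = 50, tol = 1e-6) {
  aggregate <- match.arg(aggregate)
  d <- coerce_xy(x, y)
  x <- d$x; y <- d$y
  n <- nrow(x)
  if (any(hidden < 1 | hidden > 200)) {
    stop("hidden sizes must lie in [1, 200]", call. = FALSE)
  }
  if (repeats < 1) stop("repeats must be at least 1", call. = FALSE)
  hidden <- sort(unique(as.integer(hidden)))
  if (length(folds) == 1) {
    folds <- with_seed(derive_seed(seed, 1L),
                       sort(rep_len(seq_len(folds), n))[sample.int(n)])
  }

  grid_report <- tibble::tibble(
    hidden = hidden,
    cv_rmse = vapply(seq_along(hidden), function(i) {
      bpnn_cv_rmse(x, y, hidden[i], folds, epochs, learn_rate,
                   derive_seed(seed, 100L + i), patience, tol)
    }, numeric(1))
  )
  h_best <- grid_report$hidden[which.min(grid_report$cv_rmse)]

  st <- standardize_fit(x)
  xs <- standardize_apply(x, st)
  ymu <- mean(y); ysd <- max(sd(y), 1e-10)
  repeat_report <- tibble::tibble(repeat_id = seq_len(repeats),
                                  train_loss = NA_real_, cv_rmse = NA_real_)
  nets <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    sr <- derive_seed(seed, 1000L + r)
    if (aggregate == "best") {
      repeat_report$cv_rmse[r] <- bpnn_cv_rmse(x, y, h_best, folds, epochs,
                                               learn_rate, sr, patience, tol)
    }
    net <- NULL
    for (try in 0:4) {
      net <- adam_train(xs, (y - ymu) / ysd, h_best, epochs, learn_rate,
                        derive_seed(sr, 7L + try), patience, tol)
      if (!is.null(net)) break
      message("bpnn: non-finite loss (final fit), restarting with a new seed")
    }
    if (is.null(net)) stop("bpnn training diverged repeatedly", call. = FALSE)
    nets[[r]] <- net
    repeat_report$train_loss[r] <- net$loss
  }
  best_rep <- if (aggregate == "best") which.min(repeat_report$cv_rmse) else
    which.min(repeat_report$train_loss)
  cv_rmse <- if (aggregate == "best") min(repeat_report$cv_rmse) else
    min(grid_report$cv_rmse)

  fit <- structure(list(hidden = h_best, aggregate = aggregate,
                        net = nets[[best_rep]],
                        nets = if (aggregate == "average") nets else NULL,
                        x_stats = st,
                        y_mean = ymu, y_sd = ysd, n = n, p = ncol(x),
                        cv_rmse = cv_rmse, repeat_chosen = best_rep,
                        epochs_run = nets[[best_rep]]$epochs_run,
                        grid_report = grid_report,
                        repeat_report = repeat_report, seed = seed),
                   class = "bpnn_fit")
  fit$fitted <- predict(fit, x)
  fit$y <- y
  fit
}

#' Predict from a BPNN fit
#'
#' @param object A `bpnn_fit`.
#' @param newdata Predictor matrix or spectra tibble.
#' @param ... Unused.
#' @return Numeric vector of predictions (finite for finite inputs; the
#'   ensemble mean over repeats when the fit was aggregated by averaging).
#' @export
predict.bpnn_fit <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- spectra_matrix(newdata)
  xs <- standardize_apply(as.matrix(newdata), object$x_stats)
  nets <- object$nets %||% list(object$net)
  preds <- vapply(nets, function(net) bpnn_forward(net, xs),
                  numeric(nrow(xs)))
  rowMeans(matrix(preds, nrow = nrow(xs))) * object$y_sd + object$y_mean
}

#' @export
print.bpnn_fit <- function(x, ...) {
  cat(sprintf("<bpnn_fit> hidden = %d, %s of %d repeats, CV RMSE = %.4f, n = %d\n",
              x$hidden, x$aggregate, nrow(x$repeat_report), x$cv_rmse, x$n))
  invisible(x)
}

#' One-row summary of a BPNN fit
#'
#' @param x A `bpnn_fit`.
#' @param ... Unused.
#' @return Tibble with the selected hidden size, CV RMSE, training-set
#'   metrics and run metadata.
#' @method glance bpnn_fit
#' @export
glance.bpnn_fit <- function(x, ...) {
  tibble::tibble(hidden = x$hidden, aggregate = x$aggregate,
                 cv_rmse = x$cv_rmse,
                 r2 = r_squared(x$y, x$fitted), rmse = rmse(x$y, x$fitted),
                 n = x$n, p = x$p, epochs_run = x$epochs_run,
                 repeat_chosen = x$repeat_chosen)
}

#' Tidy the weights of a BPNN fit
#'
#' @param x A `bpnn_fit`.
#' @param ... Unused.
#' @return Long tibble of weights: `layer` ("hidden"/"output"), `from`,
#'   `to`, `weight` (biases have `from = "(bias)"`).
#' @method tidy bpnn_fit
#' @export
tidy.bpnn_fit <- function(x, ...) {
  w1 <- x$net$w1; w2 <- x$net$w2
  inputs <- rownames(w1) %||% paste0("x", seq_len(nrow(w1)))
  dplyr::bind_rows(
    tibble::tibble(layer = "hidden",
                   from = rep(inputs, times = ncol(w1)),
                   to = rep(paste0("h", seq_len(ncol(w1))), each = nrow(w1)),
                   weight = as.vector(w1)),
    tibble::tibble(layer = "hidden", from = "(bias)",
                   to = paste0("h", seq_len(ncol(w1))), weight = x$net$b1),
    tibble::tibble(layer = "output", from = paste0("h", seq_len(nrow(w2))),
                   to = "y", weight = as.vector(w2)),
    tibble::tibble(layer = "output", from = "(bias)", to = "y",
                   weight = x$net$b2)
  )
}
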