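## Per-angle method comparison --------------------------------------------

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE / SST` with `SSE = sum((O - P)^2)` and
#' `SST = sum((O - mean(O))^2)`. For validation-set predictions the value
#' may be negative; it is reported raw, never clamped.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2);
#'   `observed` must not be constant.
#' @return R^2 as a plain number.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) stop("need at least 2 observations", call. = FALSE)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed values are constant; R^2 undefined", call. = FALSE)
  1 - sum((observed - predicted)^2) / sst
}

#' Root mean square error
#'
#' `RMSE = sqrt(mean((P - O)^2))`, in the units of the response.
#'
#' @inheritParams r_squared
#' @return RMSE as a plain number.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) == 0) stop("empty vectors", call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Simple linear LAI model on one predictor
#'
#' Ordinary least squares `y = slope * x + intercept`; the workhorse
#' behind every vegetation-index method.
#'
#' @param x Predictor vector (at least two distinct values).
#' @param y Response vector.
#' @return Object of class `linear_fit` with `slope`, `intercept`, `n`.
#' @export
fit_linear <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2 || length(unique(x[ok])) < 2) {
    stop("predictor is constant or has fewer than 2 defined values", call. = FALSE)
  }
  fit <- lm(y[ok] ~ x[ok])
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 n = sum(ok), n_dropped = sum(!ok)),
            class = "linear_fit")
}

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  object$slope * newdata + object$intercept
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> y = %.4g x + %.4g (n = %d)\n",
              x$slope, x$intercept, x$n))
  invisible(x)
}

method_row <- function(method, vza, set, obs, pred, info) {
  ok <- is.finite(pred) & is.finite(obs)
  tibble::tibble(method = method, vza = vza, set = set,
                 r2 = r_squared(obs[ok], pred[ok]),
                 rmse = rmse(obs[ok], pred[ok]),
                 n = sum(ok), info = list(info))
}

#' Compare LAI-estimation methods across view zenith angles
#'
#' For every angle present (or requested), trains each method on the
#' calibration subset of that angle's spectra and evaluates it on both
#' the calibration and validation subsets. The same partition (and its
#' cross-validation folds) is reused at every angle.
#'
#' Methods:
#' \describe{
#'   \item{`vi`}{a published vegetation index ([compute_vi()]) plus a
#'     linear LAI model;}
#'   \item{`optimal_vi`}{exhaustive two-band search ([r2_surface()]) on
#'     the calibration set, then a linear model at the winning pair;}
#'   \item{`plsr`}{NIPALS PLSR with the number of latent variables chosen
#'     by cross-validation ([select_components()]);}
#'   \item{`bpnn`}{single-hidden-layer network ([fit_bpnn()]).}
#' }
#'
#' @param data Stacked multi-angle spectra tibble with `lai`.
#' @param partition Partition from [make_partition()], shared across
#'   angles; or a named list of partitions keyed by angle (as
#'   `as.character(vza)`) for per-angle resplitting.
#' @param methods Subset of `c("vi", "optimal_vi", "plsr", "bpnn")`.
#' @param vzas Angles to evaluate (default: all present). An angle
#'   requested but absent from `data` is an error.
#' @param vi_name Index used by the `vi` method (default "DVI").
#' @param opt_type Index form searched by `optimal_vi` (default "DVI").
#' @param opt_step Search step in nm for `optimal_vi` (default 2).
#' @param plsr_max,plsr_scale Passed to [select_components()] /
#'   [fit_plsr()].
#' @param bpnn List of arguments for [fit_bpnn()] (e.g. `hidden`,
#'   `repeats`, `epochs`).
#' @param vi_config A [vi_band_config()].
#' @param seed Seed for the stochastic methods.
#' @return Tibble with one row per method x angle x set
#'   (calibration/validation): `method`, `vza`, `set`, `r2`, `rmse`, `n`
#'   and a list-column `info` of per-fit metadata (optimal pair, chosen
#'   number of latent variables, hidden size, ...).
#' @export
evaluate_vza <- function(data, partition,
                         methods = c("vi", "optimal_vi", "plsr", "bpnn"),
                         vzas = NULL, vi_name = "DVI", opt_type = "DVI",
                         opt_step = 2, plsr_max = 15, plsr_scale = FALSE,
                         bpnn = list(hidden = c(10, 30), repeats = 5,
                                     epochs = 150),
                         vi_config = vi_band_config(), seed = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  present <- sort(unique(data$vza))
  vzas <- sort(vzas %||% present)
  missing_v <- setdiff(vzas, present)
  if (length(missing_v) > 0) {
    stop(sprintf("requested VZAs absent from data: %s",
                 paste(missing_v, collapse = ", ")), call. = FALSE)
  }
  get_partition <- function(v) {
    if (is.data.frame(partition)) partition else partition[[as.character(v)]]
  }
  rows <- list()
  for (v in vzas) {
    dv <- data[data$vza == v, ]
    part <- get_partition(v)
    cal <- partition_subset(dv, part, "train")
    val <- partition_subset(dv, part, "test")
    folds <- partition_folds(cal, part)
    for (m in methods) {
      if (m == "vi") {
        icall <- compute_vi(cal, vi_name, vi_config)
        fit <- fit_linear(icall, cal$lai)
        pc <- predict(fit, icall)
        pv <- predict(fit, compute_vi(val, vi_name, vi_config))
        info <- list(vi_name = vi_name, slope = fit$slope,
                     intercept = fit$intercept, n_dropped = fit$n_dropped)
        label <- paste0("vi:", vi_name)
      } else if (m == "optimal_vi") {
        surf <- r2_surface(cal, opt_type, step = opt_step)
        best <- select_optimum(surf, cal)
        icall <- two_band_index(opt_type, band_at(cal, best$lambda1),
                                band_at(cal, best$lambda2))
        fit <- fit_linear(icall, cal$lai)
        pc <- predict(fit, icall)
        pv <- predict(fit, two_band_index(opt_type, band_at(val, best$lambda1),
                                          band_at(val, best$lambda2)))
        info <- list(index_type = opt_type, lambda1 = best$lambda1,
                     lambda2 = best$lambda2, r2_surface = best$r2,
                     slope = fit$slope, intercept = fit$intercept)
        label <- paste0("optimal:", opt_type)
      } else if (m == "plsr") {
        sel <- select_components(cal, a_max = plsr_max, folds = folds,
                                 scale = plsr_scale)
        fit <- fit_plsr(cal, ncomp = sel$chosen, scale = plsr_scale)
        pc <- predict(fit, cal)
        pv <- predict(fit, val)
        info <- list(ncomp = sel$chosen, cv_rmse = min(sel$curve$rmse_cv),
                     curve = sel$curve)
        label <- "plsr"
      } else { # bpnn
        args <- c(list(x = cal, folds = folds,
                       seed = derive_seed(seed, round(v) + 90L)), bpnn)
        fit <- do.call(fit_bpnn, args)
        pc <- predict(fit, cal)
        pv <- predict(fit, val)
        info <- list(hidden = fit$hidden, cv_rmse = fit$cv_rmse,
                     repeat_chosen = fit$repeat_chosen)
        label <- "bpnn"
      }
      rows <- c(rows, list(
        method_row(label, v, "calibration", cal$lai, pc, info),
        method_row(label, v, "validation", val$lai, pv, info)
      ))
    }
  }
  dplyr::bind_rows(rows)
}

#' Relative decline in R-squared versus the nadir view
#'
#' `100 * (r2(0) - r2(vza)) / r2(0)` per method and evaluation set; zero
#' at nadir by construction. Groups whose nadir R^2 is not positive get
#' `NA` (undefined decline).
#'
#' @param profile Result tibble from [evaluate_vza()]; must contain the
#'   nadir (vza 0) rows.
#' @return The profile with an added `decline_pct` column.
#' @export
decline_vs_nadir <- function(profile) {
  if (!any(profile$vza == 0)) stop("profile lacks a nadir (vza = 0) result", call. = FALSE)
  dplyr::mutate(
    dplyr::group_by(profile, .data$method, .data$set),
    decline_pct = {
      r0 <- .data$r2[.data$vza == 0][1]
      if (is.na(r0) || r0 <= 0) NA_real_ else 100 * (r0 - .data$r2) / r0
    }
  ) |> dplyr::ungroup()
}

#' Relative improvement of one method over another
#'
#' `100 * (a - b) / b`, comparing R^2 values at the same angle and
#' evaluation set. Accepts plain numbers or one-row result tibbles from
#' [evaluate_vza()] (whose `vza` and `set` must match).
#'
#' @param a,b R^2 values (or one-row result tibbles).
#' @return Percent improvement of `a` over `b`; `NA` when `b <= 0`.
#' @export
#' @examples
#' relative_improvement(0.83, 0.75)
relative_improvement <- function(a, b) {
  pick <- function(z) if (is.data.frame(z)) z$r2[1] else as.numeric(z)
  if (is.data.frame(a) && is.data.frame(b)) {
    if (a$vza[1] != b$vza[1] || a$set[1] != b$set[1]) {
      stop("results compare different angles or sets", call. = FALSE)
    }
  }
  av <- pick(a); bv <- pick(b)
  if (is.na(bv) || bv <= 0) return(NA_real_)
  100 * (av - bv) / bv
}
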