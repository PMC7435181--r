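## Exhaustive two-band index optimization ---------------------------------
##
## For an index form (ND, SR, DVI) and every ordered wavelength pair
## (lambda1, lambda2) on the search grid, the index is regressed against
## LAI by ordinary least squares and the coefficient of determination is
## stored as a square surface. For simple regression R^2 equals the squared
## Pearson correlation, which is what the vectorized path computes; tests
## pin it to the naive per-cell lm() loop.

#' Two-band index value
#'
#' The three index forms searched exhaustively: normalized difference
#' `ND = (r1 - r2) / (r1 + r2)`, simple ratio `SR = r1 / r2` and
#' difference `DVI = r1 - r2`.
#'
#' @param index_type One of "ND", "SR", "DVI".
#' @param r1,r2 Reflectance at lambda1 and lambda2 (vectorized).
#' @return Numeric vector; undefined values (zero denominators) are `NA`.
#' @export
two_band_index <- function(index_type, r1, r2) {
  index_type <- match.arg(index_type, c("ND", "SR", "DVI"))
  val <- switch(index_type,
                ND  = (r1 - r2) / (r1 + r2),
                SR  = r1 / r2,
                DVI = r1 - r2)
  val[!is.finite(val)] <- NA_real_
  val
}

#' R-squared surface over all two-band combinations
#'
#' Computes, for every ordered pair (lambda1, lambda2) on the search grid,
#' the R^2 of the ordinary least squares fit `LAI ~ index(lambda1,
#' lambda2)` on the calibration samples. Cells whose index is constant or
#' has fewer than 3 defined samples are stored as `NA`; the diagonal is
#' `NA` for all three forms (the index there is constant). A constant LAI
#' vector yields an all-zero surface with a warning.
#'
#' @param data A spectra tibble with an `lai` column (a single angle).
#' @param index_type One of "ND", "SR", "DVI".
#' @param step Search step in nm; must pick a subset of the stored grid
#'   (default 1).
#' @param partition Optional partition from [make_partition()]; when
#'   given, only the calibration ("train") samples enter the fits.
#' @return An object of class `r2_surface`: list with `index_type`, `vza`,
#'   `wavelengths`, `r2` (square matrix), `n_used` (samples per cell) and
#'   `n_cal`.
#' @export
#' @examples
#' d <- generate_canopy(canopy_config(n_samples = 40), vzas = 0)
#' s <- r2_surface(d, "DVI", step = 25)
#' select_optimum(s)
r2_surface <- function(data, index_type, step = 1, partition = NULL) {
  index_type <- match.arg(index_type, c("ND", "SR", "DVI"))
  if (!is.null(partition)) data <- partition_subset(data, partition, "train")
  if (!"lai" %in% names(data)) stop("data has no lai column", call. = FALSE)
  x <- spectra_matrix(data)
  y <- data$lai
  n <- length(y)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  wl_all <- as.numeric(colnames(x))
  keep <- (wl_all - wl_all[1]) %% step == 0
  wl <- wl_all[keep]
  x <- x[, keep, drop = FALSE]
  b <- length(wl)
  vza <- if ("vza" %in% names(data)) unique(data$vza) else NA_real_
  if (length(vza) != 1) stop("data mixes several VZAs; filter to one angle", call. = FALSE)

  r2 <- matrix(NA_real_, b, b, dimnames = list(wl, wl))
  n_used <- matrix(0L, b, b, dimnames = list(wl, wl))
  degenerate_y <- isTRUE(all.equal(var(y), 0)) || var(y) == 0
  if (degenerate_y) {
    warning("LAI is constant; all surface cells set to R^2 = 0", call. = FALSE)
  }
  for (i in seq_len(b)) {
    r1 <- x[, i]
    idx <- switch(index_type,
                  ND  = (r1 - x) / (r1 + x),
                  SR  = r1 / x,
                  DVI = r1 - x)
    idx[!is.finite(idx)] <- NA_real_
    nv <- colSums(!is.na(idx))
    if (degenerate_y) {
      row <- ifelse(nv >= 3, 0, NA_real_)
    } else {
      cc <- suppressWarnings(as.vector(cor(idx, y, use = "pairwise.complete.obs")))
      row <- cc^2
      row[nv < 3] <- NA_real_
    }
    r2[i, ] <- row
    n_used[i, ] <- as.integer(nv)
  }
  structure(list(index_type = index_type, vza = vza, wavelengths = wl,
                 r2 = r2, n_used = n_used, n_cal = n),
            class = "r2_surface")
}

#' @export
print.r2_surface <- function(x, ...) {
  cat(sprintf("<r2_surface> %s, vza %s deg, %d x %d bands (%g-%g nm), n = %d\n",
              x$index_type, format(x$vza), length(x$wavelengths),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$n_cal))
  invisible(x)
}

#' Tidy a two-band R-squared surface into long format
#'
#' @param x An `r2_surface`.
#' @param drop_na Drop undefined cells (default TRUE).
#' @param ... Unused.
#' @return Tibble with columns `lambda1`, `lambda2`, `r2`.
#' @method tidy r2_surface
#' @export
tidy.r2_surface <- function(x, drop_na = TRUE, ...) {
  out <- tibble::tibble(
    lambda1 = rep(x$wavelengths, times = length(x$wavelengths)),
    lambda2 = rep(x$wavelengths, each = length(x$wavelengths)),
    r2 = as.vector(x$r2)
  )
  if (drop_na) out <- out[!is.na(out$r2), ]
  out
}

#' Best wavelength pair of a surface
#'
#' Returns the argmax cell; exact ties are broken by the smallest lambda1,
#' then the smallest lambda2. When `data` is supplied the linear model
#' `LAI = slope * index + intercept` is refit at the winning pair.
#'
#' @param surface An `r2_surface`.
#' @param data Optional spectra tibble (with `lai`) for the slope/intercept
#'   refit.
#' @param partition Optional partition; calibration subset used for the
#'   refit.
#' @return One-row tibble: `index_type`, `vza`, `lambda1`, `lambda2`,
#'   `r2`, `slope`, `intercept`, `n`.
#' @export
select_optimum <- function(surface, data = NULL, partition = NULL) {
  r2 <- surface$r2
  if (all(is.na(r2))) stop("surface has no defined cells", call. = FALSE)
  mx <- max(r2, na.rm = TRUE)
  cand <- which(r2 == mx, arr.ind = TRUE)
  wl <- surface$wavelengths
  ord <- order(wl[cand[, 1]], wl[cand[, 2]])
  best <- cand[ord[1], ]
  l1 <- wl[best[1]]; l2 <- wl[best[2]]
  slope <- intercept <- NA_real_
  n <- surface$n_used[best[1], best[2]]
  if (!is.null(data)) {
    if (!is.null(partition)) data <- partition_subset(data, partition, "train")
    idx <- two_band_index(surface$index_type, band_at(data, l1), band_at(data, l2))
    ok <- is.finite(idx) & is.finite(data$lai)
    fit <- lm(data$lai[ok] ~ idx[ok])
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    n <- sum(ok)
  }
  tibble::tibble(index_type = surface$index_type, vza = surface$vza,
                 lambda1 = l1, lambda2 = l2, r2 = mx,
                 slope = slope, intercept = intercept, n = as.integer(n))
}

#' Export a surface as a long-format CSV
#'
#' Writes `lambda1,lambda2,r2` rows (undefined cells omitted), ready for
#' contour plotting.
#'
#' @param surface An `r2_surface`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
export_surface <- function(surface, path) {
  readr::write_csv(tidy.r2_surface(surface), path, progress = FALSE)
  invisible(path)
}

#' Read a surface written by [export_surface()]
#'
#' @param path CSV path.
#' @param index_type,vza Metadata to attach (not stored in the CSV).
#' @return An `r2_surface` (with `n_used` unknown, set to `NA`).
#' @export
read_surface <- function(path, index_type = "ND", vza = NA_real_) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  wl <- sort(unique(c(df$lambda1, df$lambda2)))
  b <- length(wl)
  r2 <- matrix(NA_real_, b, b, dimnames = list(wl, wl))
  r2[cbind(match(df$lambda1, wl), match(df$lambda2, wl))] <- df$r2
  structure(list(index_type = index_type, vza = vza, wavelengths = wl,
                 r2 = r2, n_used = matrix(NA_integer_, b, b), n_cal = NA_integer_),
            class = "r2_surface")
}
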