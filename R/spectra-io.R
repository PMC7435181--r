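## Spectra tables ---------------------------------------------------------
##
## A spectra table is an ordinary tibble with one row per sample:
##   sample_id  chr   sample identifier
##   vza        dbl   signed view zenith angle (deg; negative = backscatter)
##   lai        dbl   leaf area index (present once aligned with LAI data)
##   "400" ...  dbl   reflectance columns named by band center (nm)
## Multi-angle data are stacked (one block of rows per VZA). All wavelength
## handling goes through the helpers below so the column naming convention
## lives in exactly one place.

#' Canonical analysis wavelength grid
#'
#' The analysis grid used throughout the package: 400-900 nm at a 1-nm step
#' (501 bands). Instrument-resolution spectra are interpolated onto it with
#' [resample_spectra()].
#'
#' @return Numeric vector of band centers in nm.
#' @export
#' @examples
#' length(canonical_grid())
canonical_grid <- function() {
  seq(400, 900, by = 1)
}

#' Wavelengths stored in a spectra table
#'
#' @param data A spectra tibble (see [read_dataset()]).
#' @return Numeric vector of band centers (nm), in column order.
#' @export
spectra_wavelengths <- function(data) {
  nm <- names(data)
  wl <- suppressWarnings(as.numeric(nm))
  sort(wl[!is.na(wl)])
}

#' Extract the reflectance matrix from a spectra table
#'
#' @param data A spectra tibble.
#' @return Numeric matrix (samples x bands); rownames are sample ids,
#'   colnames are wavelengths in nm.
#' @export
spectra_matrix <- function(data) {
  wl <- spectra_wavelengths(data)
  if (length(wl) == 0) stop("no wavelength columns found", call. = FALSE)
  m <- as.matrix(data[as.character(wl)])
  storage.mode(m) <- "double"
  rownames(m) <- data$sample_id
  colnames(m) <- as.character(wl)
  m
}

check_wavelength_grid <- function(wl) {
  if (any(diff(wl) <= 0)) stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (any(wl < 325 | wl > 1075)) {
    stop("wavelengths outside the supported 325-1075 nm range", call. = FALSE)
  }
  invisible(wl)
}

vza_from_filename <- function(path) {
  m <- regmatches(basename(path), regexpr("vza[+-]?[0-9]+", basename(path)))
  if (length(m) == 0) return(NA_real_)
  as.numeric(sub("vza", "", m))
}

read_numeric_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(sample_id = readr::col_character(),
                                                .default = readr::col_character()))
  df
}

parse_numeric_cols <- function(df, cols, path) {
  for (cn in cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "NA")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in %s at row %d, column '%s'",
                   df[[cn]][bad[1]], path, bad[1], cn), call. = FALSE)
    }
    df[[cn]] <- v
  }
  df
}

#' Read a spectra CSV
#'
#' The expected dialect is comma-separated UTF-8 with a header row
#' `sample_id,400,401,...,900`; one file per view zenith angle, with the
#' angle encoded in the filename (e.g. `spectra_vza-60.csv`).
#'
#' @param path Path to the spectra CSV.
#' @param vza Signed view zenith angle in degrees. Defaults to the value
#'   parsed from the filename (`vza<signed angle>`); `NA` if absent.
#' @return A spectra tibble with columns `sample_id`, `vza` and one column
#'   per wavelength.
#' @export
read_spectra <- function(path, vza = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read_numeric_csv(path)
  if (!"sample_id" %in% names(df)) {
    stop(sprintf("spectra file %s lacks a sample_id column", path), call. = FALSE)
  }
  wl_cols <- setdiff(names(df), "sample_id")
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (anyNA(wl)) {
    stop(sprintf("spectra header of %s contains non-wavelength columns: %s",
                 path, paste(wl_cols[is.na(wl)], collapse = ", ")), call. = FALSE)
  }
  check_wavelength_grid(wl)
  df <- parse_numeric_cols(df, wl_cols, path)
  vza <- vza %||% vza_from_filename(path)
  tibble::as_tibble(
    c(list(sample_id = df$sample_id, vza = rep(as.numeric(vza), nrow(df))),
      df[wl_cols])
  )
}

#' Read a per-sample LAI CSV
#'
#' @param path Path to a CSV with header `sample_id,lai`.
#' @return Tibble with columns `sample_id` and `lai`.
#' @export
read_lai <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- read_numeric_csv(path)
  if (!all(c("sample_id", "lai") %in% names(df))) {
    stop(sprintf("LAI file %s must have columns sample_id,lai", path), call. = FALSE)
  }
  df <- parse_numeric_cols(df, "lai", path)
  if (any(df$lai <= 0, na.rm = TRUE)) {
    stop("LAI values must be strictly positive", call. = FALSE)
  }
  tibble::tibble(sample_id = df$sample_id, lai = df$lai)
}

#' Read and align a spectra file with its LAI file
#'
#' Rows are matched by `sample_id` and returned in the LAI file's order.
#' A sample present in one file but not the other is an alignment error.
#'
#' @inheritParams read_spectra
#' @param spectra_path Path to the spectra CSV.
#' @param lai_path Path to the LAI CSV.
#' @return A spectra tibble with columns `sample_id`, `vza`, `lai` and one
#'   column per wavelength.
#' @export
read_dataset <- function(spectra_path, lai_path, vza = NULL) {
  sp <- read_spectra(spectra_path, vza = vza)
  la <- read_lai(lai_path)
  extra_sp <- setdiff(sp$sample_id, la$sample_id)
  extra_la <- setdiff(la$sample_id, sp$sample_id)
  if (length(extra_sp) > 0 || length(extra_la) > 0) {
    stop(sprintf("sample ids do not align: %s",
                 paste(c(extra_sp, extra_la), collapse = ", ")), call. = FALSE)
  }
  sp <- sp[match(la$sample_id, sp$sample_id), ]
  out <- dplyr::bind_cols(sp[c("sample_id", "vza")],
                          tibble::tibble(lai = la$lai),
                          sp[as.character(spectra_wavelengths(sp))])
  tibble::as_tibble(out)
}

#' Write a spectra table (and optionally its LAI) to CSV
#'
#' Inverse of [read_dataset()]: writes one spectra file per VZA present in
#' `data` (suffix `vza<signed angle>` inserted before the extension when
#' several angles are stacked), plus an LAI file when `lai_path` is given.
#'
#' @param data A spectra tibble, optionally with an `lai` column.
#' @param spectra_path Output path for the spectra CSV (basename used as a
#'   template when `data` holds several VZAs).
#' @param lai_path Optional output path for the `sample_id,lai` CSV.
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(data, spectra_path, lai_path = NULL) {
  wl <- as.character(spectra_wavelengths(data))
  vzas <- unique(data$vza)
  paths <- character(0)
  for (v in vzas) {
    block <- data[data$vza == v | (is.na(v) & is.na(data$vza)), ]
    p <- spectra_path
    if (length(vzas) > 1) {
      p <- sub("(\\.[^.]+)$", sprintf("_vza%+d\\1", as.integer(v)), spectra_path)
    }
    readr::write_csv(block[c("sample_id", wl)], p, progress = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(lai_path)) {
    if (!"lai" %in% names(data)) stop("data has no lai column to write", call. = FALSE)
    first <- data[data$vza == vzas[1], c("sample_id", "lai")]
    readr::write_csv(first, lai_path, progress = FALSE)
    paths <- c(paths, lai_path)
  }
  invisible(paths)
}

#' Resample spectra onto a target wavelength grid
#'
#' Piecewise-linear interpolation per sample. The target grid must lie
#' within the source grid's range (no extrapolation).
#'
#' @param data A spectra tibble.
#' @param target Numeric vector of target band centers (nm); defaults to
#'   the canonical 400-900 nm, 1-nm grid.
#' @return A spectra tibble on the target grid.
#' @export
resample_spectra <- function(data, target = canonical_grid()) {
  src <- spectra_wavelengths(data)
  check_wavelength_grid(target)
  if (min(target) < min(src) || max(target) > max(src)) {
    stop(sprintf("target grid [%g, %g] extends beyond source range [%g, %g]",
                 min(target), max(target), min(src), max(src)), call. = FALSE)
  }
  m <- spectra_matrix(data)
  out <- t(apply(m, 1, function(row) approx(src, row, xout = target)$y))
  colnames(out) <- as.character(target)
  meta <- data[intersect(c("sample_id", "vza", "lai"), names(data))]
  dplyr::bind_cols(meta, tibble::as_tibble(out))
}

#' Reflectance at (nearest) wavelength
#'
#' Resolves a requested wavelength to the nearest stored band. On the
#' canonical 1-nm grid this is exact; a nearest band more than 2 nm away
#' is an error.
#'
#' @param data A spectra tibble.
#' @param wavelength Requested band center (nm).
#' @return Numeric vector of per-sample reflectance at the resolved band.
#' @export
band_at <- function(data, wavelength) {
  wl <- spectra_wavelengths(data)
  i <- which.min(abs(wl - wavelength))
  if (abs(wl[i] - wavelength) > 2) {
    stop(sprintf("no band within 2 nm of %g nm (grid spans %g-%g nm)",
                 wavelength, min(wl), max(wl)), call. = FALSE)
  }
  data[[as.character(wl[i])]]
}

#' Random calibration/validation split with cross-validation folds
#'
#' Draws a uniform random split without replacement and assigns the
#' calibration samples to `k` near-equal cross-validation folds. The
#' same partition is intended to be reused across all view zenith angles,
#' since the physical samples are shared between angles.
#'
#' @param data A spectra tibble (only `sample_id` is used; for stacked
#'   multi-angle tables the distinct ids are taken).
#' @param n_train Number of calibration samples (default 176).
#' @param k Number of cross-validation folds (default 5).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return Tibble with columns `sample_id`, `role` ("train"/"test") and
#'   `fold` (1..k for training samples, NA for test samples).
#' @export
make_partition <- function(data, n_train = 176, k = 5, seed = 1) {
  ids <- unique(data$sample_id)
  n <- length(ids)
  if (n_train >= n) {
    stop(sprintf("n_train (%d) must be smaller than the sample count (%d)",
                 n_train, n), call. = FALSE)
  }
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  with_seed(seed, {
    train <- sample(ids, n_train)
    folds <- sort(rep_len(seq_len(k), n_train))[sample.int(n_train)]
    tibble::tibble(
      sample_id = ids,
      role = ifelse(ids %in% train, "train", "test"),
      fold = as.integer(folds[match(ids, train)])
    )
  })
}

## Subset a spectra table to one role of a partition, preserving its order.
partition_subset <- function(data, partition, role) {
  keep <- partition$sample_id[partition$role == role]
  data[data$sample_id %in% keep, ]
}

## Per-sample fold labels for the training subset of `data`.
partition_folds <- function(data, partition) {
  f <- partition$fold[match(data$sample_id, partition$sample_id)]
  if (anyNA(f)) stop("fold lookup failed: data contains non-training samples", call. = FALSE)
  f
}
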