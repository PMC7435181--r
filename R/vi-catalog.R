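## Published narrow-band vegetation indices -------------------------------
##
## The 21 published VIs compared by the pipeline, grouped by the number of
## distinct bands entering each formula (8 two-band, 8 three-band, 5
## four-band). Formulas are implemented exactly as commonly tabulated for
## LAI work (including the printed constant structure of EVI-1, MCARI2 and
## MTVI2), so downstream comparisons are self-consistent. Reference
## wavelengths resolve by the nearest-band rule of [band_at()].

#' Reference wavelengths for symbolic VI bands
#'
#' CIred-edge and MTCI are tabulated with symbolic R_NIR / R_red-edge /
#' R_red bands; this config fixes them (defaults 790 / 720 / 670 nm,
#' following the source publications' conventions).
#'
#' @param nir,red_edge,red Band centers in nm.
#' @return Named list used by [compute_vi()].
#' @export
vi_band_config <- function(nir = 790, red_edge = 720, red = 670) {
  list(nir = nir, red_edge = red_edge, red = red)
}

#' Catalog of published vegetation indices
#'
#' @return Tibble with columns `name`, `long_name`, `n_bands` (2, 3 or 4)
#'   and `wavelengths` (list-column of the fixed band centers used; the
#'   symbolic bands of CIred-edge and MTCI are listed at their
#'   [vi_band_config()] defaults, and MSAVI2's band regions by their
#'   endpoints).
#' @export
#' @examples
#' dplyr::count(vi_catalog(), n_bands)
vi_catalog <- function() {
  tibble::tribble(
    ~name,          ~long_name,                                                ~n_bands, ~wavelengths,
    "NDVI",         "Normalized Difference Vegetation Index (810, 680)",        2L, c(810, 680),
    "RVI",          "Ratio Vegetation Index (810, 680)",                        2L, c(810, 680),
    "DVI",          "Difference Vegetation Index (810, 680)",                   2L, c(810, 680),
    "OSAVI",        "Optimized Soil Adjusted Vegetation Index",                 2L, c(800, 670),
    "PRI",          "Photochemical Reflectance Index",                          2L, c(570, 531),
    "WDRVI",        "Wide Dynamic Range Vegetation Index",                      2L, c(800, 670),
    "VOG",          "Vogelmann Index",                                          2L, c(740, 720),
    "CIred-edge",   "Red-edge Chlorophyll Index",                               2L, c(790, 720),
    "mND705",       "Modified Red-edge Normalized Difference Vegetation Index", 3L, c(750, 705, 445),
    "mSR705",       "Modified Red-edge Simple Ratio Index",                     3L, c(750, 705, 445),
    "EVI-1",        "Enhanced Vegetation Index",                                3L, c(860, 645, 470),
    "MCARI2",       "Modified Chlorophyll Absorption in Reflectance Index",     3L, c(800, 670, 550),
    "MTVI2",        "Modified Triangular Vegetation Index",                     3L, c(800, 670, 550),
    "SIPI",         "Structure Insensitive Pigment Index",                      3L, c(800, 680, 445),
    "MTCI",         "MERIS Terrestrial Chlorophyll Index",                      3L, c(790, 720, 670),
    "DDn",          "New Double Difference Index",                              3L, c(710, 660, 760),
    "TCARI/OSAVI",  "TCARI to OSAVI ratio",                                     4L, c(700, 670, 550, 800),
    "MSAVI2",       "Modified Soil-Adjusted Vegetation Index",                  4L, c(760, 900, 630, 690),
    "REP",          "Red-edge Position (linear interpolation)",                 4L, c(700, 670, 780, 740),
    "DD",           "Double Difference Index",                                  4L, c(749, 720, 701, 672),
    "VOG-2",        "Vogelmann Index 2",                                        4L, c(734, 747, 715, 726)
  )
}

## Mean reflectance over a closed wavelength interval (used by MSAVI2).
region_mean <- function(data, from, to) {
  wl <- spectra_wavelengths(data)
  cols <- as.character(wl[wl >= from & wl <= to])
  if (length(cols) == 0) stop(sprintf("no bands in %g-%g nm", from, to), call. = FALSE)
  rowMeans(as.matrix(data[cols]))
}

#' Compute one vegetation index per sample
#'
#' Applies the published formula at the catalog's fixed wavelengths via
#' the nearest-band rule. Undefined values (zero denominators, negative
#' square-root arguments in MCARI2/MTVI2) become `NA` for the affected
#' samples rather than errors; downstream fits drop them and record the
#' count.
#'
#' @param data A spectra tibble.
#' @param name Index name from [vi_catalog()].
#' @param config A [vi_band_config()] fixing the symbolic bands of
#'   CIred-edge and MTCI.
#' @return Numeric vector, one value per sample (`NA` where undefined).
#' @export
#' @examples
#' d <- generate_canopy(canopy_config(n_samples = 5), vzas = 0)
#' compute_vi(d, "NDVI")
compute_vi <- function(data, name, config = vi_band_config()) {
  if (!name %in% vi_catalog()$name) {
    stop(sprintf("unknown vegetation index '%s'", name), call. = FALSE)
  }
  R <- function(w) band_at(data, w)
  osavi <- function() (1 + 0.16) * (R(800) - R(670)) / (R(800) + R(670) + 0.16)
  val <- switch(
    name,
    "NDVI"   = (R(810) - R(680)) / (R(810) + R(680)),
    "RVI"    = R(810) / R(680),
    "DVI"    = R(810) - R(680),
    "OSAVI"  = osavi(),
    "PRI"    = (R(570) - R(531)) / (R(570) + R(531)),
    "WDRVI"  = (0.2 * R(800) - R(670)) / (0.2 * R(800) + R(670)) + (1 - 0.2) / (1 + 0.2),
    "VOG"    = R(740) / R(720),
    "CIred-edge" = R(config$nir) / R(config$red_edge) - 1,
    "mND705" = (R(750) - R(705)) / (R(750) + R(705) - 2 * R(445)),
    "mSR705" = (R(750) - R(445)) / (R(705) - R(445)),
    "EVI-1"  = 2.5 * (R(860) - R(645)) / (1 + R(860) + 6 * R(645) - 7.5 * R(470)),
    "MCARI2" = (1.5 * (2.5 * (R(800) - R(670)) - 1.3 * (R(800) - R(550)))) /
               (sqrt((2 * R(800) + 1)^2 - 6 * R(800) + 5 * sqrt(R(670))) - 0.5),
    "MTVI2"  = 1.5 * (1.2 * (R(800) - R(550)) - 2.5 * (R(670) - R(550))) /
               sqrt((2 * R(800) + 1)^2 - (6 * R(800) - 5 * sqrt(R(670))) - 0.5),
    "SIPI"   = (R(800) - R(445)) / (R(800) - R(680)),
    "MTCI"   = (R(config$nir) - R(config$red_edge)) / (R(config$red_edge) - R(config$red)),
    "DDn"    = 2 * R(710) - R(660) - R(760),
    "TCARI/OSAVI" =
      3 * ((R(700) - R(670)) - 0.2 * (R(700) - R(550)) * (R(700) / R(670))) / osavi(),
    "MSAVI2" = {
      nir <- region_mean(data, 760, 900); red <- region_mean(data, 630, 690)
      0.5 * (2 * nir + 1 - sqrt((2 * nir + 1)^2 - 8 * (nir - red)))
    },
    "REP"    = 700 + 40 * ((R(670) + R(780)) / 2 - R(700)) / (R(740) - R(700)),
    "DD"     = (R(749) - R(720)) - (R(701) - R(672)),
    "VOG-2"  = (R(734) - R(747)) / (R(715) + R(726))
  )
  val <- suppressWarnings(as.numeric(val))
  val[!is.finite(val)] <- NA_real_
  val
}

#' Compute several vegetation indices as a samples-by-indices table
#'
#' @param data A spectra tibble.
#' @param names Character vector of index names (default: whole catalog).
#'   Column order follows this argument.
#' @param config A [vi_band_config()].
#' @return Tibble with `sample_id` plus one column per requested index;
#'   undefined values propagate as `NA`.
#' @export
compute_vi_matrix <- function(data, names = vi_catalog()$name,
                              config = vi_band_config()) {
  out <- tibble::tibble(sample_id = data$sample_id)
  for (nm in names) out[[nm]] <- compute_vi(data, nm, config)
  out
}
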