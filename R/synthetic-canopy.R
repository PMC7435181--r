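## Synthetic multi-angular canopy reflectance -----------------------------
##
## A deliberately simple two-stream mixture: canopy reflectance is a convex
## combination of a parametric green-leaf spectrum and a linear soil line,
## weighted by the Beer-Lambert gap fraction exp(-k * omega * LAI / cos vza).
## LAI enters the signal twice: through the gap fraction (saturating) and
## through chlorophyll (correlated with LAI), which deepens the red/blue
## absorption troughs and pushes the red-edge inflection to longer
## wavelengths. A signed-angle brightness factor gives back/forward
## asymmetry and multiplicative noise grows with |vza|, so estimation
## quality degrades away from nadir by construction.

#' Leaf optical parameters for the synthetic generator
#'
#' Parametric stand-in for green-leaf optics: an NIR plateau joined to a
#' visible baseline by a sigmoid red edge, with Gaussian chlorophyll
#' absorption troughs at ~450 and ~670 nm and a green reflectance peak at
#' ~550 nm. Trough depth saturates with chlorophyll content (cab) and the
#' red-edge inflection shifts to longer wavelengths as cab grows.
#'
#' @param nir_plateau NIR plateau reflectance.
#' @param vis_base Visible baseline reflectance (troughs removed).
#' @param green_peak,green_width Height and Gaussian width (nm) of the
#'   550-nm green peak.
#' @param blue_center,blue_width Center and width (nm) of the blue trough.
#' @param red_center,red_width Center and width (nm) of the red trough.
#' @param trough_max Maximum trough depth (reflectance units).
#' @param trough_half_sat cab value (ug cm-2) at which trough depth reaches
#'   half of `trough_max`.
#' @param red_edge_center Red-edge inflection (nm) at cab = 0.
#' @param red_edge_per_cab Inflection shift per unit cab (nm per ug cm-2).
#' @param red_edge_width Sigmoid width of the red edge (nm).
#' @return A list of class `leaf_params`.
#' @export
leaf_params <- function(nir_plateau = 0.48, vis_base = 0.12,
                        green_peak = 0.05, green_width = 35,
                        blue_center = 450, blue_width = 25,
                        red_center = 670, red_width = 30,
                        trough_max = 0.10, trough_half_sat = 25,
                        red_edge_center = 700, red_edge_per_cab = 0.6,
                        red_edge_width = 8) {
  structure(as.list(environment()), class = "leaf_params")
}

#' Configuration of the synthetic canopy generator
#'
#' Defaults reproduce the statistical structure the analysis assumes:
#' 221 samples with LAI drawn from a truncated normal with mean 4.90 and
#' SD 1.63 on \[1.25, 8.76\], observed at 13 view zenith angles from -60 to
#' +60 degrees, with a red-edge reflectance signal that covaries with LAI,
#' a brighter backscatter direction, and noise that grows with |vza|.
#'
#' @param n_samples Number of samples.
#' @param lai_mean,lai_sd,lai_min,lai_max Truncated-normal LAI distribution
#'   (m2 leaf per m2 ground).
#' @param cab_base,cab_per_lai,cab_sd Chlorophyll-LAI coupling:
#'   cab = cab_base + cab_per_lai * LAI + N(0, cab_sd), floored at 0
#'   (ug cm-2).
#' @param k_ext Beer-Lambert extinction coefficient.
#' @param clumping Clumping index Omega in (0, 1].
#' @param soil_intercept,soil_slope Soil line: reflectance at 400 nm and
#'   slope per nm.
#' @param soil_brightness_sd SD of the per-sample soil brightness factor
#'   (mean 1).
#' @param leaf_nir_sd SD of the per-sample NIR plateau factor (mean 1);
#'   emulates leaf structural/water variability, which grows with
#'   wavelength across the NIR, so distant NIR reference bands carry
#'   sample-specific nuisance that two nearby red-edge bands share and
#'   cancel.
#' @param asym_h Back/forward brightness asymmetry; the vegetation term is
#'   scaled by `1 - asym_h * vza / 60`, so with `asym_h > 0` the
#'   backscattering direction (negative vza) is brighter.
#' @param noise_sd0 Observation-noise SD at nadir, as a fraction of each
#'   sample's mean reflectance (noise is Gaussian, scaled by the sample's
#'   overall brightness and spectrally flat).
#' @param noise_gamma Angular noise growth: SD at angle vza is
#'   `noise_sd0 * (1 + noise_gamma * |vza| / 60)`.
#' @param leaf A [leaf_params()] object.
#' @param grid Wavelength grid for generated spectra (nm).
#' @param seed Integer seed making the whole dataset reproducible.
#' @return A list of class `canopy_config`.
#' @export
#' @examples
#' cfg <- canopy_config(n_samples = 20, seed = 7)
#' d <- generate_canopy(cfg, vzas = c(-60, 0, 60))
#' dplyr::count(d, vza)
canopy_config <- function(n_samples = 221,
                          lai_mean = 4.90, lai_sd = 1.63,
                          lai_min = 1.25, lai_max = 8.76,
                          cab_base = 20, cab_per_lai = 5, cab_sd = 2,
                          k_ext = 0.5, clumping = 0.9,
                          soil_intercept = 0.10, soil_slope = 4e-4,
                          soil_brightness_sd = 0.15,
                          leaf_nir_sd = 0.06,
                          asym_h = 0.08,
                          noise_sd0 = 0.02, noise_gamma = 1.5,
                          leaf = leaf_params(),
                          grid = canonical_grid(),
                          seed = 1) {
  cfg <- structure(as.list(environment()), class = "canopy_config")
  if (cfg$lai_min <= 0) stop("lai_min must be > 0", call. = FALSE)
  if (cfg$lai_min >= cfg$lai_max) stop("lai_min must be below lai_max", call. = FALSE)
  if (cfg$k_ext <= 0) stop("k_ext must be > 0", call. = FALSE)
  if (cfg$clumping <= 0 || cfg$clumping > 1) stop("clumping must be in (0, 1]", call. = FALSE)
  if (cfg$noise_sd0 < 0 || cfg$noise_gamma < 0) stop("noise parameters must be >= 0", call. = FALSE)
  check_wavelength_grid(cfg$grid)
  cfg
}

#' Draw LAI values from the configured truncated normal
#'
#' Inverse-CDF sampling of a normal truncated to \[lai_min, lai_max\];
#' deterministic given `seed` (pass `seed = NULL` to consume the current
#' RNG stream instead).
#'
#' @param n Number of draws (defaults to `config$n_samples`).
#' @param config A [canopy_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return Numeric vector of LAI values.
#' @export
sample_lai <- function(n = NULL, config = canopy_config(), seed = config$seed) {
  n <- n %||% config$n_samples
  draw <- function() {
    if (config$lai_sd == 0) return(rep(config$lai_mean, n))
    lo <- pnorm(config$lai_min, config$lai_mean, config$lai_sd)
    hi <- pnorm(config$lai_max, config$lai_mean, config$lai_sd)
    qnorm(runif(n, lo, hi), config$lai_mean, config$lai_sd)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Gap fraction along a view direction
#'
#' Beer-Lambert probability that the soil background is visible:
#' `exp(-k_ext * clumping * lai / cos(vza))`.
#'
#' @param lai Leaf area index (vectorized).
#' @param vza View zenith angle in degrees, |vza| < 90.
#' @param config A [canopy_config()] supplying `k_ext` and `clumping`.
#' @return Gap fraction in (0, 1].
#' @export
gap_fraction <- function(lai, vza, config = canopy_config()) {
  if (any(abs(vza) >= 90)) stop("|vza| must be below 90 degrees", call. = FALSE)
  exp(-config$k_ext * config$clumping * lai / cos(vza * pi / 180))
}

#' Parametric leaf reflectance spectrum
#'
#' @param cab Chlorophyll content (ug cm-2); negative values are clamped
#'   to 0. May be a vector (one spectrum per value).
#' @param params A [leaf_params()] object.
#' @param grid Wavelength grid (nm).
#' @param nir_scale Per-sample NIR plateau factor (leaf structural/water
#'   variability); scalar or one value per `cab`. Its effect ramps up
#'   linearly from 700 to 900 nm, so two nearby red-edge bands share (and
#'   a difference cancels) most of it, while a distant NIR reference band
#'   does not.
#' @return For scalar `cab` a numeric vector over `grid`; for vector `cab`
#'   a matrix (length(cab) x length(grid)). Values clipped to
#'   \[0.01, 0.99\].
#' @export
leaf_reflectance <- function(cab, params = leaf_params(), grid = canonical_grid(),
                             nir_scale = 1) {
  cab <- pmax(cab, 0)
  p <- params
  depth <- p$trough_max * cab / (cab + p$trough_half_sat)       # saturating in cab
  gauss <- function(center, width) exp(-(grid - center)^2 / (2 * width^2))
  vis_base <- p$vis_base + p$green_peak * gauss(550, p$green_width)
  # rows = samples, cols = bands
  vis <- matrix(vis_base, nrow = length(cab), ncol = length(grid), byrow = TRUE) -
    outer(depth, gauss(p$blue_center, p$blue_width)) -
    outer(depth, gauss(p$red_center, p$red_width))
  infl <- p$red_edge_center + p$red_edge_per_cab * cab
  s <- 1 / (1 + exp(-outer(-infl, grid, `+`) / p$red_edge_width))
  ramp <- pmin(pmax((grid - 700) / 200, 0), 1)
  plateau <- p$nir_plateau * (1 + outer(rep_len(nir_scale, length(cab)) - 1, ramp))
  r <- (1 - s) * vis + s * plateau
  r <- pmin(pmax(r, 0.01), 0.99)
  if (length(cab) == 1) as.vector(r) else r
}

soil_spectrum <- function(config, grid = config$grid) {
  config$soil_intercept + config$soil_slope * (grid - 400)
}

#' Simulate one canopy reflectance spectrum
#'
#' Mixes the leaf and soil spectra by the gap fraction, applies the
#' signed-angle brightness factor to the vegetation term, and (optionally)
#' Gaussian observation noise scaled to the sample's mean brightness,
#' with an SD that grows with |vza|. Noise draws consume the current RNG
#' stream; seed externally for reproducibility.
#'
#' @param lai Leaf area index (scalar).
#' @param cab Chlorophyll content (ug cm-2).
#' @param vza View zenith angle (degrees).
#' @param config A [canopy_config()].
#' @param soil_bright Per-sample soil brightness factor (default 1).
#' @param nir_scale Per-sample NIR plateau factor (default 1).
#' @param noise Apply observation noise? (default TRUE)
#' @return Reflectance vector over `config$grid`, clipped to \[0, 1\].
#' @export
simulate_canopy <- function(lai, cab, vza, config = canopy_config(),
                            soil_bright = 1, nir_scale = 1, noise = TRUE) {
  g <- gap_fraction(lai, vza, config)
  a <- 1 - config$asym_h * vza / 60
  leaf <- leaf_reflectance(cab, config$leaf, config$grid, nir_scale)
  r <- a * (1 - g) * leaf + g * soil_bright * soil_spectrum(config)
  if (noise && config$noise_sd0 > 0) {
    sdv <- config$noise_sd0 * (1 + config$noise_gamma * abs(vza) / 60)
    r <- r + mean(r) * rnorm(length(r), 0, sdv)
  }
  pmin(pmax(r, 0), 1)
}

#' Generate a multi-angular synthetic dataset
#'
#' Draws the per-sample state (LAI, chlorophyll, soil brightness) once and
#' observes every sample at each requested view zenith angle; only the
#' observation noise differs between angles, mirroring field campaigns in
#' which the same physical plots are measured at all angles.
#'
#' @param config A [canopy_config()].
#' @param vzas View zenith angles (degrees); default the 13 angles
#'   -60, -50, ..., +60.
#' @return A spectra tibble with columns `sample_id`, `vza`, `lai` and one
#'   column per wavelength, stacked over angles; every angle block shares
#'   sample ids and LAI.
#' @export
generate_canopy <- function(config = canopy_config(),
                            vzas = seq(-60, 60, by = 10)) {
  n <- config$n_samples
  grid <- config$grid
  with_seed(config$seed, {
    lai <- sample_lai(n, config, seed = NULL)
    cab <- pmax(config$cab_base + config$cab_per_lai * lai +
                  rnorm(n, 0, config$cab_sd), 0)
    bright <- pmax(rnorm(n, 1, config$soil_brightness_sd), 0.2)
    nir_scale <- pmax(rnorm(n, 1, config$leaf_nir_sd), 0.5)
    ids <- sprintf("S%03d", seq_len(n))
    leaf <- leaf_reflectance(cab, config$leaf, grid, nir_scale)  # n x bands
    soil <- soil_spectrum(config)
    blocks <- lapply(vzas, function(v) {
      g <- gap_fraction(lai, v, config)
      a <- 1 - config$asym_h * v / 60
      r <- a * (1 - g) * leaf + outer(g * bright, soil)
      if (config$noise_sd0 > 0) {
        sdv <- config$noise_sd0 * (1 + config$noise_gamma * abs(v) / 60)
        r <- r + rowMeans(r) * matrix(rnorm(length(r), 0, sdv), nrow = n)
      }
      r <- pmin(pmax(r, 0), 1)
      colnames(r) <- as.character(grid)
      dplyr::bind_cols(
        tibble::tibble(sample_id = ids, vza = v, lai = lai),
        tibble::as_tibble(r)
      )
    })
    dplyr::bind_rows(blocks)
  })
}
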