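# Small in-code fixtures shared across the suite.

# Random reflectance table on an arbitrary grid.
toy_spectra <- function(n = 5, wl = seq(400, 900, by = 50), seed = 1,
                        vza = 0, lai = NULL) {
  set.seed(seed)
  lai <- lai %||% runif(n, 1.25, 8.76)
  m <- matrix(runif(n * length(wl), 0.05, 0.6), n, length(wl),
              dimnames = list(NULL, wl))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("T%02d", seq_len(n)), vza = vza, lai = lai),
    tibble::as_tibble(m)
  )
}

# Flat spectrum (every band equal to r) on the canonical grid, with chosen
# bands overridden; handy for hand-arithmetic index checks.
flat_spectra <- function(r = 0.3, overrides = list(), n = 1) {
  wl <- canonical_grid()
  m <- matrix(r, n, length(wl), dimnames = list(NULL, wl))
  for (w in names(overrides)) m[, w] <- overrides[[w]]
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("F%02d", seq_len(n)), vza = 0,
                   lai = seq_len(n) + 1),
    tibble::as_tibble(m)
  )
}

`%||%` <- rlang::`%||%`
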