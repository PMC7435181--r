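# Independent naive oracles: direct scalar arithmetic on a named
# reflectance vector, written without reference to the package internals.

# r: named numeric vector, names are wavelengths on the canonical grid.
naive_vi <- function(name, r) {
  R <- function(w) unname(r[as.character(w)])
  band_mean <- function(from, to) {
    wl <- as.numeric(names(r))
    mean(r[wl >= from & wl <= to])
  }
  osavi <- (1 + 0.16) * (R(800) - R(670)) / (R(800) + R(670) + 0.16)
  switch(name,
    "NDVI"       = (R(810) - R(680)) / (R(810) + R(680)),
    "RVI"        = R(810) / R(680),
    "DVI"        = R(810) - R(680),
    "OSAVI"      = osavi,
    "PRI"        = (R(570) - R(531)) / (R(570) + R(531)),
    "WDRVI"      = (0.2 * R(800) - R(670)) / (0.2 * R(800) + R(670)) + 0.8 / 1.2,
    "VOG"        = R(740) / R(720),
    "CIred-edge" = R(790) / R(720) - 1,
    "mND705"     = (R(750) - R(705)) / (R(750) + R(705) - 2 * R(445)),
    "mSR705"     = (R(750) - R(445)) / (R(705) - R(445)),
    "EVI-1"      = 2.5 * (R(860) - R(645)) / (1 + R(860) + 6 * R(645) - 7.5 * R(470)),
    "MCARI2"     = (1.5 * (2.5 * (R(800) - R(670)) - 1.3 * (R(800) - R(550)))) /
                   (sqrt((2 * R(800) + 1)^2 - 6 * R(800) + 5 * sqrt(R(670))) - 0.5),
    "MTVI2"      = 1.5 * (1.2 * (R(800) - R(550)) - 2.5 * (R(670) - R(550))) /
                   sqrt((2 * R(800) + 1)^2 - (6 * R(800) - 5 * R(670)^0.5) - 0.5),
    "SIPI"       = (R(800) - R(445)) / (R(800) - R(680)),
    "MTCI"       = (R(790) - R(720)) / (R(720) - R(670)),
    "DDn"        = 2 * R(710) - R(660) - R(760),
    "TCARI/OSAVI" = (3 * ((R(700) - R(670)) - 0.2 * (R(700) - R(550)) * (R(700) / R(670)))) / osavi,
    "MSAVI2"     = {
      nir <- band_mean(760, 900); red <- band_mean(630, 690)
      0.5 * (2 * nir + 1 - sqrt((2 * nir + 1)^2 - 8 * (nir - red)))
    },
    "REP"        = 700 + 40 * ((R(670) + R(780)) / 2 - R(700)) / (R(740) - R(700)),
    "DD"         = (R(749) - R(720)) - (R(701) - R(672)),
    "VOG-2"      = (R(734) - R(747)) / (R(715) + R(726)),
    stop("oracle has no formula for ", name)
  )
}

naive_two_band <- function(type, r1, r2) {
  switch(type, ND = (r1 - r2) / (r1 + r2), SR = r1 / r2, DVI = r1 - r2)
}

naive_r2 <- function(obs, pred) {
  sse <- 0; sst <- 0; m <- sum(obs) / length(obs)
  for (i in seq_along(obs)) {
    sse <- sse + (obs[i] - pred[i])^2
    sst <- sst + (obs[i] - m)^2
  }
  1 - sse / sst
}

naive_rmse <- function(obs, pred) {
  acc <- 0
  for (i in seq_along(obs)) acc <- acc + (pred[i] - obs[i])^2
  sqrt(acc / length(obs))
}

# Per-cell lm() R^2 surface, the brute-force reference for r2_surface().
naive_surface <- function(data, type) {
  m <- spectra_matrix(data)
  wl <- as.numeric(colnames(m))
  y <- data$lai
  b <- length(wl)
  out <- matrix(NA_real_, b, b, dimnames = list(wl, wl))
  for (i in seq_len(b)) {
    for (j in seq_len(b)) {
      idx <- naive_two_band(type, m[, i], m[, j])
      idx[!is.finite(idx)] <- NA
      ok <- !is.na(idx)
      if (sum(ok) < 3 || sd(idx[ok]) == 0) next
      out[i, j] <- summary(lm(y[ok] ~ idx[ok]))$r.squared
    }
  }
  out
}
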