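# Shared fixture builders. Everything is generated in code; no data files.

# Brillouin spectrum with delta-like peaks placed on exact axis channels.
deltaSpectrum <- function(values, axis = seq(2, 35, by = 0.05),
                          modality = "brillouin") {
  iy <- numeric(length(axis))
  for (k in seq_along(values)) {
    i <- which.min(abs(axis - as.numeric(names(values)[k])))
    iy[i] <- values[k]
  }
  spectrum(axis, iy, modality)
}

# Raman spectrum made of Gaussian-ish narrow Lorentzian bands on a known
# polynomial baseline, for preprocessing tests.
lorentzBand <- function(axis, center, fwhm, height) {
  height / (1 + (2 * (axis - center) / fwhm)^2)
}

# A small fully-populated map with one Brillouin and one Raman spectrum per
# pixel, intensities varying per pixel so round-trip identity is meaningful.
tinyMap <- function(nrow = 2, ncol = 2) {
  bAxis <- seq(4, 32, by = 0.5)
  rAxis <- seq(800, 1800, by = 5)
  npix <- nrow * ncol
  b <- t(vapply(seq_len(npix), function(k)
    lorentzBand(bAxis, 6.5 + 0.1 * k, 0.8, 10 + k) +
      lorentzBand(bAxis, 18 + 0.1 * k, 1.2, 30 + k),
    numeric(length(bAxis))))
  r <- t(vapply(seq_len(npix), function(k)
    lorentzBand(rAxis, 965, 12, 5 + k) + lorentzBand(rAxis, 1445, 16, 10),
    numeric(length(rAxis))))
  spectralMap(nrow, ncol, brillouinAxis = bAxis, brillouin = b,
              ramanAxis = rAxis, raman = r, step = 3, origin = c(10, 20))
}

# Feature map with deterministic values for ROI statistics tests.
constantFeatureMap <- function(nrow, ncol, values) {
  feats <- lapply(values, function(v) matrix(v, nrow, ncol))
  new("FeatureMap", features = feats, step = 3, origin = c(0, 0))
}
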