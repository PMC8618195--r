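# Fluorescence baseline removal, reference normalisation and the three
# chemical markers.

test_that("baseline removal annihilates a pure polynomial input", {
  axis <- seq(250, 3700, by = 2)
  u <- (axis - min(axis)) / diff(range(axis))
  base <- 100 + 80 * u - 120 * u^2 + 50 * u^3
  s <- spectrum(axis, base, "raman")
  flat <- removeBaseline(s, order = 5)
  expect_lt(max(abs(intensity(flat))), 1e-6 * max(base))
})

test_that("baseline removal preserves peaks sitting on zero baseline", {
  axis <- seq(250, 3700, by = 1)
  peaks <- lorentzBand(axis, 965, 12, 8) + lorentzBand(axis, 1445, 16, 10) +
    lorentzBand(axis, 2935, 20, 12)
  s <- spectrum(axis, peaks, "raman")
  flat <- removeBaseline(s, order = 5)
  for (ctr in c(965, 1445, 2935)) {
    got <- max(intensity(flat)[abs(axis - ctr) < 5])
    want <- max(peaks[abs(axis - ctr) < 5])
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("baseline removal recovers peak heights on a polynomial background", {
  axis <- seq(250, 3700, by = 1)
  u <- (axis - min(axis)) / diff(range(axis))
  base <- 20 * (0.8 - 0.5 * u + 0.2 * u^2)
  heights <- c(`965` = 8, `1445` = 10, `2935` = 12)
  peaks <- lorentzBand(axis, 965, 12, heights[1]) +
    lorentzBand(axis, 1445, 16, heights[2]) +
    lorentzBand(axis, 2935, 18, heights[3])
  s <- spectrum(axis, base + peaks, "raman")
  flat <- removeBaseline(s, order = 5)
  for (k in seq_along(heights)) {
    ctr <- as.numeric(names(heights)[k])
    got <- max(intensity(flat)[abs(axis - ctr) < 5])
    expect_equal(got, unname(heights[k]), tolerance = 0.05)
  }
})

test_that("reference normalisation pins the 1445 window maximum to 1", {
  axis <- seq(800, 1800, by = 1)
  s <- spectrum(axis, lorentzBand(axis, 1445, 16, 5) +
                  lorentzBand(axis, 965, 12, 3), "raman")
  n1 <- normalizeToReference(s)
  win <- abs(axis - 1445) <= 10
  expect_equal(max(intensity(n1)[win]), 1)
  expect_equal(intensity(n1), intensity(s) / max(intensity(s)[win]))
  # idempotence
  n2 <- normalizeToReference(n1)
  expect_equal(intensity(n2), intensity(n1))
  # all-zero reference region is a flagged missing feature
  bare <- spectrum(axis, lorentzBand(axis, 965, 12, 3), "raman")
  bare@intensity[abs(axis - 1445) <= 10] <- 0
  expect_error(normalizeToReference(bare), class = "bramsMissingFeature")
})

test_that("peak intensity is the window maximum", {
  s <- spectrum(c(964, 966), c(2, 5), "raman")
  expect_equal(peakIntensity(s, 965, 8), 5)
  s1 <- spectrum(965, 3, "raman")
  expect_equal(peakIntensity(s1, 965, 8), 3)
  axis <- seq(940, 990, by = 1)
  apex <- spectrum(axis, lorentzBand(axis, 965, 10, 4), "raman")
  expect_equal(peakIntensity(apex, 965, 8), 4)
  expect_error(peakIntensity(s1, 2000, 8), "no channels")
})

test_that("mineralization ratio compares the two marker peaks", {
  axis <- seq(800, 1800, by = 1)
  mk <- function(a965, a860)
    spectrum(axis, lorentzBand(axis, 965, 12, a965) +
               lorentzBand(axis, 860, 12, a860) +
               lorentzBand(axis, 1445, 16, 1), "raman")
  expect_equal(mineralizationRatio(mk(2, 2)), 1, tolerance = 1e-3)
  expect_equal(mineralizationRatio(mk(2, 1)), 2, tolerance = 5e-3)
  # scale invariance
  s <- mk(3, 2)
  s10 <- spectrum(axis, intensity(s) * 10, "raman")
  expect_equal(mineralizationRatio(s10), mineralizationRatio(s))
})

test_that("band first moment matches symmetric two-band arithmetic", {
  axis <- seq(2800, 3100, by = 0.5)
  one <- spectrum(axis, lorentzBand(axis, 2935, 20, 5), "raman")
  expect_equal(bandFirstMoment(one, c(2800, 3100)), 2935, tolerance = 0.5)
  # equal-area bands at 2872 and 2935 average to the midpoint
  two <- spectrum(axis, lorentzBand(axis, 2872, 20, 5) +
                    lorentzBand(axis, 2935, 20, 5), "raman")
  expect_equal(bandFirstMoment(two, c(2800, 3100)), 2903.5, tolerance = 0.5)
})

test_that("CH moment decreases strictly with the lipid contribution", {
  axis <- seq(2750, 3150, by = 0.5)
  moments <- vapply(seq(0, 4, by = 0.5), function(a) {
    s <- spectrum(axis, lorentzBand(axis, 2872, 20, a) +
                    lorentzBand(axis, 2935, 22, 2), "raman")
    bandFirstMoment(s, c(2800, 3100))
  }, numeric(1))
  expect_true(all(diff(moments) < 0))
  expect_lt(min(moments), 2935)
  expect_gt(min(moments), 2872)
})

test_that("full Raman extraction recovers template ground truth", {
  cfg <- analysisConfig()
  # lipid-dominated pixel: CH moment near the 2872 lipid band
  lip <- pixelTruth(6.8, 18, 50, mineral = 0.02, collagen = 0.05,
                    lipid = 2, heme = 0, carotenoid = 0)
  fl <- extractRamanFeatures(simulateRamanSpectrum(lip), cfg)$features
  expect_lt(fl[["ch_moment"]], 2890)
  # heme-rich pixel: heme-amide moment below the protein-only value
  prot <- pixelTruth(6.8, 18, 50, mineral = 0.5, collagen = 1, lipid = 0.05,
                     heme = 0, carotenoid = 0)
  heme <- pixelTruth(6.8, 18, 50, mineral = 0.5, collagen = 1, lipid = 0.05,
                     heme = 1, carotenoid = 0)
  fp <- extractRamanFeatures(simulateRamanSpectrum(prot), cfg)$features
  fh <- extractRamanFeatures(simulateRamanSpectrum(heme), cfg)$features
  expect_lt(fh[["heme_moment"]], fp[["heme_moment"]])
  # mineral-free pixel: mineral-to-matrix ratio near zero
  bare <- pixelTruth(6.8, 18, 50, mineral = 0, collagen = 1, lipid = 0.1,
                     heme = 0, carotenoid = 0)
  fb <- extractRamanFeatures(simulateRamanSpectrum(bare), cfg)$features
  expect_lt(fb[["mineral_to_matrix"]], 0.05)
})

test_that("markers are invariant to scaling and removable baselines", {
  cfg <- analysisConfig()
  tr <- pixelTruth(6.8, 18, 50, mineral = 1.2, collagen = 1, lipid = 0.3,
                   heme = 0.1, carotenoid = 0.02,
                   baseline = c(0, 0, 0))
  s0 <- simulateRamanSpectrum(tr)
  f0 <- extractRamanFeatures(s0, cfg)$features
  # positive rescaling
  s10 <- spectrum(spectralAxis(s0), intensity(s0) * 37, "raman")
  expect_equal(extractRamanFeatures(s10, cfg)$features, f0,
               tolerance = 1e-9)
  # additive polynomial baseline of order <= baselineOrder
  u <- (spectralAxis(s0) - 250) / (3700 - 250)
  base <- max(intensity(s0)) * (0.8 - 0.3 * u + 0.4 * u^2 - 0.2 * u^4)
  sb <- spectrum(spectralAxis(s0), intensity(s0) + pmax(base, 0), "raman")
  fb <- extractRamanFeatures(sb, cfg)$features
  expect_equal(fb[["mineral_to_matrix"]], f0[["mineral_to_matrix"]],
               tolerance = 0.05)
  expect_equal(fb[["ch_moment"]], f0[["ch_moment"]], tolerance = 2 / 2900)
  expect_equal(fb[["heme_moment"]], f0[["heme_moment"]],
               tolerance = 2 / 1600)
})

test_that("crystallinity reports the FWHM of the phosphate band", {
  axis <- seq(900, 1040, by = 0.5)
  s <- spectrum(axis, lorentzBand(axis, 965, 14, 6) + 1e-3, "raman")
  expect_equal(crystallinity(s), 14, tolerance = 0.02)
})

test_that("the band catalogue is sorted and covers the marker bands", {
  cat <- bandCatalogue()
  expect_true(!is.unsorted(cat$wavenumber))
  expect_true(all(c(860, 965, 1445, 1580, 2872, 2935) %in% cat$wavenumber))
  expect_true(all(cat$wavenumber > 0))
})
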