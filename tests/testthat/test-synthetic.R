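# The phantom generator: determinism, construction guarantees, and
# closed-loop parameter recovery through the analysis pipeline.

test_that("simulators are deterministic under a fixed seed", {
  tr <- pixelTruth(6.8, 18.2, 40, snr = 50)
  b1 <- simulateBrillouinSpectrum(tr, seed = 123)
  b2 <- simulateBrillouinSpectrum(tr, seed = 123)
  expect_identical(intensity(b1), intensity(b2))
  r1 <- simulateRamanSpectrum(tr, seed = 123)
  r2 <- simulateRamanSpectrum(tr, seed = 123)
  expect_identical(intensity(r1), intensity(r2))
  # different seeds differ
  expect_false(identical(intensity(b1),
                         intensity(simulateBrillouinSpectrum(tr,
                                                             seed = 124))))
  # the caller's RNG stream is not consumed
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(simulateBrillouinSpectrum(tr, seed = 9))
  expect_identical(runif(3), before)
})

test_that("a pure-soft spectrum has no intensity above 13 GHz", {
  tr <- pixelTruth(6.8, 18, 100)
  s <- simulateBrillouinSpectrum(tr)
  expect_true(all(intensity(s)[spectralAxis(s) > 13] == 0))
})

test_that("in-band areas stand in the configured fraction ratio", {
  cfg <- analysisConfig()
  for (frac in c(10, 33.9, 50, 80)) {
    s <- simulateBrillouinSpectrum(pixelTruth(6.87, 18.6, frac), config = cfg)
    aS <- bandIntensity(s, cfg@softRange)
    aH <- bandIntensity(s, cfg@hardRange, edges = c(FALSE, TRUE))
    expect_equal(100 * aS / (aS + aH), frac, tolerance = 0.01)
  }
  # the efficiency weighting is applied on the soft band
  cfg2 <- analysisConfig(efficiencyRatio = 2)
  s2 <- simulateBrillouinSpectrum(pixelTruth(6.87, 18.6, 50), config = cfg2)
  f2 <- extractBrillouinFeatures(s2, cfg2)
  expect_equal(f2[["I_soft"]], 50, tolerance = 0.1)
})

test_that("lipid-only Raman template puts the CH moment at the lipid band", {
  tr <- pixelTruth(6.8, 18, 50, mineral = 0, collagen = 0, lipid = 1,
                   heme = 0, carotenoid = 0)
  tf <- templateRamanFeatures(tr)
  # band-moment truncation of the Lorentzian tails biases the moment a few
  # cm^-1 above the nominal 2872 line
  expect_lt(abs(tf[["ch_moment"]] - 2872), 5)
  expect_error(simulateRamanSpectrum(
    pixelTruth(6.8, 18, 50, mineral = 0, collagen = 0, lipid = 0,
               heme = 0, carotenoid = 0)), "weights")
})

test_that("phantom construction yields the advertised region structure", {
  ph <- generatePhantom("cortical", shape = c(16, 16), seed = 5)
  expect_gte(sum(ph$truth$region == "vessel"), 1)
  expect_gte(sum(ph$truth$region == "matrix"), 100)
  expect_equal(nrow(ph$truth), 256)
  tr <- generatePhantom("trabecular", shape = c(16, 16), seed = 5)
  expect_true(all(c("spicule") %in% tr$truth$region))
  expect_true(any(grepl("marrow", tr$truth$region)))
  expect_error(generatePhantom("cortical", shape = c(3, 8), seed = 1))
  expect_error(generatePhantom("cortical", shape = c(8, 8)), "seed")
  # same seed, byte-identical phantom
  ph2 <- generatePhantom("cortical", shape = c(16, 16), seed = 5)
  expect_identical(ph$map@brillouin, ph2$map@brillouin)
  expect_identical(ph$map@raman, ph2$map@raman)
  expect_identical(ph$truth, ph2$truth)
})

test_that("the pipeline recovers phantom ground truth without noise", {
  cfg <- analysisConfig()
  ph <- generatePhantom("cortical", shape = c(8, 8), seed = 41)
  fm <- mapFeatures(ph$map, cfg)
  tt <- ph$truth
  for (k in seq_len(nrow(tt))) {
    i <- tt$row[k] + 1L
    j <- tt$col[k] + 1L
    expect_lt(abs(featureMatrix(fm, "nu_soft")[i, j] - tt$nu_soft[k]), 0.05)
    expect_lt(abs(featureMatrix(fm, "nu_hard")[i, j] - tt$nu_hard[k]), 0.05)
    expect_lt(abs(featureMatrix(fm, "I_soft")[i, j] - tt$frac_soft[k]), 1)
    expect_lt(abs(featureMatrix(fm, "M_soft")[i, j] /
                    longitudinalModulus(tt$nu_soft[k]) - 1), 0.02)
    expect_lt(abs(featureMatrix(fm, "M_hard")[i, j] /
                    longitudinalModulus(tt$nu_hard[k]) - 1), 0.02)
    tf <- templateRamanFeatures(tt[k, ], config = cfg)
    expect_lt(abs(featureMatrix(fm, "ch_moment")[i, j] - tf[["ch_moment"]]),
              2)
    expect_lt(abs(featureMatrix(fm, "mineral_to_matrix")[i, j] /
                    tf[["mineral_to_matrix"]] - 1), 0.05)
  }
})

test_that("feature-recovery error shrinks as noise vanishes", {
  # median |I_soft error| over 50 pixels at three Poisson noise levels
  medianErr <- function(snr) {
    errs <- vapply(1:50, function(k) {
      tr <- pixelTruth(6.7, 18.1, 40, snr = snr)
      f <- extractBrillouinFeatures(simulateBrillouinSpectrum(tr,
                                                              seed = 1000 + k))
      abs(f[["I_soft"]] - 40)
    }, numeric(1))
    median(errs)
  }
  e <- vapply(c(10, 30, 100), medianErr, numeric(1))
  expect_true(all(diff(e) <= 0))
  expect_lt(e[3], e[1])
})

test_that("the study fixture encodes the configured treatment contrasts", {
  fx <- generateStudyFixture(seed = 99, shape = c(4, 4))
  expect_named(fx, c("cortical_frozen_diaphysis",
                     "trabecular_frozen_diaphysis",
                     "cortical_frozen_epiphysis",
                     "trabecular_frozen_epiphysis",
                     "cortical_fixed_diaphysis",
                     "trabecular_fixed_diaphysis"),
               ignore.order = TRUE)
  mn <- function(roi, col) mean(fx[[roi]]$truth[[col]])
  # fixation raises nu_soft by sqrt(1.34)/sqrt(1.37) and depletes frac_soft
  expect_equal(mn("cortical_fixed_diaphysis", "nu_soft") /
                 mn("cortical_frozen_diaphysis", "nu_soft"),
               sqrt(1.34), tolerance = 0.01)
  expect_equal(mn("trabecular_fixed_diaphysis", "nu_soft") /
                 mn("trabecular_frozen_diaphysis", "nu_soft"),
               sqrt(1.37), tolerance = 0.01)
  expect_lt(mn("cortical_fixed_diaphysis", "frac_soft"),
            0.35 * mn("cortical_frozen_diaphysis", "frac_soft"))
  # fixation strips lipids and heme
  expect_lt(mn("cortical_fixed_diaphysis", "lipid"),
            0.2 * mn("cortical_frozen_diaphysis", "lipid"))
  expect_equal(mn("trabecular_fixed_diaphysis", "heme"), 0)
  # epiphyseal trabecular marrow is heme-enriched vs diaphyseal
  expect_gt(mn("trabecular_frozen_epiphysis", "heme"),
            3 * mn("trabecular_frozen_diaphysis", "heme"))
  # determinism
  fx2 <- generateStudyFixture(seed = 99, shape = c(4, 4))
  expect_identical(fx$cortical_frozen_diaphysis$map@raman,
                   fx2$cortical_frozen_diaphysis$map@raman)
})

test_that("fixture comparisons carry the reported signs of change", {
  fx <- generateStudyFixture(seed = 7, shape = c(4, 4))
  mAvg <- function(roi) {
    fm <- mapFeatures(fx[[roi]]$map)
    mean(featureMatrix(fm, "M_avg"))
  }
  # + for fixation in both tissues
  expect_gt(mAvg("cortical_fixed_diaphysis"),
            mAvg("cortical_frozen_diaphysis"))
  expect_gt(mAvg("trabecular_fixed_diaphysis"),
            mAvg("trabecular_frozen_diaphysis"))
  # + for cortical epiphysis vs diaphysis, - for trabecular
  expect_gt(mAvg("cortical_frozen_epiphysis"),
            mAvg("cortical_frozen_diaphysis"))
  expect_lt(mAvg("trabecular_frozen_epiphysis"),
            mAvg("trabecular_frozen_diaphysis"))
})
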