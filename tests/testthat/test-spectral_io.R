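# On-disk formats: spectra, maps (both dialects), feature tables, config.

test_that("spectra parse from two-column text with headers", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# modality: brillouin", "# position: 3 6",
               "10.0 5.0", "11.0 7.0"), f)
  s <- readSpectrum(f)
  expect_equal(spectralAxis(s), c(10, 11))
  expect_equal(intensity(s), c(5, 7))
  expect_equal(modality(s), "brillouin")
  expect_equal(position(s), c(3, 6))
})

test_that("malformed spectrum files raise format errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("11.0 5.0", "10.0 7.0"), f)
  expect_error(readSpectrum(f, "brillouin"), "strictly increasing")
  writeLines(c("# modality: raman", "800 1.0", "801 -2.0"), f)
  expect_error(readSpectrum(f), "negative intensity at line 3")
  writeLines(c("10.0 5.0"), f)
  expect_error(readSpectrum(f), "modality")
})

test_that("spectrum write/read round trip preserves values", {
  axis <- seq(4, 32, by = 0.37)
  s <- spectrum(axis, rexp(length(axis)) + 0.1, "brillouin",
                position = c(12, 15))
  f <- withr::local_tempfile(fileext = ".txt")
  writeSpectrum(s, f)
  s2 <- readSpectrum(f)
  expect_equal(spectralAxis(s2), spectralAxis(s), tolerance = 1e-5)
  expect_equal(intensity(s2), intensity(s), tolerance = 1e-5)
  expect_identical(modality(s2), modality(s))
  expect_equal(position(s2), position(s))
})

test_that("maps round trip through the long format", {
  map <- tinyMap()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMap(map, f, format = "long")
  m2 <- readMap(f)
  expect_equal(mapDim(m2), mapDim(map))
  expect_equal(gridStep(m2), gridStep(map))
  expect_equal(gridOrigin(m2), gridOrigin(map))
  expect_equal(m2@brillouinAxis, map@brillouinAxis, tolerance = 1e-5)
  expect_equal(m2@brillouin, map@brillouin, tolerance = 1e-5)
  expect_equal(m2@raman, map@raman, tolerance = 1e-5)
})

test_that("maps round trip through the directory layout identically", {
  map <- tinyMap()
  d1 <- withr::local_tempdir()
  f <- file.path(withr::local_tempdir(), "map.tsv")
  writeMap(map, d1, format = "dir")
  writeMap(map, f, format = "long")
  mdir <- readMap(d1)
  mlong <- readMap(f)
  # both dialects re-read to identical in-memory objects
  expect_equal(mdir@brillouin, mlong@brillouin, tolerance = 1e-12)
  expect_equal(mdir@raman, mlong@raman, tolerance = 1e-12)
  expect_equal(mapDim(mdir), mapDim(mlong))
  expect_equal(gridStep(mdir), gridStep(mlong))
})

test_that("a missing modality at a pixel is absent, not zero", {
  map <- tinyMap()
  map@raman[2, ] <- NA_real_
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMap(map, f, format = "long")
  m2 <- readMap(f)
  expect_true(all(is.na(m2@raman[2, ])))
  expect_false(anyNA(m2@brillouin[2, ]))
  expect_null(getSpectrum(m2, 0, 1, "raman"))
  expect_s4_class(getSpectrum(m2, 0, 1, "brillouin"), "Spectrum")
})

test_that("ragged and inconsistent maps are rejected with coordinates", {
  map <- tinyMap()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeMap(map, f, format = "long")
  tab <- read.table(f, header = TRUE, sep = "\t", comment.char = "#")
  # drop pixel (x=1, y=0) entirely
  tab2 <- tab[!(tab$x == 1 & tab$y == 0), ]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  file.copy(paste0(f, ".meta.yaml"), paste0(f2, ".meta.yaml"))
  expect_error(readMap(f2), "\\(1, 0\\)")
  # shift one pixel's Brillouin axis: inconsistent axes within a modality
  tab3 <- tab
  sel <- tab3$x == 0 & tab3$y == 0 & tab3$modality == "brillouin"
  tab3$axis_value[sel] <- tab3$axis_value[sel] + 0.01
  f3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab3, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  file.copy(paste0(f, ".meta.yaml"), paste0(f3, ".meta.yaml"))
  expect_error(readMap(f3), "inconsistent")
})

test_that("feature tables round trip with empty cells for masked pixels", {
  ph <- generatePhantom("cortical", shape = c(4, 4), seed = 2)
  fm <- mapFeatures(ph$map)
  fm@features$mineral_to_matrix[2, 3] <- NA_real_
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFeaturesTable(fm, f)
  # header + one row per pixel
  lines <- readLines(f)
  expect_length(lines, 17)
  # absent value written as an empty cell, not zero
  row <- strsplit(lines[1 + 1 * 4 + 2 + 1], "\t")[[1]]
  cols <- strsplit(lines[1], "\t")[[1]]
  expect_identical(row[which(cols == "mineral_to_matrix")], "")
  fm2 <- readFeaturesTable(f)
  expect_true(is.na(featureMatrix(fm2, "mineral_to_matrix")[2, 3]))
  for (feat in featureNames(fm))
    expect_equal(featureMatrix(fm2, feat), featureMatrix(fm, feat),
                 tolerance = 1e-5, info = feat)
})

test_that("single-pixel feature tables have a header and one data row", {
  fm <- constantFeatureMap(1, 1, list(M_avg = 12.5))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFeaturesTable(fm, f)
  expect_length(readLines(f), 2)
  mismatched <- list(M_avg = matrix(1, 1, 1), M_soft = matrix(1, 2, 2))
  expect_error(writeFeaturesTable(mismatched, f), "share one grid shape")
})

test_that("configs round trip through YAML", {
  cfg <- analysisConfig(efficiencyRatio = 1.7, baselineOrder = 4,
                        autoscale = TRUE, softRange = c(3.5, 13))
  f <- withr::local_tempfile(fileext = ".yaml")
  writeConfig(cfg, f)
  cfg2 <- readConfig(f)
  for (s in slotNames(cfg))
    expect_equal(slot(cfg2, s), slot(cfg, s), info = s)
  writeLines("bogusKey: 3", f)
  expect_error(readConfig(f), "unknown config key")
})

test_that("ROI files read back with required columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\trow_lo\trow_hi\tcol_lo\tcol_hi",
               "vessel\t0\t4\t2\t6"), f)
  r <- readROIs(f)
  expect_equal(r$id, "vessel")
  expect_equal(r$col_hi, 6)
  writeLines("id\trow_lo", f)
  expect_error(readROIs(f), "columns")
})

test_that("invalid domain objects are rejected by validity checks", {
  expect_error(spectrum(c(1, 1), c(1, 2), "brillouin"), "increasing")
  expect_error(spectrum(c(5, 6), c(-1, 2), "brillouin"), "non-negative")
  expect_error(spectrum(c(60, 70), c(1, 2), "brillouin"), "within")
  expect_error(spectrum(c(99, 100), c(1, 2), "raman"), "within")
  expect_error(analysisConfig(softRange = c(13, 4)), "ordered")
  expect_error(analysisConfig(kappa = -1), "positive")
})
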