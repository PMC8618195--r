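#' @include AllClasses.R constructors.R brillouin.R
NULL

## Classed condition used to flag per-pixel missing features; callers that
## process whole maps catch it and record NA instead of failing.
.missingFeature <- function(msg) {
  stop(structure(class = c("bramsMissingFeature", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Iterative polynomial fluorescence baseline removal
#'
#' Modified polynomial fitting: fit a polynomial of the given order to the
#' spectrum, replace every intensity above the fit by the fit, and repeat
#' until the fit stabilises (relative change < 1e-6) or the iteration cap is
#' reached. Peaks, which always sit above the fluorescence continuum, are
#' progressively excluded so the polynomial settles onto the baseline. The
#' final fit is subtracted and negative residuals are clipped to zero (the
#' moment weights downstream must be non-negative).
#'
#' The fit uses an orthogonal polynomial basis on the centred, scaled axis,
#' so it stays well conditioned on wavenumber axes spanning thousands of
#' cm^-1. The clip-refit map converges geometrically but slowly when peaks
#' are dense, so every third iteration the fit is advanced by a
#' geometric-series extrapolation of its own increments (accepted only for a
#' stable contraction estimate, 0 < rho < 1); the iteration then continues
#' from the extrapolated fit, reaching the same fixed point in far fewer
#' refits.
#'
#' @param x a [Spectrum-class] (any modality; in the standard pipeline, raw
#'   Raman spectra).
#' @param order polynomial order (>= 1, default 5).
#' @param iterations iteration cap (default 50).
#' @return A [Spectrum-class] with the baseline removed, same axis.
#' @seealso [normalizeToReference()], [extractRamanFeatures()]
#' @export
removeBaseline <- function(x, order = 5L, iterations = 50L) {
  stopifnot(is(x, "Spectrum"), order >= 1L, iterations >= 1L)
  n <- length(x@axis)
  if (n <= order + 1L)
    stop("spectrum must have more than order + 1 channels")
  basis <- cbind(1, stats::poly(x@axis, degree = order))
  qrB <- qr(basis)
  if (qrB$rank < ncol(basis))
    stop("baseline fit is ill-conditioned; rescale the axis")
  y <- x@intensity
  fit <- rep(0, n)
  prev <- NULL
  prev2 <- NULL
  scale <- max(abs(y), 1e-300)
  for (k in seq_len(iterations)) {
    newfit <- qr.fitted(qrB, y)
    if (k > 1L && max(abs(newfit - fit)) < 1e-6 * scale) {
      fit <- newfit
      break
    }
    prev2 <- prev
    prev <- fit
    fit <- newfit
    if (!is.null(prev2) && k %% 3L == 0L) {
      d1 <- prev - prev2
      d2 <- fit - prev
      rho <- sum(d2 * d1) / sum(d1 * d1)
      if (is.finite(rho) && rho > 0 && rho < 1)
        fit <- fit + rho / (1 - rho) * d2
    }
    y <- pmin(y, fit)
  }
  initialize(x, intensity = pmax(x@intensity - fit, 0))
}

#' Normalise a spectrum to a reference band
#'
#' Divides all intensities by the maximum intensity found within
#' `refWavenumber +/- window` (the window maximum is robust to small
#' calibration shifts between instruments). After normalisation the
#' reference-window maximum is exactly 1. In the standard pipeline the
#' reference is the CH2 wagging band at 1445 cm^-1, present in both lipids
#' and proteins.
#'
#' @param x a baseline-removed [Spectrum-class].
#' @param refWavenumber reference band position (axis units).
#' @param window window half-width (axis units).
#' @return The normalised [Spectrum-class]. Signals a missing-feature
#'   condition when the reference window holds no positive intensity.
#' @export
normalizeToReference <- function(x, refWavenumber = 1445, window = 10) {
  stopifnot(is(x, "Spectrum"), window > 0)
  idx <- .bandChannels(x@axis, refWavenumber + c(-window, window))
  if (length(idx) == 0L)
    .missingFeature("reference window covers no channels")
  ref <- max(x@intensity[idx])
  if (!is.finite(ref) || ref <= 0)
    .missingFeature("no positive intensity in the reference window")
  initialize(x, intensity = x@intensity / ref)
}

#' Peak intensity in a window
#'
#' The maximum intensity within `center +/- window`. Marker ratios use window
#' maxima rather than fitted areas, matching intensity-ratio usage and
#' tolerating small calibration shifts.
#'
#' @param x a [Spectrum-class].
#' @param center peak position (axis units).
#' @param window window half-width (axis units).
#' @return Maximum intensity in the window.
#' @examples
#' s <- spectrum(c(964, 966), c(2, 5), "raman")
#' peakIntensity(s, 965, 8)  # 5
#' @export
peakIntensity <- function(x, center, window = 8) {
  stopifnot(is(x, "Spectrum"), window > 0)
  idx <- .bandChannels(x@axis, center + c(-window, window))
  if (length(idx) == 0L)
    stop("window covers no channels")
  max(x@intensity[idx])
}

#' Mineral-to-matrix ratio
#'
#' Intensity ratio of the nu1 PO4^3- phosphate stretch (~965 cm^-1) to the
#' proline ring breathing band (~860 cm^-1): a marker of the mineralization
#' degree of the collagen bundles. Scale-invariant, so it may be computed on
#' raw or normalised spectra; the standard pipeline computes it after
#' normalisation.
#'
#' @param x a preprocessed Raman [Spectrum-class].
#' @param config an [AnalysisConfig-class] (peak positions and window).
#' @return Non-negative ratio; signals a missing-feature condition when the
#'   proline intensity is zero.
#' @export
mineralizationRatio <- function(x, config = analysisConfig()) {
  mineral <- peakIntensity(x, config@mineralPeak, config@peakWindow)
  proline <- peakIntensity(x, config@prolinePeak, config@peakWindow)
  if (proline <= 0)
    .missingFeature("zero proline intensity")
  mineral / proline
}

#' First spectral moment of a Raman band
#'
#' Identical contract to [spectralMoment()] (shared implementation) on the
#' Raman axis: the intensity-weighted mean wavenumber over the band, both
#' edges included. Used for the CH2-CH3 band (2800--3100 cm^-1,
#' lipid-to-protein balance: lipids pull the moment toward 2872 cm^-1,
#' proteins toward 2935 cm^-1) and the heme-amide band (1500--1720 cm^-1,
#' where heme at 1580 cm^-1 pulls the moment below the amide I position).
#'
#' @param x a Raman [Spectrum-class].
#' @param band numeric `(lo, hi)` in cm^-1.
#' @return Band centre in cm^-1, or `NA_real_` for an empty band.
#' @export
bandFirstMoment <- function(x, band) {
  spectralMoment(x, band)
}

#' Hydroxyapatite crystallinity (optional marker)
#'
#' Full width at half maximum of the nu1 PO4^3- band, found by linear
#' interpolation of the half-maximum crossings on either side of the window
#' apex. An established bone-quality metric; not part of the default feature
#' set.
#'
#' @param x a preprocessed Raman [Spectrum-class].
#' @param config an [AnalysisConfig-class].
#' @param searchWidth half-width (cm^-1) around the apex searched for the
#'   half-maximum crossings.
#' @return FWHM in cm^-1, or `NA_real_` when a crossing is not bracketed.
#' @export
crystallinity <- function(x, config = analysisConfig(), searchWidth = 40) {
  idx <- .bandChannels(x@axis,
                       config@mineralPeak + c(-searchWidth, searchWidth))
  if (length(idx) < 3L) return(NA_real_)
  ax <- x@axis[idx]
  iy <- x@intensity[idx]
  ## apex restricted to the marker window so shoulders don't capture it
  win <- which(abs(ax - config@mineralPeak) <= config@peakWindow)
  if (length(win) == 0L) return(NA_real_)
  apex <- win[which.max(iy[win])]
  half <- iy[apex] / 2
  if (half <= 0) return(NA_real_)
  cross <- function(i1, i2) {
    # linear interpolation of the half-maximum crossing between channels
    ax[i1] + (half - iy[i1]) * (ax[i2] - ax[i1]) / (iy[i2] - iy[i1])
  }
  left <- NA_real_
  if (apex > 1L) for (i in seq(apex, 2L)) {
    if (iy[i - 1L] < half && iy[i] >= half) {
      left <- cross(i - 1L, i)
      break
    }
  }
  right <- NA_real_
  if (apex < length(iy)) {
    for (i in seq(apex, length(iy) - 1L)) {
      if (iy[i] >= half && iy[i + 1L] < half) {
        right <- cross(i + 1L, i)
        break
      }
    }
  }
  right - left
}

#' Per-pixel Raman chemistry
#'
#' Full single-spectrum Raman analysis: iterative polynomial baseline
#' removal, normalisation to the reference band, then the three markers
#' (mineral-to-matrix ratio, CH2-CH3 band first moment, heme-amide band
#' first moment). A failed normalisation or marker yields `NA` for the
#' affected features; the pixel is retained.
#'
#' @param x a raw Raman [Spectrum-class].
#' @param config an [AnalysisConfig-class].
#' @return A list with `features` (named numeric: `mineral_to_matrix`,
#'   `ch_moment`, `heme_moment`) and `normalized` (the preprocessed
#'   [Spectrum-class], or `NULL` when normalisation failed).
#' @export
extractRamanFeatures <- function(x, config = analysisConfig()) {
  stopifnot(is(x, "Spectrum"), is(config, "AnalysisConfig"))
  if (x@modality != "raman")
    stop("extractRamanFeatures requires a Raman spectrum")
  feats <- c(mineral_to_matrix = NA_real_, ch_moment = NA_real_,
             heme_moment = NA_real_)
  flat <- removeBaseline(x, config@baselineOrder, config@baselineIters)
  norm <- tryCatch(
    normalizeToReference(flat, config@refWavenumber, config@refWindow),
    bramsMissingFeature = function(e) NULL)
  if (is.null(norm))
    return(list(features = feats, normalized = NULL))
  feats["mineral_to_matrix"] <- tryCatch(
    mineralizationRatio(norm, config),
    bramsMissingFeature = function(e) NA_real_)
  feats["ch_moment"] <- bandFirstMoment(norm, config@chBand)
  feats["heme_moment"] <- bandFirstMoment(norm, config@hemeBand)
  list(features = feats, normalized = norm)
}

#' Catalogue of typical bone-tissue Raman bands
#'
#' Reference table of the Raman vibrations commonly resolved in cortical and
#' trabecular bone spectra, with their standard assignments. Band ranges
#' (e.g. the carotenoid 1125--1160 cm^-1 region) are listed by their lower
#' and upper limits.
#'
#' @return A data.frame with columns `wavenumber` (cm^-1, sorted),
#'   `wavenumber_hi` (`NA` for single bands, the upper limit for ranges) and
#'   `assignment`.
#' @examples
#' head(bandCatalogue())
#' @export
bandCatalogue <- function() {
  df <- data.frame(
    wavenumber = c(860, 870, 965, 1003, 1030, 1068, 1125, 1170, 1242, 1298,
                   1445, 1580, 1655, 1745, 2872, 2935, 3150),
    wavenumber_hi = c(NA, NA, NA, NA, NA, NA, 1160, NA, NA, NA,
                      NA, NA, 1675, NA, NA, NA, 3500),
    assignment = c(
      "Proline (benzene ring breathing)",
      "Hydroxyproline (benzene ring breathing)",
      "nu1 PO4 3- (P-O symmetric stretch)",
      "Phenylalanine (aromatic ring breathing)",
      "nu3 PO4 3- (P-O asymmetric stretch)",
      "nu1 CO3 2- (C-O in-plane stretch)",
      "C-CH3 carotenoids",
      "Hemoglobin",
      "Amide III (C-N-H stretch)",
      "Fatty acids (CH2-CH3 twisting and wagging)",
      "CH2 (lipids)",
      "Hemoglobin",
      "Amide I (C=O stretch)",
      "Esters (C=O)",
      "CH2 lipids",
      "CH3 proteins",
      "OH stretching"),
    stringsAsFactors = FALSE
  )
  df[order(df$wavenumber), , drop = FALSE]
}
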