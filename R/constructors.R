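#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a Spectrum
#'
#' @param axis numeric, strictly increasing channel positions (GHz for
#'   Brillouin, cm^-1 for Raman).
#' @param intensity numeric, non-negative counts, same length as `axis`.
#' @param modality `"brillouin"` or `"raman"`.
#' @param position optional `(x, y)` stage position in micrometres.
#'
#' @return A validated [Spectrum-class] object.
#' @examples
#' s <- spectrum(c(10, 11), c(5, 7), "brillouin")
#' spectralAxis(s)
#' @export
spectrum <- function(axis, intensity, modality = c("brillouin", "raman"),
                     position = c(NA_real_, NA_real_)) {
  modality <- match.arg(modality)
  new("Spectrum", axis = as.numeric(axis), intensity = as.numeric(intensity),
      modality = modality, position = as.numeric(position))
}

#' Construct a SpectralMap from per-pixel spectra
#'
#' @param nrow,ncol grid dimensions.
#' @param brillouinAxis,ramanAxis shared axes (NULL when the modality is
#'   absent from the map).
#' @param brillouin,raman pixels-by-channels intensity matrices in row-major
#'   pixel order, or NULL; all-`NA` rows mark pixels where the modality was
#'   not acquired.
#' @param step grid spacing in micrometres.
#' @param origin `(x0, y0)` in micrometres.
#'
#' @return A validated [SpectralMap-class].
#' @export
spectralMap <- function(nrow, ncol, brillouinAxis = NULL, brillouin = NULL,
                        ramanAxis = NULL, raman = NULL, step = 3,
                        origin = c(0, 0)) {
  npix <- as.integer(nrow) * as.integer(ncol)
  fix <- function(axis, mat) {
    if (is.null(axis)) {
      list(axis = numeric(0), mat = matrix(numeric(0), nrow = npix, ncol = 0))
    } else {
      if (is.null(mat))
        stop("intensity matrix required when an axis is given")
      list(axis = as.numeric(axis), mat = as.matrix(mat))
    }
  }
  b <- fix(brillouinAxis, brillouin)
  r <- fix(ramanAxis, raman)
  new("SpectralMap", nrow = as.integer(nrow), ncol = as.integer(ncol),
      step = step, origin = as.numeric(origin),
      brillouinAxis = b$axis, brillouin = b$mat,
      ramanAxis = r$axis, raman = r$mat)
}

#' Pipeline configuration
#'
#' Builds an [AnalysisConfig-class] with the standard defaults; any parameter
#' can be overridden by name. See the class documentation for the meaning and
#' units of every slot.
#'
#' @param softRange,hardRange Brillouin band limits, GHz.
#' @param lambdaLaser laser wavelength, nm.
#' @param kappa rho/n^2, g/cm^3.
#' @param efficiencyRatio soft-vs-hard scattering-efficiency weight.
#' @param baselineOrder,baselineIters Raman baseline polynomial order and
#'   iteration cap.
#' @param backgroundSubtract subtract a constant Brillouin background before
#'   moments (median of channels outside both bands).
#' @param refWavenumber,refWindow Raman normalisation reference and window
#'   half-width, cm^-1.
#' @param fingerprintRange,chBand,hemeBand analysis windows, cm^-1.
#' @param mineralPeak,prolinePeak,peakWindow marker peaks and window
#'   half-width, cm^-1.
#' @param autoscale unit-variance scaling before PCA (centering is always on).
#' @param separationThreshold standardized separation above which a component
#'   is said to divide two groups.
#' @param histogramBins bins used in ROI histograms.
#'
#' @return An [AnalysisConfig-class] object.
#' @examples
#' cfg <- analysisConfig(efficiencyRatio = 1.2)
#' cfg
#' @export
analysisConfig <- function(softRange = c(4, 13),
                           hardRange = c(13, 32),
                           lambdaLaser = 532,
                           kappa = 1.29,
                           efficiencyRatio = 1,
                           baselineOrder = 5L,
                           baselineIters = 50L,
                           backgroundSubtract = FALSE,
                           refWavenumber = 1445,
                           refWindow = 10,
                           fingerprintRange = c(800, 1780),
                           chBand = c(2800, 3100),
                           hemeBand = c(1500, 1720),
                           mineralPeak = 965,
                           prolinePeak = 860,
                           peakWindow = 8,
                           autoscale = FALSE,
                           separationThreshold = 2,
                           histogramBins = 30L) {
  new("AnalysisConfig",
      softRange = as.numeric(softRange), hardRange = as.numeric(hardRange),
      lambdaLaser = lambdaLaser, kappa = kappa,
      efficiencyRatio = efficiencyRatio,
      baselineOrder = as.integer(baselineOrder),
      baselineIters = as.integer(baselineIters),
      backgroundSubtract = backgroundSubtract,
      refWavenumber = refWavenumber, refWindow = refWindow,
      fingerprintRange = as.numeric(fingerprintRange),
      chBand = as.numeric(chBand), hemeBand = as.numeric(hemeBand),
      mineralPeak = mineralPeak, prolinePeak = prolinePeak,
      peakWindow = peakWindow, autoscale = autoscale,
      separationThreshold = separationThreshold,
      histogramBins = as.integer(histogramBins))
}
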