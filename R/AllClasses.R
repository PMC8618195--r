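#' @import methods
NULL

## Central S4 containers. Pixel grids are stored row-major: pixel index
## (row - 1) * ncol + col, rows/cols 0-based in user-facing coordinates.

#' Spectrum: a single spectroscopic record
#'
#' One spectrum on a strictly increasing axis, tagged with its modality.
#' Brillouin axes are frequency shifts in GHz and must lie within 0--50 GHz;
#' Raman axes are wavenumbers in cm^-1 within 100--4100 cm^-1. The axis units
#' are never mixed: the modality tag declares them per record, which keeps the
#' GHz-vs-cm^-1 distinction explicit all the way into the modulus conversion.
#'
#' @slot axis numeric, strictly increasing channel positions (GHz or cm^-1).
#' @slot intensity numeric, non-negative counts per channel, same length as
#'   `axis`.
#' @slot modality character, `"brillouin"` or `"raman"`.
#' @slot position numeric length-2 `(x, y)` stage position in micrometres, or
#'   `c(NA_real_, NA_real_)` when the spectrum is not part of a map.
#'
#' @seealso [spectrum()] for the user-facing constructor, [readSpectrum()]
#' @export
setClass("Spectrum",
  representation(
    axis      = "numeric",
    intensity = "numeric",
    modality  = "character",
    position  = "numeric"
  ),
  prototype(position = c(NA_real_, NA_real_))
)

.axisLimits <- list(brillouin = c(0, 50), raman = c(100, 4100))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@modality) != 1L ||
      !object@modality %in% c("brillouin", "raman"))
    msg <- c(msg, "modality must be one of 'brillouin', 'raman'")
  if (length(object@axis) != length(object@intensity))
    msg <- c(msg, "axis and intensity must have the same length")
  if (length(object@axis) == 0L)
    msg <- c(msg, "spectrum must have at least one channel")
  if (anyNA(object@axis) || any(!is.finite(object@axis)))
    msg <- c(msg, "axis must be finite")
  if (length(object@axis) > 1L && any(diff(object@axis) <= 0))
    msg <- c(msg, "axis must be strictly increasing")
  if (any(object@intensity < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  if (length(object@modality) == 1L &&
      object@modality %in% names(.axisLimits) && length(object@axis) > 0L &&
      all(is.finite(object@axis))) {
    lim <- .axisLimits[[object@modality]]
    if (min(object@axis) < lim[1] || max(object@axis) > lim[2])
      msg <- c(msg, sprintf("%s axis must lie within [%g, %g]",
                            object@modality, lim[1], lim[2]))
  }
  if (length(object@position) != 2L)
    msg <- c(msg, "position must be a length-2 numeric (x, y)")
  if (length(msg)) msg else TRUE
})

#' SpectralMap: a rectangular grid of paired spectra
#'
#' Regular x-y lattice of pixels, each holding a Brillouin and/or a Raman
#' spectrum. All spectra of one modality share a common axis, so intensities
#' are stored as one pixels-by-channels matrix per modality; a pixel with a
#' missing modality has an all-`NA` row (absent, never zero). Pixel (i, j)
#' (0-based row i, column j) sits at stage position
#' `origin + c(j, i) * step` micrometres.
#'
#' @slot nrow,ncol integer grid dimensions.
#' @slot step numeric, grid spacing in micrometres (> 0, default 3).
#' @slot origin numeric length-2 `(x0, y0)` in micrometres.
#' @slot brillouinAxis,ramanAxis numeric shared axes (possibly length 0 when
#'   the modality is absent from the whole map).
#' @slot brillouin,raman numeric matrices, `nrow*ncol` pixels (row-major) by
#'   channels.
#'
#' @seealso [spectralMap()], [readMap()], [mapFeatures()]
#' @export
setClass("SpectralMap",
  representation(
    nrow          = "integer",
    ncol          = "integer",
    step          = "numeric",
    origin        = "numeric",
    brillouinAxis = "numeric",
    ramanAxis     = "numeric",
    brillouin     = "matrix",
    raman         = "matrix"
  ),
  prototype(step = 3, origin = c(0, 0))
)

setValidity("SpectralMap", function(object) {
  msg <- character()
  npix <- object@nrow * object@ncol
  if (object@nrow < 1L || object@ncol < 1L)
    msg <- c(msg, "grid must have at least one pixel")
  if (length(object@step) != 1L || !is.finite(object@step) ||
      object@step <= 0)
    msg <- c(msg, "step must be a single positive number")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must be length-2 (x0, y0)")
  chkmod <- function(axis, mat, what, lim) {
    m <- character()
    if (ncol(mat) != length(axis))
      m <- c(m, sprintf("%s matrix columns must match axis length", what))
    if (length(axis) > 0L) {
      if (nrow(mat) != npix)
        m <- c(m, sprintf("%s matrix must have one row per pixel", what))
      if (any(diff(axis) <= 0))
        m <- c(m, sprintf("%s axis must be strictly increasing", what))
      if (min(axis) < lim[1] || max(axis) > lim[2])
        m <- c(m, sprintf("%s axis out of range [%g, %g]", what,
                          lim[1], lim[2]))
      if (any(mat < 0, na.rm = TRUE))
        m <- c(m, sprintf("%s intensities must be non-negative", what))
      ## a pixel either has the full spectrum or none of it
      na <- is.na(mat)
      partial <- rowSums(na) > 0L & rowSums(na) < ncol(mat)
      if (any(partial))
        m <- c(m, sprintf("%s pixels must be fully present or fully absent",
                          what))
    }
    m
  }
  msg <- c(msg,
           chkmod(object@brillouinAxis, object@brillouin, "brillouin",
                  .axisLimits$brillouin),
           chkmod(object@ramanAxis, object@raman, "raman",
                  .axisLimits$raman))
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: parameters of the chemo-mechanical pipeline
#'
#' All tunable constants in one validated object. Defaults reproduce the
#' standard analysis: soft phase integrated over 4--13 GHz, hard phase over
#' 13--32 GHz (the 13 GHz edge channel belongs to the soft band), 532 nm
#' excitation, kappa = rho/n^2 = 1.29 g/cm^3 held constant across the tissue,
#' order-5 iterative polynomial fluorescence baseline, normalisation to the
#' 1445 cm^-1 CH2 band, fingerprint region 800--1780 cm^-1 for PCA.
#'
#' @slot softRange,hardRange numeric (lo, hi) GHz band limits.
#' @slot lambdaLaser numeric, laser wavelength in nm.
#' @slot kappa numeric, rho/n^2 in g/cm^3.
#' @slot efficiencyRatio numeric, soft-vs-hard scattering-efficiency weight.
#' @slot baselineOrder,baselineIters integer, polynomial baseline parameters.
#' @slot backgroundSubtract logical, subtract a constant Brillouin background
#'   (median of channels outside both bands) before moments; off by default.
#' @slot refWavenumber,refWindow numeric, Raman normalisation reference
#'   (cm^-1) and window half-width.
#' @slot fingerprintRange,chBand,hemeBand numeric (lo, hi) cm^-1 windows.
#' @slot mineralPeak,prolinePeak,peakWindow numeric, marker peak positions and
#'   window half-width (cm^-1).
#' @slot autoscale logical, scale PCA columns to unit variance (off by
#'   default; mean centering is always applied).
#' @slot separationThreshold numeric, standardized mean separation above which
#'   a principal component is reported as dividing two groups.
#' @slot histogramBins integer, bins for ROI histograms.
#'
#' @seealso [analysisConfig()], [readConfig()]
#' @export
setClass("AnalysisConfig",
  representation(
    softRange           = "numeric",
    hardRange           = "numeric",
    lambdaLaser         = "numeric",
    kappa               = "numeric",
    efficiencyRatio     = "numeric",
    baselineOrder       = "integer",
    baselineIters       = "integer",
    backgroundSubtract  = "logical",
    refWavenumber       = "numeric",
    refWindow           = "numeric",
    fingerprintRange    = "numeric",
    chBand              = "numeric",
    hemeBand            = "numeric",
    mineralPeak         = "numeric",
    prolinePeak         = "numeric",
    peakWindow          = "numeric",
    autoscale           = "logical",
    separationThreshold = "numeric",
    histogramBins       = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  rng <- function(x, what) {
    if (length(x) != 2L || anyNA(x) || x[1] >= x[2])
      sprintf("%s must be an ordered (lo, hi) pair", what)
    else character()
  }
  msg <- c(msg,
           rng(object@softRange, "softRange"),
           rng(object@hardRange, "hardRange"),
           rng(object@fingerprintRange, "fingerprintRange"),
           rng(object@chBand, "chBand"),
           rng(object@hemeBand, "hemeBand"))
  pos <- function(x, what) {
    if (length(x) != 1L || is.na(x) || x <= 0)
      sprintf("%s must be a single positive number", what)
    else character()
  }
  msg <- c(msg,
           pos(object@lambdaLaser, "lambdaLaser"),
           pos(object@kappa, "kappa"),
           pos(object@efficiencyRatio, "efficiencyRatio"),
           pos(object@refWindow, "refWindow"),
           pos(object@peakWindow, "peakWindow"),
           pos(object@separationThreshold, "separationThreshold"))
  if (object@baselineOrder < 1L)
    msg <- c(msg, "baselineOrder must be >= 1")
  if (object@baselineIters < 1L)
    msg <- c(msg, "baselineIters must be >= 1")
  if (object@histogramBins < 1L)
    msg <- c(msg, "histogramBins must be >= 1")
  if (length(msg)) msg else TRUE
})

#' FeatureMap: per-pixel chemo-mechanical features on the acquisition grid
#'
#' One numeric matrix per feature, all sharing the grid shape; `NA` cells mark
#' pixels where a feature could not be computed (empty band, missing
#' modality), and are excluded from every downstream statistic.
#'
#' @slot features named list of numeric matrices (`nu_soft`, `nu_hard`,
#'   `I_soft`, `I_hard`, `M_soft`, `M_hard`, `M_avg`, `mineral_to_matrix`,
#'   `ch_moment`, `heme_moment`).
#' @slot step,origin grid metadata inherited from the source [SpectralMap].
#'
#' @seealso [mapFeatures()], [roiStatistics()]
#' @export
setClass("FeatureMap",
  representation(
    features = "list",
    step     = "numeric",
    origin   = "numeric"
  )
)

setValidity("FeatureMap", function(object) {
  msg <- character()
  if (length(object@features) == 0L)
    msg <- c(msg, "at least one feature matrix required")
  if (is.null(names(object@features)) || any(names(object@features) == ""))
    msg <- c(msg, "features must be named")
  dims <- lapply(object@features, dim)
  if (!all(vapply(object@features, is.matrix, logical(1))))
    msg <- c(msg, "each feature must be a matrix")
  else if (length(unique(dims)) > 1L)
    msg <- c(msg, "all feature matrices must share the same shape")
  if (length(msg)) msg else TRUE
})

#' SpectralMatrix: preprocessed spectra ready for chemometrics
#'
#' Observations (pixels) in rows, wavenumber channels in columns; every row is
#' a baseline-removed, reference-normalised Raman spectrum cropped to the
#' fingerprint region. Pixels whose preprocessing failed are dropped before
#' construction, so the matrix has no missing cells.
#'
#' @slot data numeric matrix, observations by channels.
#' @slot wavenumbers numeric, strictly increasing column wavenumbers (cm^-1).
#' @slot labels data.frame with columns `roi`, `x`, `y`, one row per
#'   observation.
#'
#' @seealso [buildSpectralMatrix()], [runPCA()]
#' @export
setClass("SpectralMatrix",
  representation(
    data        = "matrix",
    wavenumbers = "numeric",
    labels      = "data.frame"
  )
)

setValidity("SpectralMatrix", function(object) {
  msg <- character()
  if (anyNA(object@data))
    msg <- c(msg, "matrix must not contain missing cells")
  if (ncol(object@data) != length(object@wavenumbers))
    msg <- c(msg, "columns must match wavenumbers")
  if (length(object@wavenumbers) > 1L && any(diff(object@wavenumbers) <= 0))
    msg <- c(msg, "wavenumbers must be strictly increasing")
  if (nrow(object@data) != nrow(object@labels))
    msg <- c(msg, "labels must have one row per observation")
  if (!all(c("roi", "x", "y") %in% names(object@labels)))
    msg <- c(msg, "labels must have columns roi, x, y")
  if (length(msg)) msg else TRUE
})

#' PCAResult: principal component decomposition of a SpectralMatrix
#'
#' Column-mean-centred singular value decomposition. Loadings are stored as a
#' components-by-wavenumbers matrix with orthonormal rows; scores are
#' observations by components; `scores %*% loadings` reconstructs the centred
#' data when all components are retained. The sign convention fixes each
#' component so its largest-magnitude loading weight is positive.
#'
#' @slot loadings numeric matrix, components by wavenumbers.
#' @slot scores numeric matrix, observations by components.
#' @slot explainedVariancePct,cumulativeVariancePct numeric per component.
#' @slot meanSpectrum numeric, the column means removed before decomposition.
#' @slot scale numeric, the column scales (all 1 unless autoscaling).
#' @slot wavenumbers numeric channel positions.
#' @slot labels data.frame carried over from the input matrix.
#'
#' @seealso [runPCA()], [groupSeparation()]
#' @export
setClass("PCAResult",
  representation(
    loadings              = "matrix",
    scores                = "matrix",
    explainedVariancePct  = "numeric",
    cumulativeVariancePct = "numeric",
    meanSpectrum          = "numeric",
    scale                 = "numeric",
    wavenumbers           = "numeric",
    labels                = "data.frame"
  )
)

setValidity("PCAResult", function(object) {
  msg <- character()
  k <- nrow(object@loadings)
  if (ncol(object@scores) != k)
    msg <- c(msg, "scores and loadings disagree on component count")
  if (length(object@explainedVariancePct) != k ||
      length(object@cumulativeVariancePct) != k)
    msg <- c(msg, "variance vectors must have one entry per component")
  if (any(object@explainedVariancePct < -1e-12))
    msg <- c(msg, "explained variance must be non-negative")
  if (k > 1L && any(diff(object@explainedVariancePct) > 1e-9))
    msg <- c(msg, "explained variance must be non-increasing")
  if (any(object@cumulativeVariancePct > 100 + 1e-9))
    msg <- c(msg, "cumulative variance cannot exceed 100%")
  if (ncol(object@loadings) != length(object@wavenumbers))
    msg <- c(msg, "loadings columns must match wavenumbers")
  if (length(msg)) msg else TRUE
})
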