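#' @include AllClasses.R AllGenerics.R
NULL

#' Accessors for Spectrum objects
#'
#' @param x a [Spectrum-class].
#' @return `spectralAxis` and `intensity` return numeric vectors; `modality`
#'   a character scalar; `position` the `(x, y)` stage position in
#'   micrometres.
#' @name Spectrum-accessors
NULL

#' @rdname Spectrum-accessors
#' @export
setMethod("spectralAxis", "Spectrum", function(x) x@axis)

#' @rdname Spectrum-accessors
#' @export
setMethod("intensity", "Spectrum", function(x) x@intensity)

#' @rdname Spectrum-accessors
#' @export
setMethod("modality", "Spectrum", function(x) x@modality)

#' @rdname Spectrum-accessors
#' @export
setMethod("position", "Spectrum", function(x) x@position)

#' @rdname Spectrum-accessors
#' @export
setMethod("length", "Spectrum", function(x) length(x@axis))

setMethod("show", "Spectrum", function(object) {
  unit <- if (object@modality == "brillouin") "GHz" else "cm^-1"
  cat(sprintf("Spectrum (%s): %d channels, %.4g..%.4g %s\n",
              object@modality, length(object@axis),
              min(object@axis), max(object@axis), unit))
  if (!anyNA(object@position))
    cat(sprintf("  position: (%g, %g) um\n",
                object@position[1], object@position[2]))
})

#' Accessors for SpectralMap objects
#'
#' @param x a [SpectralMap-class].
#' @param row,col 0-based pixel indices.
#' @param modality `"brillouin"` or `"raman"`.
#' @return `gridStep` the spacing in micrometres; `gridOrigin` the `(x0, y0)`
#'   origin; `mapDim` the `(rows, cols)` grid shape; `hasModality` a logical
#'   rows-by-cols matrix of pixel presence; `getSpectrum` the requested
#'   [Spectrum-class] or `NULL` when absent at that pixel.
#' @name SpectralMap-accessors
NULL

#' @rdname SpectralMap-accessors
#' @export
setMethod("gridStep", "SpectralMap", function(x) x@step)

#' @rdname SpectralMap-accessors
#' @export
setMethod("gridOrigin", "SpectralMap", function(x) x@origin)

#' @rdname SpectralMap-accessors
#' @export
setMethod("mapDim", "SpectralMap", function(x) c(x@nrow, x@ncol))

.pixelIndex <- function(map, row, col) {
  stopifnot(row >= 0L, row < map@nrow, col >= 0L, col < map@ncol)
  row * map@ncol + col + 1L
}

#' @rdname SpectralMap-accessors
#' @export
setMethod("hasModality", "SpectralMap", function(x, modality) {
  mat <- slot(x, modality)
  present <- if (ncol(mat) == 0L) rep(FALSE, x@nrow * x@ncol)
             else !is.na(mat[, 1L])
  matrix(present, nrow = x@nrow, ncol = x@ncol, byrow = TRUE)
})

#' @rdname SpectralMap-accessors
#' @export
setMethod("getSpectrum", "SpectralMap", function(x, row, col, modality) {
  modality <- match.arg(modality, c("brillouin", "raman"))
  i <- .pixelIndex(x, row, col)
  mat <- slot(x, modality)
  if (ncol(mat) == 0L || is.na(mat[i, 1L])) return(NULL)
  axis <- if (modality == "brillouin") x@brillouinAxis else x@ramanAxis
  pos <- x@origin + c(col, row) * x@step
  spectrum(axis, mat[i, ], modality, position = pos)
})

setMethod("show", "SpectralMap", function(object) {
  cat(sprintf("SpectralMap: %d x %d pixels, step %g um\n",
              object@nrow, object@ncol, object@step))
  for (m in c("brillouin", "raman")) {
    mat <- slot(object, m)
    if (ncol(mat) > 0L)
      cat(sprintf("  %s: %d channels, %d/%d pixels present\n", m, ncol(mat),
                  sum(!is.na(mat[, 1L])), nrow(mat)))
  }
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig\n")
  cat(sprintf("  Brillouin bands: soft [%g, %g] GHz, hard (%g, %g] GHz\n",
              object@softRange[1], object@softRange[2],
              object@hardRange[1], object@hardRange[2]))
  cat(sprintf("  lambda %g nm, kappa %g g/cm^3, efficiency ratio %g\n",
              object@lambdaLaser, object@kappa, object@efficiencyRatio))
  cat(sprintf("  baseline: order %d, <= %d iterations\n",
              object@baselineOrder, object@baselineIters))
  cat(sprintf("  normalisation: %g +/- %g cm^-1\n",
              object@refWavenumber, object@refWindow))
  cat(sprintf("  fingerprint [%g, %g] cm^-1, CH [%g, %g], heme-amide [%g, %g]\n",
              object@fingerprintRange[1], object@fingerprintRange[2],
              object@chBand[1], object@chBand[2],
              object@hemeBand[1], object@hemeBand[2]))
})

#' Accessors for FeatureMap objects
#'
#' @param x a [FeatureMap-class].
#' @param feature feature name, one of `featureNames(x)`.
#' @return `featureNames` the character vector of stored features;
#'   `featureMatrix` the requested rows-by-cols numeric matrix.
#' @name FeatureMap-accessors
NULL

#' @rdname FeatureMap-accessors
#' @export
setMethod("featureNames", "FeatureMap", function(x) names(x@features))

#' @rdname FeatureMap-accessors
#' @export
setMethod("featureMatrix", "FeatureMap", function(x, feature) {
  if (!feature %in% names(x@features))
    stop("unknown feature: ", feature)
  x@features[[feature]]
})

#' @rdname FeatureMap-accessors
#' @export
setMethod("mapDim", "FeatureMap", function(x) dim(x@features[[1L]]))

#' @rdname FeatureMap-accessors
#' @export
setMethod("gridStep", "FeatureMap", function(x) x@step)

#' @rdname FeatureMap-accessors
#' @export
setMethod("gridOrigin", "FeatureMap", function(x) x@origin)

setMethod("show", "FeatureMap", function(object) {
  d <- dim(object@features[[1L]])
  cat(sprintf("FeatureMap: %d x %d pixels, %d features\n",
              d[1], d[2], length(object@features)))
  cat("  ", paste(names(object@features), collapse = ", "), "\n")
})

setMethod("show", "SpectralMatrix", function(object) {
  cat(sprintf("SpectralMatrix: %d spectra x %d channels (%g..%g cm^-1)\n",
              nrow(object@data), ncol(object@data),
              min(object@wavenumbers), max(object@wavenumbers)))
  tab <- table(object@labels$roi)
  cat("  ROIs:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

#' Accessors for PCAResult objects
#'
#' @param x a [PCAResult-class].
#' @param ... unused, for generic compatibility.
#' @return `scores` the observations-by-components matrix; `loadings` the
#'   components-by-wavenumbers matrix with orthonormal rows;
#'   `explainedVariance` / `cumulativeVariance` percentages per component.
#' @name PCAResult-accessors
NULL

#' @rdname PCAResult-accessors
#' @export
setMethod("scores", "PCAResult", function(x) x@scores)

#' @rdname PCAResult-accessors
#' @export
setMethod("loadings", "PCAResult", function(x, ...) x@loadings)

#' @rdname PCAResult-accessors
#' @export
setMethod("explainedVariance", "PCAResult",
          function(x) x@explainedVariancePct)

#' @rdname PCAResult-accessors
#' @export
setMethod("cumulativeVariance", "PCAResult",
          function(x) x@cumulativeVariancePct)

setMethod("show", "PCAResult", function(object) {
  k <- nrow(object@loadings)
  cat(sprintf("PCAResult: %d components over %d channels, %d observations\n",
              k, ncol(object@loadings), nrow(object@scores)))
  cat("  explained variance (%):",
      paste(sprintf("%.1f", object@explainedVariancePct), collapse = ", "),
      "\n")
  cat("  cumulative (%):       ",
      paste(sprintf("%.1f", object@cumulativeVariancePct), collapse = ", "),
      "\n")
})
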