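#' @include AllClasses.R
NULL

#' @rdname Spectrum-accessors
#' @export
setGeneric("spectralAxis", function(x) standardGeneric("spectralAxis"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("position", function(x) standardGeneric("position"))

#' @rdname SpectralMap-accessors
#' @export
setGeneric("gridStep", function(x) standardGeneric("gridStep"))

#' @rdname SpectralMap-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname SpectralMap-accessors
#' @export
setGeneric("mapDim", function(x) standardGeneric("mapDim"))

#' @rdname SpectralMap-accessors
#' @export
setGeneric("getSpectrum", function(x, row, col, modality)
  standardGeneric("getSpectrum"))

#' @rdname SpectralMap-accessors
#' @export
setGeneric("hasModality", function(x, modality)
  standardGeneric("hasModality"))

#' @rdname FeatureMap-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname FeatureMap-accessors
#' @export
setGeneric("featureMatrix", function(x, feature)
  standardGeneric("featureMatrix"))

#' @rdname PCAResult-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname PCAResult-accessors
#' @importFrom stats loadings
#' @export
setGeneric("loadings")

#' @rdname PCAResult-accessors
#' @export
setGeneric("explainedVariance", function(x)
  standardGeneric("explainedVariance"))

#' @rdname PCAResult-accessors
#' @export
setGeneric("cumulativeVariance", function(x)
  standardGeneric("cumulativeVariance"))
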