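#' @include AllClasses.R
NULL

#' Accessors for FLIMStack layers and metadata
#'
#' @param x a [FLIMStack-class] object.
#' @return the requested layer (numeric matrix) or metadata scalar.
#' @examples
#' stk <- deriveLifetimeLayers(matrix(100, 4, 4), matrix(0.3, 4, 4),
#'                             matrix(0.9, 4, 4), modFreqHz = 30e6)
#' dim(intensityLayer(stk))
#' modFreq(stk)
#' @name FLIMStack-accessors
NULL

#' @rdname FLIMStack-accessors
#' @export
setGeneric("intensityLayer", function(x) standardGeneric("intensityLayer"))
#' @rdname FLIMStack-accessors
#' @export
setGeneric("phaseLayer", function(x) standardGeneric("phaseLayer"))
#' @rdname FLIMStack-accessors
#' @export
setGeneric("modIndexLayer", function(x) standardGeneric("modIndexLayer"))
#' @rdname FLIMStack-accessors
#' @export
setGeneric("tauPhaseLayer", function(x) standardGeneric("tauPhaseLayer"))
#' @rdname FLIMStack-accessors
#' @export
setGeneric("tauModLayer", function(x) standardGeneric("tauModLayer"))
#' @rdname FLIMStack-accessors
#' @export
setGeneric("modFreq", function(x) standardGeneric("modFreq"))
#' @rdname FLIMStack-accessors
#' @export
setGeneric("magnification", function(x) standardGeneric("magnification"))
#' @rdname FLIMStack-accessors
#' @export
setGeneric("emissionFilter", function(x) standardGeneric("emissionFilter"))

#' Physical size of a projected pixel
#'
#' The camera sensor pixel (5.6 um edge by default) is demagnified by
#' the objective, so the sample-plane pixel edge is
#' \code{sensorPixelUm / magnification}: 0.28 um at 20x, 0.56 um at
#' 10x, 2.8 um at 2x.
#'
#' @param x a magnification factor (numeric) or a [FLIMStack-class]
#'   whose metadata supplies it.
#' @param ... for the numeric method, \code{sensorPixelUm} (default
#'   5.6).
#' @return pixel edge length in micrometres.
#' @examples
#' pixelSizeUm(20)   # 0.28
#' pixelSizeUm(2)    # 2.8
#' @export
setGeneric("pixelSizeUm", function(x, ...) standardGeneric("pixelSizeUm"))

#' Accessors for Gaussian fits and material ranges
#'
#' @param x a [GaussianFit-class] or [MaterialRange-class] object.
#' @return the requested component.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
setGeneric("fitMu", function(x) standardGeneric("fitMu"))
#' @rdname fit-accessors
#' @export
setGeneric("fitSigma", function(x) standardGeneric("fitSigma"))
#' @rdname fit-accessors
#' @export
setGeneric("fitN", function(x) standardGeneric("fitN"))
#' @rdname fit-accessors
#' @export
setGeneric("materialName", function(x) standardGeneric("materialName"))
#' @rdname fit-accessors
#' @export
setGeneric("rangeLo", function(x) standardGeneric("rangeLo"))
#' @rdname fit-accessors
#' @export
setGeneric("rangeHi", function(x) standardGeneric("rangeHi"))

#' Accessors for classification results
#'
#' @param x a [ClassificationResult-class] object.
#' @param material a material name; if missing, all materials.
#' @return \code{shares()}: named percent vector; \code{materialFit()}:
#'   a [GaussianFit-class] or named list of them; \code{cleanedMask()}
#'   / \code{rawMask()}: 0/1 matrices; \code{particleTable()}: a
#'   data frame of particle measurements.
#' @name ClassificationResult-accessors
NULL

#' @rdname ClassificationResult-accessors
#' @export
setGeneric("shares", function(x) standardGeneric("shares"))
#' @rdname ClassificationResult-accessors
#' @export
setGeneric("materialFit", function(x, material) standardGeneric("materialFit"))
#' @rdname ClassificationResult-accessors
#' @export
setGeneric("cleanedMask", function(x, material) standardGeneric("cleanedMask"))
#' @rdname ClassificationResult-accessors
#' @export
setGeneric("rawMask", function(x, material) standardGeneric("rawMask"))
#' @rdname ClassificationResult-accessors
#' @export
setGeneric("particleTable", function(x, material) standardGeneric("particleTable"))
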