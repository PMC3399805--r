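#' @rdname mip
#' @export
setGeneric("mip", function(volume, axis = "axial") standardGeneric("mip"))

#' @rdname kmeansBinarize
#' @export
setGeneric("kmeansBinarize", function(image) standardGeneric("kmeansBinarize"))

#' @rdname skeletonize
#' @export
setGeneric("skeletonize", function(image) standardGeneric("skeletonize"))

#' @rdname splitHemispheres
#' @export
setGeneric("splitHemispheres",
           function(image) standardGeneric("splitHemispheres"))

#' @rdname boxCounts
#' @export
setGeneric("boxCounts",
           function(image, anchor = c(0L, 0L)) standardGeneric("boxCounts"))

#' @rdname minkowskiAreas
#' @export
setGeneric("minkowskiAreas",
           function(image, nMax = 20L) standardGeneric("minkowskiAreas"))

#' @rdname partitionMoments
#' @export
setGeneric("partitionMoments",
           function(image, q = seq(0, 5, by = 0.25), boxSizes = NULL)
             standardGeneric("partitionMoments"))

#' @rdname generalizedSpectrum
#' @export
setGeneric("generalizedSpectrum",
           function(x, q = seq(0, 5, by = 0.25), rThreshold = 0.995, ...)
             standardGeneric("generalizedSpectrum"))

#' @rdname maxSlope
#' @export
setGeneric("maxSlope", function(curve) standardGeneric("maxSlope"))

#' Extract the pixel matrix of an image
#'
#' @param object a [GrayImage-class] or [BinaryImage-class].
#' @return the underlying matrix (rows = height, columns = width).
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' Number of foreground (vessel) pixels
#'
#' @param object a [BinaryImage-class].
#' @return integer foreground count.
#' @export
setGeneric("foregroundCount",
           function(object) standardGeneric("foregroundCount"))

#' Scales of a scaling curve
#' @param object a [ScalingCurve-class].
#' @return numeric vector of scales.
#' @export
setGeneric("scales", function(object) standardGeneric("scales"))

#' Measures of a scaling curve
#' @param object a [ScalingCurve-class].
#' @return numeric vector of measures.
#' @export
setGeneric("measures", function(object) standardGeneric("measures"))

#' Fitted dimension value
#' @param object an [FDEstimate-class].
#' @return the dimension estimate.
#' @export
setGeneric("fdValue", function(object) standardGeneric("fdValue"))

#' Fit correlation coefficient
#' @param object an [FDEstimate-class] or [GeneralizedSpectrum-class].
#' @return Pearson R of the log-log fit (per q for spectra).
#' @export
setGeneric("fitR", function(object) standardGeneric("fitR"))

#' Moment orders of a spectrum
#' @param object a [GeneralizedSpectrum-class] or [PartitionMoments-class].
#' @return numeric vector of q values.
#' @export
setGeneric("qGrid", function(object) standardGeneric("qGrid"))

#' Generalized dimension values
#' @param object a [GeneralizedSpectrum-class].
#' @return numeric vector of D_q, parallel to [qGrid()].
#' @export
setGeneric("dqValues", function(object) standardGeneric("dqValues"))
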