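## Constructors, accessors and show methods.

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of nonnegative intensities (rows = height).
#' @return a [GrayImage-class].
#' @examples
#' img <- GrayImage(matrix(runif(12), 3, 4))
#' dim(img)
#' @export
GrayImage <- function(pixels) {
  new("GrayImage", pixels = .asNumericMatrix(pixels))
}

#' Construct a BinaryImage
#'
#' @param pixels matrix of 0/1 (or logical) values, rows = height.
#' @return a [BinaryImage-class].
#' @examples
#' img <- BinaryImage(diag(5))
#' foregroundCount(img)
#' @export
BinaryImage <- function(pixels) {
  m <- .asNumericMatrix(pixels)
  storage.mode(m) <- "integer"
  new("BinaryImage", pixels = m)
}

#' Construct a Volume3D
#'
#' @param voxels 3-D numeric array of nonnegative intensities.
#' @param axes labels for the three array axes, in array order.
#' @return a [Volume3D-class].
#' @export
Volume3D <- function(voxels, axes = c("axial", "coronal", "sagittal")) {
  new("Volume3D", voxels = voxels, axes = axes)
}

#' Construct a ScalingCurve
#'
#' @param scales strictly increasing positive scales.
#' @param measures positive measures, same length.
#' @param method "box" or "minkowski".
#' @return a [ScalingCurve-class].
#' @export
scalingCurve <- function(scales, measures, method) {
  new("ScalingCurve", scales = as.numeric(scales),
      measures = as.numeric(measures), method = method)
}

#' Construct an IntensityTimeCurve
#'
#' @param times strictly increasing, uniformly spaced times (s).
#' @param intensities signal values, same length.
#' @return an [IntensityTimeCurve-class].
#' @export
intensityTimeCurve <- function(times, intensities) {
  new("IntensityTimeCurve", times = as.numeric(times),
      intensities = as.numeric(intensities))
}

.asNumericMatrix <- function(pixels) {
  if (is.logical(pixels)) pixels <- pixels * 1L
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  storage.mode(pixels) <- "double"
  pixels
}

#' @describeIn pixels pixel matrix of a grayscale image
#' @export
setMethod("pixels", "GrayImage", function(object) object@pixels)

#' @describeIn pixels pixel matrix of a binary image
#' @export
setMethod("pixels", "BinaryImage", function(object) object@pixels)

#' @export
setMethod("dim", "GrayImage", function(x) dim(x@pixels))

#' @export
setMethod("dim", "BinaryImage", function(x) dim(x@pixels))

#' @export
setMethod("dim", "Volume3D", function(x) dim(x@voxels))

#' @describeIn foregroundCount foreground pixel count
#' @export
setMethod("foregroundCount", "BinaryImage",
          function(object) sum(object@pixels))

#' @describeIn scales scales slot
#' @export
setMethod("scales", "ScalingCurve", function(object) object@scales)

#' @describeIn measures measures slot
#' @export
setMethod("measures", "ScalingCurve", function(object) object@measures)

#' @describeIn fdValue dimension value of an estimate
#' @export
setMethod("fdValue", "FDEstimate", function(object) object@value)

#' @describeIn fitR fit R of a dimension estimate
#' @export
setMethod("fitR", "FDEstimate", function(object) object@fitR)

#' @describeIn fitR per-q fit R of a spectrum
#' @export
setMethod("fitR", "GeneralizedSpectrum", function(object) object@fitR)

#' @describeIn qGrid q grid of a spectrum
#' @export
setMethod("qGrid", "GeneralizedSpectrum", function(object) object@q)

#' @describeIn qGrid moment orders of partition moments
#' @export
setMethod("qGrid", "PartitionMoments", function(object) object@q)

#' @describeIn dqValues D_q values of a spectrum
#' @export
setMethod("dqValues", "GeneralizedSpectrum", function(object) object@Dq)

setMethod("show", "GrayImage", function(object) {
  d <- dim(object)
  cat(sprintf("GrayImage: %d x %d (W x H), intensity range [%g, %g]\n",
              d[2L], d[1L], min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryImage", function(object) {
  d <- dim(object)
  cat(sprintf("BinaryImage: %d x %d (W x H), %d foreground pixels (%.2f%%)\n",
              d[2L], d[1L], foregroundCount(object),
              100 * mean(object@pixels)))
})

setMethod("show", "Volume3D", function(object) {
  d <- dim(object)
  cat(sprintf("Volume3D: %d x %d x %d (%s)\n", d[1L], d[2L], d[3L],
              paste(object@axes, collapse = " x ")))
})

setMethod("show", "ScalingCurve", function(object) {
  cat(sprintf("ScalingCurve (%s): %d points, scales %g..%g\n",
              object@method, length(object@scales), min(object@scales),
              max(object@scales)))
})

setMethod("show", "FDEstimate", function(object) {
  r <- object@range
  cat(sprintf("FDEstimate (%s): D = %.4f  [fit R = %.4f, points %d..%d%s]\n",
              object@method, object@value, object@fitR, r@first, r@last,
              if (r@flagged) ", flagged" else ""))
})

setMethod("show", "GeneralizedSpectrum", function(object) {
  cat(sprintf("GeneralizedSpectrum: %d q values in [%g, %g]\n",
              length(object@q), min(object@q), max(object@q)))
  for (qq in c(0, 1, 2)) {
    i <- which(abs(object@q - qq) < 1e-9)
    if (length(i) == 1L)
      cat(sprintf("  D_%g = %.4f\n", qq, object@Dq[i]))
  }
})

setMethod("show", "SyntheticSubject", function(object) {
  cat(sprintf("SyntheticSubject %s (%s)%s: branches L=%d R=%d\n",
              object@id, object@group,
              if (object@group == "patient")
                paste0(", AVM ", object@avmSide) else "",
              object@branchCounts["left"], object@branchCounts["right"]))
})

setMethod("show", "CohortReport", function(object) {
  cat("CohortReport\n")
  cat(sprintf("  %d subjects, %d dimension values\n",
              nrow(object@subjects), nrow(object@fdTable)))
  cat("  summary (mean +/- SEM):\n")
  s <- object@summaryTable
  for (i in seq_len(min(nrow(s), 12L)))
    cat(sprintf("    %-10s %-8s %.3f +/- %.3f\n", s$region[i], s$method[i],
                s$mean[i], s$sem[i]))
  if (nrow(object@correlations))
    cat(sprintf("  %d correlations computed\n", nrow(object@correlations)))
})
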