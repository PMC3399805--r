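## Central S4 containers. Pixel grids are stored as plain integer/numeric
## matrices in the usual R orientation: rows = image height (y, top row first),
## columns = image width (x, leftmost column first), 1-based indices. The
## "W x H" notation used in the docs therefore maps to an H-row, W-column
## matrix.

#' GrayImage: a nonnegative-intensity 2-D raster
#'
#' Container for a grayscale image, typically a maximum intensity projection
#' of an angiographic volume. Intensities must be finite and nonnegative.
#'
#' @slot pixels numeric matrix, rows = height, columns = width.
#' @seealso [GrayImage()], [kmeansBinarize()]
#' @export
setClass("GrayImage", representation(pixels = "matrix"))

setValidity("GrayImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1x1")
  if (any(!is.finite(p))) return("intensities must be finite")
  if (any(p < 0)) return("intensities must be nonnegative")
  TRUE
})

#' BinaryImage: a 0/1 foreground raster
#'
#' The universal input to the fractal estimators. Foreground (vessel) pixels
#' are 1, background 0.
#'
#' @slot pixels integer matrix of 0s and 1s, rows = height, columns = width.
#' @seealso [BinaryImage()], [boxCounts()], [minkowskiAreas()],
#'   [generalizedSpectrum()]
#' @export
setClass("BinaryImage", representation(pixels = "matrix"))

setValidity("BinaryImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (nrow(p) < 1L || ncol(p) < 1L) return("image must be at least 1x1")
  if (any(!(p == 0 | p == 1))) return("pixels must all be 0 or 1")
  TRUE
})

#' Volume3D: a 3-D intensity volume
#'
#' @slot voxels numeric 3-D array.
#' @slot axes character vector of length 3 naming the array axes, in array
#'   order. Defaults to c("axial", "coronal", "sagittal") so that the first
#'   axis carries the axial projection direction.
#' @seealso [Volume3D()], [mip()]
#' @export
setClass("Volume3D", representation(voxels = "array", axes = "character"))

setValidity("Volume3D", function(object) {
  v <- object@voxels
  if (length(dim(v)) != 3L) return("voxels must be a 3-D array")
  if (any(dim(v) < 1L)) return("all volume dimensions must be >= 1")
  if (any(!is.finite(v))) return("intensities must be finite")
  if (length(object@axes) != 3L) return("axes must name the three array axes")
  if (anyDuplicated(object@axes)) return("axis labels must be distinct")
  TRUE
})

#' ScalingCurve: ordered (scale, measure) pairs
#'
#' Backs every log-log regression in the package: box sizes and occupied-box
#' counts for the box-counting method, dilation radii and dilated foreground
#' areas for the Minkowski method.
#'
#' @slot scales strictly increasing positive numeric (epsilon or r).
#' @slot measures positive numeric of the same length (N(epsilon) or A(r)).
#' @slot method "box" or "minkowski".
#' @seealso [scalingCurve()], [selectLinearRange()], [fitDimension()]
#' @export
setClass("ScalingCurve",
         representation(scales = "numeric", measures = "numeric",
                        method = "character"))

setValidity("ScalingCurve", function(object) {
  s <- object@scales; m <- object@measures
  if (length(s) != length(m)) return("scales and measures must match in length")
  if (length(s) < 3L) return("a scaling curve needs at least 3 points")
  if (any(!is.finite(s)) || any(s <= 0)) return("scales must be positive")
  if (any(diff(s) <= 0)) return("scales must be strictly increasing")
  if (any(!is.finite(m)) || any(m <= 0)) return("measures must be positive")
  if (!object@method %in% c("box", "minkowski"))
    return("method must be 'box' or 'minkowski'")
  TRUE
})

#' RegressionRange: a contiguous window into a ScalingCurve
#'
#' @slot first,last integer indices into the curve (last - first >= 2, so the
#'   window holds at least three points).
#' @slot flagged TRUE when no window of length >= 3 reached the correlation
#'   threshold and the best length-3 window was returned instead.
#' @seealso [selectLinearRange()]
#' @export
setClass("RegressionRange",
         representation(first = "integer", last = "integer",
                        flagged = "logical"))

setValidity("RegressionRange", function(object) {
  if (length(object@first) != 1L || length(object@last) != 1L)
    return("first and last must be scalars")
  if (object@first < 1L) return("first index must be >= 1")
  if (object@last - object@first < 2L)
    return("a regression range must span at least 3 points")
  TRUE
})

#' FDEstimate: a fitted fractal dimension with its regression metadata
#'
#' @slot value the dimension estimate (dimensionless; in [0, 2] for 2-D
#'   inputs).
#' @slot method "box" or "minkowski".
#' @slot fitR Pearson correlation of the log-log fit over the range used.
#' @slot range the [RegressionRange-class] actually used.
#' @slot intercept intercept of the log-log regression.
#' @slot curve the full [ScalingCurve-class] the fit was taken from.
#' @seealso [fitDimension()], [boxDimension()], [minkowskiDimension()]
#' @export
setClass("FDEstimate",
         representation(value = "numeric", method = "character",
                        fitR = "numeric", range = "RegressionRange",
                        intercept = "numeric", curve = "ScalingCurve"))

setValidity("FDEstimate", function(object) {
  if (length(object@value) != 1L || !is.finite(object@value))
    return("value must be a finite scalar")
  if (abs(object@fitR) > 1 + 1e-8) return("|fit R| must be <= 1")
  TRUE
})

#' PartitionMoments: normalized box-mass moments of a binary image
#'
#' For each dyadic box size l and moment order q, stores
#' M(q, l) = sum_i (M_i / M_0)^q over occupied boxes, where M_i is the
#' foreground pixel count in box i and M_0 the total foreground count.
#' M(0, l) is the occupied-box count and M(1, l) is exactly 1.
#'
#' @slot boxSizes dyadic box sizes l.
#' @slot q moment orders (all >= 0).
#' @slot moments matrix of M(q, l), rows = q, columns = box sizes.
#' @slot entropy per box size, sum_i mu_i * log(mu_i) (natural log), the
#'   quantity whose scaling slope gives the information dimension D_1.
#' @slot mass total foreground count M_0.
#' @slot extent image extent L = max(width, height).
#' @seealso [partitionMoments()], [generalizedSpectrum()]
#' @export
setClass("PartitionMoments",
         representation(boxSizes = "numeric", q = "numeric",
                        moments = "matrix", entropy = "numeric",
                        mass = "numeric", extent = "numeric"))

setValidity("PartitionMoments", function(object) {
  if (any(object@q < 0)) return("moment orders q must be >= 0")
  if (nrow(object@moments) != length(object@q) ||
      ncol(object@moments) != length(object@boxSizes))
    return("moments matrix must be q x boxSizes")
  if (length(object@entropy) != length(object@boxSizes))
    return("entropy must have one entry per box size")
  TRUE
})

#' GeneralizedSpectrum: the Renyi dimension spectrum D_q
#'
#' @slot q the evaluation grid (default 0 to 5 in steps of 0.25).
#' @slot Dq the generalized dimensions.
#' @slot fitR per-q Pearson correlation of the underlying log-log fit.
#' @slot range the box-size [RegressionRange-class] shared by all q.
#' @seealso [generalizedSpectrum()]
#' @export
setClass("GeneralizedSpectrum",
         representation(q = "numeric", Dq = "numeric", fitR = "numeric",
                        range = "RegressionRange"))

setValidity("GeneralizedSpectrum", function(object) {
  if (length(object@q) != length(object@Dq) ||
      length(object@q) != length(object@fitR))
    return("q, Dq and fitR must have equal length")
  if (any(!is.finite(object@Dq))) return("D_q must be finite")
  TRUE
})

#' IntensityTimeCurve: a uniformly sampled contrast-transit curve
#'
#' @slot times sample times in seconds, strictly increasing, uniform step.
#' @slot intensities signal intensities (arbitrary units).
#' @seealso [intensityTimeCurve()], [maxSlope()]
#' @export
setClass("IntensityTimeCurve",
         representation(times = "numeric", intensities = "numeric"))

setValidity("IntensityTimeCurve", function(object) {
  t <- object@times
  if (length(t) < 3L) return("a curve needs at least 3 samples")
  if (length(t) != length(object@intensities))
    return("times and intensities must match in length")
  dt <- diff(t)
  if (any(dt <= 0)) return("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-8 * max(dt))
    return("sampling must be uniform")
  TRUE
})

#' SyntheticSubject: one simulated study participant
#'
#' Holds the paired hemisphere images plus the physiological covariates the
#' study pipeline consumes. For patients, the hemisphere carrying the
#' simulated malformation has strictly more branches than the contralateral
#' one; controls are symmetric and carry no AVM side.
#'
#' @slot id subject identifier.
#' @slot group "patient" or "control".
#' @slot left,right the hemisphere images (each 182 wide x 436 high by
#'   default).
#' @slot avmSide "left", "right", or NA_character_ for controls.
#' @slot branchCounts named numeric, ground-truth branch counts for left and
#'   right.
#' @slot curve the subject's [IntensityTimeCurve-class].
#' @slot nidusDiameters four diameters in cm (two views x min/max); all NA
#'   for controls.
#' @seealso [generateCohort()]
#' @export
setClass("SyntheticSubject",
         representation(id = "character", group = "character",
                        left = "BinaryImage", right = "BinaryImage",
                        avmSide = "character", branchCounts = "numeric",
                        curve = "IntensityTimeCurve",
                        nidusDiameters = "numeric"))

setValidity("SyntheticSubject", function(object) {
  if (!object@group %in% c("patient", "control"))
    return("group must be 'patient' or 'control'")
  if (!all(c("left", "right") %in% names(object@branchCounts)))
    return("branchCounts must be named 'left' and 'right'")
  if (object@group == "patient") {
    if (!object@avmSide %in% c("left", "right"))
      return("patients must have avmSide 'left' or 'right'")
    other <- setdiff(c("left", "right"), object@avmSide)
    if (!(object@branchCounts[object@avmSide] >
          object@branchCounts[other]))
      return("the AVM side must have strictly more branches")
    if (length(object@nidusDiameters) != 4L ||
        any(!is.finite(object@nidusDiameters)) ||
        any(object@nidusDiameters <= 0))
      return("patients need four positive nidus diameters")
  }
  TRUE
})

#' CohortReport: the full study output
#'
#' @slot fdTable long-format data.frame (subject, group, hemisphere, role,
#'   method, value) with one row per subject x region x dimension estimate.
#' @slot summaryTable group means and SEM per method and region, Table-style.
#' @slot pairedTests paired hemisphere contrasts (AVM vs non-AVM in patients,
#'   left vs right in controls) per method.
#' @slot correlations AVM-side dimension vs physiology correlations
#'   (r, p, n, slope, intercept).
#' @slot sampleSizes Fisher-z sample sizes per method and covariate.
#' @slot subjects per-subject covariates (max slope, nidus diameter, branch
#'   counts).
#' @slot settings the configuration list the report was generated from.
#' @seealso [runStudy()]
#' @export
setClass("CohortReport",
         representation(fdTable = "data.frame", summaryTable = "data.frame",
                        pairedTests = "data.frame",
                        correlations = "data.frame",
                        sampleSizes = "data.frame", subjects = "data.frame",
                        settings = "list"))
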