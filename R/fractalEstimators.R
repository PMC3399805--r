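## Box-counting and Minkowski (dilation) dimension estimators with
## correlation-threshold selection of the log-log scaling range.

.dyadicSizes <- function(H, W) {
  2^(0:floor(log2(max(H, W))))
}

## occupied-box count for one box size, grid anchored at the top-left pixel
## shifted by `anchor` = c(rowOffset, colOffset)
.occupiedBoxes <- function(coords, eps, anchor = c(0L, 0L)) {
  ci <- (coords[, 1L] - 1L + anchor[1L]) %/% eps
  cj <- (coords[, 2L] - 1L + anchor[2L]) %/% eps
  length(unique(ci * (max(cj) + 1) + cj))
}

#' Box counts over a dyadic series of box sizes
#'
#' Covers the image with a grid of square boxes of side epsilon = 2^n
#' (n = 0, 1, 2, ... while epsilon <= max(W, H)) anchored at the top-left
#' corner, and counts the boxes containing at least one foreground pixel.
#' Partial boxes at the right and bottom edges count as boxes. The grid
#' anchor is configurable because for image sides that are not powers of
#' two the count — and hence the fitted dimension — depends on where the
#' grid originates; the default anchor is the top-left pixel.
#'
#' @param image a nonempty [BinaryImage-class].
#' @param anchor integer grid-origin offset c(rowOffset, colOffset).
#' @return a [ScalingCurve-class] (method "box") with scales = epsilon and
#'   measures = N(epsilon). N is strictly positive and non-increasing;
#'   N(1) equals the foreground count.
#' @examples
#' full <- BinaryImage(matrix(1L, 64, 64))
#' measures(boxCounts(full))  # (64/eps)^2
#' @rdname boxCounts
#' @export
setMethod("boxCounts", "BinaryImage", function(image, anchor = c(0L, 0L)) {
  px <- image@pixels
  if (sum(px) == 0L) stop("no foreground")
  coords <- which(px == 1L, arr.ind = TRUE)
  sizes <- .dyadicSizes(nrow(px), ncol(px))
  counts <- vapply(sizes, function(eps)
    .occupiedBoxes(coords, eps, anchor), numeric(1))
  scalingCurve(sizes, counts, "box")
})

#' Dilated foreground areas (Minkowski "sausage" curve)
#'
#' Dilates the foreground with square structuring elements of side 2n + 1
#' for n = 0..nMax and records the covered area A(r_n) at each radius
#' r_n = (2n + 1) / 2. Dilation is clipped at the canvas, so A is bounded
#' by W * H; A(r_0) is the foreground count. Only the regression slope of
#' log A versus log r matters downstream, so any proportional redefinition
#' of the radius leaves the fitted dimension unchanged.
#'
#' @param image a nonempty [BinaryImage-class].
#' @param nMax largest structuring-element index n; must be >= 2. The
#'   default (NULL) uses 20 — the standard protocol for study-sized
#'   images — capped so that the largest structuring element stays below
#'   about one sixth of the image extent, since dilation radii beyond the
#'   self-similar range of a small object bias the fitted dimension.
#' @return a [ScalingCurve-class] (method "minkowski") with scales = r_n and
#'   measures = A(r_n), non-decreasing.
#' @examples
#' one <- matrix(0L, 64, 64); one[32, 32] <- 1L
#' measures(minkowskiAreas(BinaryImage(one), nMax = 3))  # (2n+1)^2
#' @rdname minkowskiAreas
#' @export
setMethod("minkowskiAreas", "BinaryImage", function(image, nMax = NULL) {
  px <- image@pixels
  if (sum(px) == 0L) stop("no foreground")
  if (is.null(nMax)) nMax <- .defaultNMax(px)
  nMax <- as.integer(nMax)
  if (nMax < 2L) stop("nMax must be >= 2")
  areas <- numeric(nMax + 1L)
  areas[1L] <- sum(px)
  cur <- px
  brush <- EBImage::makeBrush(3L, shape = "box")
  for (n in seq_len(nMax)) {
    cur <- EBImage::dilate(cur, brush)  # n-fold 3x3 dilation == side 2n+1
    areas[n + 1L] <- sum(cur)
  }
  scalingCurve((2 * (0:nMax) + 1) / 2, areas, "minkowski")
})

## default dilation budget: n = 20 (squares up to side 41), capped so the
## largest structuring element side (2n + 1) stays below ~1/6 of the image
## extent on small canvases
.defaultNMax <- function(px) {
  max(2L, min(20L, as.integer((max(dim(px)) / 6 - 1) %/% 2)))
}

## |Pearson R| of the log-log points in window [i, j]; a perfectly flat
## measure is exactly log-linear (slope 0), so it scores 1.
.windowAbsR <- function(ls, lmens, i, j) {
  y <- lmens[i:j]
  if (sd(y) == 0) return(1)
  abs(cor(ls[i:j], y))
}

#' Select the log-log scaling range by a correlation threshold
#'
#' Natural structures in digital rasters scale linearly only over part of
#' the accessible range, so fitting all points would bias the dimension.
#' This picks the longest contiguous window of curve points whose log-log
#' Pearson |R| reaches `rThreshold` (default 0.995). Ties between windows
#' of equal length are broken toward the smaller starting scale. If no
#' window of at least three points qualifies, the length-3 window with the
#' highest |R| is returned with `flagged = TRUE`.
#'
#' @param curve a [ScalingCurve-class] with >= 3 points.
#' @param rThreshold correlation threshold in (0, 1).
#' @return a [RegressionRange-class].
#' @examples
#' cv <- scalingCurve(2^(0:6), 2^(2 * (6:0)), "box")  # exact power law
#' selectLinearRange(cv)  # full range
#' @export
selectLinearRange <- function(curve, rThreshold = 0.995) {
  stopifnot(is(curve, "ScalingCurve"))
  if (rThreshold <= 0 || rThreshold >= 1)
    stop("rThreshold must be in (0, 1)")
  ls <- log(curve@scales)
  lmens <- log(curve@measures)
  n <- length(ls)
  for (len in n:3) {
    for (start in 1:(n - len + 1L)) {
      if (.windowAbsR(ls, lmens, start, start + len - 1L) >= rThreshold) {
        return(new("RegressionRange", first = as.integer(start),
                   last = as.integer(start + len - 1L), flagged = FALSE))
      }
    }
  }
  rs <- vapply(1:(n - 2L), function(s) .windowAbsR(ls, lmens, s, s + 2L),
               numeric(1))
  best <- which.max(rs)
  new("RegressionRange", first = as.integer(best),
      last = as.integer(best + 2L), flagged = TRUE)
}

#' Fit a fractal dimension from a scaling curve
#'
#' Ordinary least squares of log(measure) on log(scale) within the selected
#' range. For the box method the dimension is minus the slope of
#' log N(epsilon) versus log epsilon; for the Minkowski method the
#' dilated-area convention gives D_m = 2 - slope of log A(r) versus log r.
#'
#' @param curve a [ScalingCurve-class].
#' @param range a [RegressionRange-class]; defaults to
#'   [selectLinearRange()] with the standard 0.995 threshold.
#' @return an [FDEstimate-class] carrying the dimension, the fit R, the
#'   intercept, and the range and curve used.
#' @examples
#' cv <- boxCounts(BinaryImage(matrix(1L, 64, 64)))
#' fdValue(fitDimension(cv))  # 2
#' @export
fitDimension <- function(curve, range = selectLinearRange(curve)) {
  stopifnot(is(curve, "ScalingCurve"), is(range, "RegressionRange"))
  if (range@last > length(curve@scales))
    stop("range exceeds curve length")
  idx <- range@first:range@last
  x <- log(curve@scales[idx])
  y <- log(curve@measures[idx])
  if (sd(x) == 0) stop("degenerate regression: zero variance in log scales")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  value <- switch(curve@method, box = -slope, minkowski = 2 - slope)
  r <- if (sd(y) == 0) 1 else cor(x, y)
  new("FDEstimate", value = value, method = curve@method, fitR = r,
      range = range, intercept = unname(coef(fit)[1L]), curve = curve)
}

#' Box-counting dimension of a binary image
#'
#' Convenience wrapper: [boxCounts()] then [selectLinearRange()] then
#' [fitDimension()].
#'
#' @param image a nonempty [BinaryImage-class].
#' @param rThreshold correlation threshold for the range selection.
#' @param anchor grid-origin offset, see [boxCounts()].
#' @return an [FDEstimate-class] (method "box").
#' @export
boxDimension <- function(image, rThreshold = 0.995, anchor = c(0L, 0L)) {
  curve <- boxCounts(image, anchor = anchor)
  fitDimension(curve, selectLinearRange(curve, rThreshold))
}

#' Minkowski (dilation) dimension of a binary image
#'
#' Convenience wrapper: [minkowskiAreas()] then [selectLinearRange()] then
#' [fitDimension()].
#'
#' @param image a nonempty [BinaryImage-class].
#' @param nMax largest structuring-element index, see [minkowskiAreas()].
#' @param rThreshold correlation threshold for the range selection.
#' @return an [FDEstimate-class] (method "minkowski").
#' @export
minkowskiDimension <- function(image, nMax = NULL, rThreshold = 0.995) {
  curve <- minkowskiAreas(image, nMax = nMax)
  fitDimension(curve, selectLinearRange(curve, rThreshold))
}

#' Log-log diagnostic plot of a scaling curve
#'
#' Plots log(measure) against log(scale), marks the points inside the
#' fitted range and overlays the regression line — the standard diagnostic
#' for judging the scaling regime of an estimate.
#'
#' @param x an [FDEstimate-class].
#' @param y ignored.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
setMethod("plot", signature(x = "FDEstimate", y = "missing"),
          function(x, y, ...) {
  cv <- x@curve
  ls <- log(cv@scales); lmens <- log(cv@measures)
  idx <- x@range@first:x@range@last
  plot(ls, lmens, xlab = "log scale", ylab = "log measure",
       main = sprintf("%s dimension: D = %.3f (R = %.4f)", cv@method,
                      x@value, x@fitR), ...)
  points(ls[idx], lmens[idx], pch = 19)
  slope <- switch(cv@method, box = -x@value, minkowski = 2 - x@value)
  abline(x@intercept, slope, lty = 2)
  invisible(x)
})
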