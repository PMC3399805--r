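## Image operations: projection, segmentation, thinning, hemisphere split.

#' Maximum intensity projection
#'
#' Collapses a 3-D volume to a 2-D image by taking, for each pixel of the
#' projection plane, the maximum intensity along the projected axis. The
#' default projects along the first array axis ("axial").
#'
#' @param volume a [Volume3D-class].
#' @param axis axis to project along: one of the volume's axis labels or an
#'   axis index 1-3.
#' @return a [GrayImage-class] whose shape is the two remaining axes, in
#'   array order.
#' @examples
#' v <- Volume3D(array(runif(8 * 6 * 5), dim = c(8, 6, 5)))
#' mip(v)                     # 6 x 5 image
#' mip(v, axis = "sagittal")  # 8 x 6 image
#' @rdname mip
#' @export
setMethod("mip", "Volume3D", function(volume, axis = "axial") {
  if (is.character(axis)) {
    k <- match(axis, volume@axes)
    if (is.na(k))
      stop("unknown axis label '", axis, "'; volume axes are: ",
           paste(volume@axes, collapse = ", "))
  } else {
    k <- as.integer(axis)
    if (is.na(k) || k < 1L || k > 3L) stop("axis index must be 1, 2 or 3")
  }
  keep <- setdiff(1:3, k)
  GrayImage(apply(volume@voxels, keep, max))
})

#' Binarize a grayscale image by exact two-class k-means on intensity
#'
#' Segments the image into two intensity clusters with the exact
#' one-dimensional two-means solution (an exhaustive threshold search over
#' the sorted unique intensities, minimizing the within-cluster sum of
#' squares) and returns the higher-mean cluster as foreground. The exact
#' solver makes the segmentation deterministic: no random initialization is
#' involved, and the result is invariant to positive affine rescaling of
#' the intensities.
#'
#' @param image a [GrayImage-class] with at least two distinct intensities.
#' @return a [BinaryImage-class]; foreground = brighter cluster.
#' @examples
#' g <- GrayImage(matrix(c(10, 10, 200, 10, 200, 200), 2, 3))
#' pixels(kmeansBinarize(g))
#' @rdname kmeansBinarize
#' @export
setMethod("kmeansBinarize", "GrayImage", function(image) {
  x <- as.vector(image@pixels)
  v <- sort(unique(x))
  if (length(v) < 2L) stop("no contrast to segment")
  cnt <- tabulate(match(x, v), nbins = length(v))
  ## prefix sums over the sorted histogram: for a split after value j the
  ## within-cluster SSE is sum(x^2) - n1*mean1^2 - n2*mean2^2
  cs <- cumsum(cnt * v)
  css <- cumsum(cnt * v^2)
  cn <- cumsum(cnt)
  nTot <- cn[length(v)]
  sTot <- cs[length(v)]
  j <- seq_len(length(v) - 1L)
  n1 <- cn[j]; n2 <- nTot - n1
  m1 <- cs[j] / n1; m2 <- (sTot - cs[j]) / n2
  sse <- css[length(v)] - n1 * m1^2 - n2 * m2^2
  split <- which.min(sse)           # ties: lowest threshold, deterministic
  thr <- v[split]                   # cluster 1: <= thr, cluster 2: > thr
  BinaryImage(matrix(as.integer(x > thr), nrow(image@pixels)))
})

## zero-padded neighbour shift: result[i, j] = m[i + dr, j + dc]
.shift <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1L, 1L + dr):min(H, H + dr)
  cs <- max(1L, 1L + dc):min(W, W + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

## 8-connected component labels of foreground pixels, via igraph on the
## pixel adjacency graph. Returns an integer vector of labels parallel to
## which(px == 1) (column-major order), or integer(0) for an empty image.
.label8 <- function(px) {
  idx <- which(px == 1)
  if (length(idx) == 0L) return(integer(0))
  H <- nrow(px); W <- ncol(px)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  from <- integer(0); to <- integer(0)
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    nr <- r + d[1L]; nc <- cc + d[2L]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    ok[ok] <- px[cbind(nr[ok], nc[ok])] == 1
    from <- c(from, idx[ok])
    to <- c(to, (nc[ok] - 1L) * H + nr[ok])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE, vertices = data.frame(name = as.character(idx)))
  unname(igraph::components(g)$membership[as.character(idx)])
}

#' Count 8-connected foreground components
#'
#' @param image a [BinaryImage-class].
#' @return integer number of 8-connected components (0 for an empty image).
#' @export
componentCount <- function(image) {
  lab <- .label8(pixels(image))
  if (length(lab) == 0L) 0L else max(lab)
}

#' Skeletonize a binary image (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels with the two-subiteration Zhang-Suen
#' scheme until a fixed point is reached, reducing vessels to (essentially)
#' one-pixel-wide 8-connected curves. A component guard supplements the
#' parallel scheme: when a subiteration would delete the last remaining
#' pixels of an 8-connected component (the classic failure case is an
#' isolated 2x2 block, which plain Zhang-Suen erases completely), one pixel
#' of that component is retained so the component count of the input is
#' preserved. The result is idempotent: skeletonizing a skeleton returns it
#' unchanged.
#'
#' @param image a [BinaryImage-class].
#' @return a [BinaryImage-class] with foreground a subset of the input's.
#' @examples
#' bar <- matrix(0L, 10, 60); bar[4:6, 6:55] <- 1L
#' sk <- skeletonize(BinaryImage(bar))
#' foregroundCount(sk)  # close to the bar length
#' @rdname skeletonize
#' @export
setMethod("skeletonize", "BinaryImage", function(image) {
  m <- image@pixels
  if (sum(m) == 0L) return(image)
  H <- nrow(m); W <- ncol(m)
  lab0 <- integer(H * W)
  lab0[which(m == 1)] <- .label8(m)   # static labels; thinning only deletes
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- .shift(m, -1L,  0L); p3 <- .shift(m, -1L,  1L)
      p4 <- .shift(m,  0L,  1L); p5 <- .shift(m,  1L,  1L)
      p6 <- .shift(m,  1L,  0L); p7 <- .shift(m,  1L, -1L)
      p8 <- .shift(m,  0L, -1L); p9 <- .shift(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (pass == 1L) {
        cond <- p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        cond <- p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      del <- m == 1L & B >= 2L & B <= 6L & A == 1L & cond
      if (any(del)) {
        ## component guard: never delete a whole component
        fg <- which(m == 1L)
        delIdx <- which(del)
        remain <- setdiff(fg, delIdx)
        gone <- setdiff(unique(lab0[delIdx]), unique(lab0[remain]))
        if (length(gone)) {
          for (g in gone) del[delIdx[lab0[delIdx] == g][1L]] <- FALSE
        }
        if (any(del)) {
          m[del] <- 0L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  BinaryImage(m)
})

#' Split an image into left and right hemisphere halves
#'
#' Cuts the image at the vertical midline: the left half keeps the first
#' W/2 columns, the right half the rest. With the study's 364 x 436
#' projection geometry this yields two 182 x 436 halves. "Left" means the
#' left half of the raster; mapping raster side to anatomical side
#' (radiological vs neurological display) is the caller's responsibility.
#'
#' @param image a [BinaryImage-class] with an even width.
#' @return a list with elements `left` and `right`, both [BinaryImage-class].
#' @examples
#' img <- BinaryImage(matrix(rbinom(24, 1, 0.4), 4, 6))
#' halves <- splitHemispheres(img)
#' dim(halves$left)
#' @rdname splitHemispheres
#' @export
setMethod("splitHemispheres", "BinaryImage", function(image) {
  W <- ncol(image@pixels)
  if (W %% 2L != 0L)
    stop("image width must be even; pad or crop before splitting")
  half <- W %/% 2L
  list(left  = BinaryImage(image@pixels[, 1:half, drop = FALSE]),
       right = BinaryImage(image@pixels[, (half + 1L):W, drop = FALSE]))
})
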