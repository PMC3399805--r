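## Synthetic inputs: DLA clusters, analytic prefractals, multiplicative
## cascades, and a synthetic AVM cohort of branching vessel trees.

#' Grow a diffusion-limited aggregation cluster
#'
#' Lattice DLA: walkers released from a launch annulus perform
#' nearest-neighbour random walks and freeze on first contact with the
#' cluster (4-neighbour sticking by default), starting from a single seed
#' at the grid centre. Walkers beyond the kill radius (or off the grid) are
#' discarded and relaunched. Growth stops when the cluster radius reaches
#' `stopFraction` of the smaller half-extent of the grid, or when the
#' particle budget is exhausted.
#'
#' @param width,height grid size in pixels (width = columns).
#' @param seed optional RNG seed; when given, the R RNG state is set
#'   locally (and restored afterwards) so the cluster is a pure function of
#'   the seed. When NULL, the current RNG stream is used.
#' @param budget particle budget (>= 1), counting the seed: the cluster
#'   never holds more than `budget` pixels, and `budget = 1` returns the
#'   bare seed. The default is large enough that the radius rule stops
#'   growth first on all supported grids.
#' @param stopFraction stop when the cluster radius reaches this fraction
#'   of min(width, height) / 2; in (0, 0.5).
#' @param annulusMargin launch radius = cluster radius + this margin.
#' @param killFactor kill radius = killFactor x launch radius.
#' @param eightNeighbour use 8-neighbour sticking instead of 4-neighbour.
#' @return a [BinaryImage-class] containing one 8-connected cluster that
#'   includes the seed pixel.
#' @examples
#' cl <- generateDLA(128, 128, seed = 1)
#' foregroundCount(cl)
#' @export
generateDLA <- function(width, height, seed = NULL, budget = 50000L,
                        stopFraction = 0.45, annulusMargin = 5,
                        killFactor = 3, eightNeighbour = FALSE) {
  width <- as.integer(width); height <- as.integer(height)
  stopifnot(width >= 3L, height >= 3L)
  if (budget < 1L) stop("budget must be >= 1")
  if (stopFraction <= 0 || stopFraction >= 0.5)
    stop("stopFraction must be in (0, 0.5)")
  if (!is.null(seed)) {
    old <- .saveRNG()
    on.exit(.restoreRNG(old))
    set.seed(as.integer(seed))
  }
  BinaryImage(dla_grow_cpp(height, width, as.integer(budget), stopFraction,
                           annulusMargin, killFactor, eightNeighbour))
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' DLA cluster rasterized on the in-vivo 364 x 436 geometry
#'
#' Grows the cluster on a square 436 x 436 grid and centre-crops the width
#' to 364 columns, so the same morphology populates both the power-of-two
#' and the in-vivo matrix geometries when studying grid-size sensitivity.
#'
#' @inheritParams generateDLA
#' @return a [BinaryImage-class] of 364 x 436 (W x H).
#' @export
generateDLA364x436 <- function(seed = NULL, ...) {
  full <- generateDLA(436L, 436L, seed = seed, ...)
  off <- (436L - 364L) %/% 2L
  BinaryImage(pixels(full)[, (off + 1L):(off + 364L)])
}

#' Rasterize an analytic prefractal
#'
#' Deterministic depth-k prefractals with known dimensions, used as
#' analytic oracles for the estimators: the Sierpinski carpet
#' (D = log 8 / log 3), the Sierpinski triangle (D = log 3 / log 2) and the
#' Koch curve (D = log 4 / log 3).
#'
#' @param kind "sierpinski_carpet", "sierpinski_triangle" or "koch_curve".
#' @param depth recursion depth >= 1 (>= 0 for the Koch curve); the canvas
#'   is sized to the generator (3^depth for carpet and Koch, 2^depth for
#'   the triangle) and capped at 4096 pixels a side.
#' @return a [BinaryImage-class]. The carpet has exactly 8^depth foreground
#'   pixels and the triangle 3^depth.
#' @examples
#' foregroundCount(generatePrefractal("sierpinski_carpet", 3))  # 8^3
#' @export
generatePrefractal <- function(kind = c("sierpinski_carpet",
                                        "sierpinski_triangle",
                                        "koch_curve"),
                               depth) {
  kind <- match.arg(kind)
  depth <- as.integer(depth)
  if (kind != "koch_curve" && depth < 1L) stop("depth must be >= 1")
  if (kind == "koch_curve" && depth < 0L) stop("depth must be >= 0")
  side <- switch(kind,
                 sierpinski_carpet = 3^depth,
                 sierpinski_triangle = 2^depth,
                 koch_curve = 3^depth + 1)
  if (side > 4096) stop("depth too large for the 4096-pixel canvas limit")
  switch(kind,
         sierpinski_carpet = .carpet(depth),
         sierpinski_triangle = .triangle(depth),
         koch_curve = .koch(depth))
}

.carpet <- function(depth) {
  cell <- matrix(c(1, 1, 1, 1, 0, 1, 1, 1, 1), 3, 3)
  m <- Reduce(kronecker, rep(list(cell), depth))
  BinaryImage(m)
}

.triangle <- function(depth) {
  n <- 2^depth
  i <- 0:(n - 1L)
  m <- outer(i, i, function(a, b) as.integer(bitwAnd(a, b) == 0L))
  BinaryImage(m)
}

## pixel coordinates of a straight stroke between two (possibly fractional)
## endpoints; 8-connected, one pixel per step
.strokePixels <- function(x0, y0, x1, y1) {
  n <- max(abs(round(x1) - round(x0)), abs(round(y1) - round(y0)), 1)
  s <- seq(0, 1, length.out = n + 1)
  cbind(x = round(x0 + (x1 - x0) * s), y = round(y0 + (y1 - y0) * s))
}

## draw a stroke into a matrix (rows = y from top), clipping at the canvas
.drawStroke <- function(m, x0, y0, x1, y1) {
  p <- .strokePixels(x0, y0, x1, y1)
  r <- nrow(m) - p[, "y"]          # y measured upward from the bottom row
  c <- p[, "x"]
  ok <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
  m[cbind(r[ok], c[ok])] <- 1L
  m
}

.koch <- function(depth) {
  side <- 3^depth
  seg <- matrix(c(0, 0, side, 0), ncol = 2, byrow = TRUE)  # x, y endpoints
  pts <- complex(real = c(0, side), imaginary = c(0, 0))
  for (k in seq_len(depth)) {
    out <- complex(0)
    for (i in seq_len(length(pts) - 1L)) {
      a <- pts[i]; b <- pts[i + 1L]
      v <- (b - a) / 3
      out <- c(out, a, a + v, a + v + v * exp(1i * pi / 3), a + 2 * v)
    }
    pts <- c(out, pts[length(pts)])
  }
  h <- max(1, ceiling(max(Im(pts))) + 1)
  m <- matrix(0L, h + 1L, side + 1L)
  for (i in seq_len(length(pts) - 1L)) {
    m <- .drawStroke(m, Re(pts[i]) + 1, Im(pts[i]),
                     Re(pts[i + 1L]) + 1, Im(pts[i + 1L]))
  }
  BinaryImage(m)
}

#' Binomial multiplicative cascade measure
#'
#' The standard 1-D multifractal test measure: starting from unit mass on
#' one cell, each cell repeatedly splits in two with mass fractions p and
#' 1 - p. After `depth` splits the 2^depth cell masses sum to 1 and the
#' Renyi spectrum has the closed form
#' D_q = log2(p^q + (1-p)^q) / (1 - q).
#'
#' @param p left-child mass fraction, in (0, 1).
#' @param depth number of splittings, >= 1.
#' @return numeric vector of 2^depth cell masses summing to 1.
#' @examples
#' generateCascade(0.7, 3)  # the 8 products of 0.7/0.3 factors
#' @export
generateCascade <- function(p, depth) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  as.numeric(Reduce(function(v, .) kronecker(v, c(p, 1 - p)),
                    seq_len(depth), init = 1))
}

#' Closed-form Renyi spectrum of the binomial cascade
#'
#' @param p left-child mass fraction in (0, 1).
#' @param q moment orders.
#' @return D_q = log2(p^q + (1-p)^q) / (1-q), with the entropy limit at
#'   q = 1.
#' @export
cascadeSpectrumExact <- function(p, q) {
  vapply(q, function(qq) {
    if (abs(qq - 1) < 1e-9) {
      -(p * log2(p) + (1 - p) * log2(1 - p))
    } else {
      log2(p^qq + (1 - p)^qq) / (1 - qq)
    }
  }, numeric(1))
}

## Hemisphere raster: a bifurcating backbone tree plus a stratified field of
## small "lobule" knots (clusters of short crossing strokes), one per
## occupied grid cell. The knots emulate the fine-scale vessel crossings a
## maximum intensity projection produces, spread evenly over the hemisphere
## the way cortex is vascularized; the stratification keeps coarse-scale
## density homogeneous, which is what gives skeletons their decreasing
## Renyi spectrum. Draws from the current RNG stream. The number of drawn
## strokes (the branch count) is deterministic for fixed parameters.
.vesselHemisphere <- function(width, height, tree, lobules) {
  m <- matrix(0L, height, width)
  count <- 0L
  segs <- list(list(x = width / 2, y = 8, angle = pi / 2,
                    len = tree$trunk, level = 1L))
  while (length(segs)) {
    s <- segs[[length(segs)]]
    segs[[length(segs)]] <- NULL
    x1 <- s$x + s$len * cos(s$angle)
    y1 <- s$y + s$len * sin(s$angle)
    m <- .drawStroke(m, s$x, s$y, x1, y1)
    count <- count + 1L
    if (s$level < tree$levels) {
      for (sgn in c(-1, 1)) {
        ang <- s$angle + sgn * tree$spread + rnorm(1, 0, tree$jitterSD)
        segs[[length(segs) + 1L]] <-
          list(x = x1, y = y1, angle = ang, len = s$len * tree$decay,
               level = s$level + 1L)
      }
    }
  }
  nx <- floor(width / lobules$cell)
  ny <- floor(height / lobules$cell)
  nOcc <- round(lobules$fillFraction * nx * ny)
  occ <- sample(nx * ny, nOcc)        # exact count: branch total deterministic
  for (cellId in occ) {
    ix <- (cellId - 1L) %% nx
    iy <- (cellId - 1L) %/% nx
    x <- (ix + runif(1, 0.25, 0.75)) * lobules$cell
    y <- (iy + runif(1, 0.25, 0.75)) * lobules$cell
    for (k in seq_len(lobules$strokes)) {
      ang <- runif(1, 0, pi)
      l <- runif(1, lobules$strokeLen * 0.5, lobules$strokeLen)
      m <- .drawStroke(m, x - l / 2 * cos(ang), y - l / 2 * sin(ang),
                       x + l / 2 * cos(ang), y + l / 2 * sin(ang))
    }
    count <- count + lobules$strokes
  }
  list(pixels = m, branches = count)
}

## AVM nidus: d extra curved vessel strokes packed in a disk whose radius
## grows as sqrt(d), so the local vessel density stays constant while the
## malformed region (and the box counts it claims) grows with d
.avmNidus <- function(m, d, cx, cy, nidus) {
  radius <- nidus$radiusCoef * sqrt(d)
  for (i in seq_len(d)) {
    rr <- radius * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    x0 <- cx + rr * cos(th); y0 <- cy + rr * sin(th)
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, nidus$lenMin, nidus$lenMax)
    xm <- x0 + len / 2 * cos(ang); ym <- y0 + len / 2 * sin(ang)
    ang2 <- ang + rnorm(1, 0, 0.4)
    m <- .drawStroke(m, x0, y0, xm, ym)
    m <- .drawStroke(m, xm, ym, xm + len / 2 * cos(ang2),
                     ym + len / 2 * sin(ang2))
  }
  m
}

## gamma-variate bolus f(t) = ((t - t0)/beta ... ) rasterized on a uniform
## time grid, scaled so its analytic peak upslope equals `peakSlope`
.bolusCurve <- function(peakSlope, times = seq(0, 60, by = 0.5), t0 = 8,
                        alpha = 3, beta = 1.8) {
  f <- function(x) ifelse(x > 0, x^alpha * exp(-x / beta), 0)
  xstar <- beta * (alpha - sqrt(alpha))       # rising inflection point
  unitMax <- exp(-xstar / beta) * xstar^(alpha - 1) * (alpha - xstar / beta)
  k <- peakSlope / unitMax
  intensityTimeCurve(times, k * f(times - t0))
}

#' Generate a synthetic AVM study cohort
#'
#' Builds `nPatients` patients and `nControls` controls. Every hemisphere
#' is rasterized one pixel wide on a 182 x 436 canvas as a bifurcating
#' backbone tree overlaid with a stratified field of small "lobule" knots
#' (clusters of short crossing strokes, one per occupied grid cell) that
#' emulate the fine-scale vessel crossings a maximum intensity projection
#' produces while keeping coarse-scale density homogeneous. Patients
#' additionally receive a nidus on a randomly chosen AVM side: `d` extra
#' curved vessels packed in a disk whose radius grows as sqrt(d) (constant
#' local density), with `d` drawn uniformly from
#' `complexity$dMin .. complexity$dMax`; controls are symmetric. Each
#' subject carries a gamma-variate contrast bolus whose analytic peak
#' upslope is `slope0 + slopePerBranch x (total branch count)` plus
#' Gaussian noise, and patients carry four nidus diameters (two views x
#' min/max, cm) whose mean is `diam0 + diamPerBranch x d` plus noise — so
#' at zero noise both covariates are exactly monotone in the ground-truth
#' complexity.
#'
#' @param nPatients,nControls subject counts, both >= 1.
#' @param seed RNG seed; the cohort is a pure function of it.
#' @param complexity list with integer `dMin`, `dMax`: range of extra nidus
#'   branches.
#' @param noise list with `slopeSD` (a.u./s) and `diamSD` (cm): Gaussian
#'   noise on the peak upslope and on each nidus diameter.
#' @param tree backbone-tree parameters: `levels` (bifurcation depth),
#'   `trunk` (trunk length, px), `decay` (length decay per level), `spread`
#'   (branching half-angle, rad), `jitterSD` (angle jitter SD, rad).
#' @param lobules knot-field parameters: `cell` (grid cell size, px),
#'   `fillFraction` (fraction of cells carrying a knot), `strokes` (strokes
#'   per knot), `strokeLen` (maximum stroke length, px).
#' @param nidus AVM vessel parameters: `radiusCoef` (disk radius =
#'   radiusCoef * sqrt(d), px), `lenMin`, `lenMax` (vessel lengths, px).
#' @param width,height hemisphere canvas in pixels.
#' @param slope0,slopePerBranch affine map from total branch count to peak
#'   upslope (a.u./s).
#' @param diam0,diamPerBranch affine map from nidus branch count to mean
#'   nidus diameter (cm).
#' @return a list of [SyntheticSubject-class] objects (patients first).
#' @examples
#' cohort <- generateCohort(2, 2, seed = 7)
#' cohort[[1]]
#' @export
generateCohort <- function(nPatients = 10L, nControls = 10L, seed = 1L,
                           complexity = list(dMin = 30L, dMax = 150L),
                           noise = list(slopeSD = 0.1, diamSD = 0.05),
                           tree = list(levels = 6L, trunk = 50, decay = 0.76,
                                       spread = 0.55, jitterSD = 0.2),
                           lobules = list(cell = 14, fillFraction = 0.55,
                                          strokes = 4L, strokeLen = 5),
                           nidus = list(radiusCoef = 5, lenMin = 8,
                                        lenMax = 18),
                           width = 182L, height = 436L,
                           slope0 = 1, slopePerBranch = 0.02,
                           diam0 = 0.5, diamPerBranch = 0.015) {
  if (nPatients < 1L || nControls < 1L) stop("counts must be >= 1")
  if (tree$levels < 1L || tree$trunk <= 0) stop("degenerate tree parameters")
  if (lobules$strokes < 1L) stop("degenerate lobule parameters")
  if (complexity$dMin < 1L || complexity$dMax < complexity$dMin)
    stop("degenerate complexity parameters")
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))

  makeSide <- function() .vesselHemisphere(width, height, tree, lobules)

  subjects <- vector("list", nPatients + nControls)
  for (i in seq_len(nPatients)) {
    L <- makeSide(); R <- makeSide()
    d <- sample(complexity$dMin:complexity$dMax, 1L)
    side <- sample(c("left", "right"), 1L)
    cx <- runif(1, 0.35, 0.65) * width
    cy <- runif(1, 0.40, 0.70) * height
    if (side == "left") {
      L$pixels <- .avmNidus(L$pixels, d, cx, cy, nidus)
      L$branches <- L$branches + d
    } else {
      R$pixels <- .avmNidus(R$pixels, d, cx, cy, nidus)
      R$branches <- R$branches + d
    }
    total <- L$branches + R$branches
    peak <- slope0 + slopePerBranch * total + rnorm(1, 0, noise$slopeSD)
    meanDiam <- diam0 + diamPerBranch * d
    diams <- meanDiam * c(0.85, 1.15, 0.9, 1.1) +
      rnorm(4, 0, noise$diamSD)
    diams <- pmax(diams, 0.05)
    subjects[[i]] <- new("SyntheticSubject",
                         id = sprintf("P%02d", i), group = "patient",
                         left = BinaryImage(L$pixels),
                         right = BinaryImage(R$pixels),
                         avmSide = side,
                         branchCounts = c(left = L$branches,
                                          right = R$branches),
                         curve = .bolusCurve(peak),
                         nidusDiameters = diams)
  }
  for (i in seq_len(nControls)) {
    L <- makeSide(); R <- makeSide()
    total <- L$branches + R$branches
    peak <- slope0 + slopePerBranch * total + rnorm(1, 0, noise$slopeSD)
    subjects[[nPatients + i]] <-
      new("SyntheticSubject",
          id = sprintf("C%02d", i), group = "control",
          left = BinaryImage(L$pixels), right = BinaryImage(R$pixels),
          avmSide = NA_character_,
          branchCounts = c(left = L$branches, right = R$branches),
          curve = .bolusCurve(peak),
          nidusDiameters = rep(NA_real_, 4))
  }
  subjects
}
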