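test_that("boxCounts matches the exhaustive occupancy oracle", {
  ## degenerate cases with known counts
  one <- matrix(0L, 32, 32); one[17, 5] <- 1L
  cv <- boxCounts(BinaryImage(one))
  expect_true(all(measures(cv) == 1))
  expect_equal(fdValue(fitDimension(cv)), 0)

  full <- BinaryImage(matrix(1L, 64, 64))
  cvf <- boxCounts(full)
  expect_equal(measures(cvf), (64 / scales(cvf))^2)
  expect_equal(fdValue(fitDimension(cvf)), 2)

  ## random image: every N(eps) equals the brute-force double loop,
  ## for the default and for a shifted grid anchor
  px <- randomImage(64, 64, 0.15, seed = 11)
  for (anchor in list(c(0L, 0L), c(3L, 5L))) {
    cv <- boxCounts(BinaryImage(px), anchor = anchor)
    for (k in seq_along(scales(cv))) {
      expect_identical(measures(cv)[k],
                       as.numeric(bfBoxCount(px, scales(cv)[k], anchor)))
    }
  }

  ## invariants: N non-increasing, N(1) = mass, N bounded by the grid
  img <- BinaryImage(randomImage(57, 43, 0.1, seed = 5))  # odd sizes
  cv <- boxCounts(img)
  expect_true(all(diff(measures(cv)) <= 0))
  expect_equal(measures(cv)[1], foregroundCount(img))
  expect_true(all(measures(cv) <=
                  ceiling(43 / scales(cv)) * ceiling(57 / scales(cv))))

  expect_error(boxCounts(BinaryImage(matrix(0L, 8, 8))), "no foreground")
})

test_that("minkowskiAreas matches brute-force dilation", {
  ## single pixel: A = (2n+1)^2, dimension 0
  one <- matrix(0L, 64, 64); one[32, 32] <- 1L
  cv <- minkowskiAreas(BinaryImage(one), nMax = 5)
  expect_equal(measures(cv), (2 * (0:5) + 1)^2)
  expect_equal(fdValue(fitDimension(cv, fixedWindow(1, 6))), 0)

  ## saturated image: A constant, dimension 2
  cvf <- minkowskiAreas(BinaryImage(matrix(1L, 32, 32)), nMax = 4)
  expect_true(all(measures(cvf) == 32 * 32))
  expect_equal(fdValue(fitDimension(cvf, fixedWindow(1, 5))), 2)

  ## line far from borders: A(r_n) = (100 + 2n)(2n + 1), slope -> 1
  ln <- matrix(0L, 200, 300); ln[100, 101:200] <- 1L
  cvl <- minkowskiAreas(BinaryImage(ln), nMax = 10)
  expect_equal(measures(cvl), (100 + 2 * (0:10)) * (2 * (0:10) + 1))
  est <- fitDimension(cvl, fixedWindow(1, 11))
  expect_lt(abs(fdValue(est) - 1), 0.1)

  ## brute-force dilation oracle on a random image
  px <- randomImage(32, 32, 0.06, seed = 2)
  cv <- minkowskiAreas(BinaryImage(px), nMax = 4)
  for (n in 0:4) {
    expect_identical(measures(cv)[n + 1], as.numeric(bfDilatedArea(px, n)))
  }

  ## A non-decreasing and bounded by the canvas
  expect_true(all(diff(measures(cv)) >= 0))
  expect_true(all(measures(cv) <= 32 * 32))

  expect_error(minkowskiAreas(BinaryImage(matrix(0L, 8, 8)), nMax = 3),
               "no foreground")
  expect_error(minkowskiAreas(BinaryImage(matrix(1L, 8, 8)), nMax = 1),
               "nMax")
})

test_that("selectLinearRange picks the maximal window above the threshold", {
  ## an exact power law keeps the full range
  cv <- scalingCurve(2^(0:6), 10 * 2^(-1.5 * (0:6)), "box")
  rng <- selectLinearRange(cv)
  expect_equal(c(rng@first, rng@last), c(1L, 7L))
  expect_false(rng@flagged)

  ## 8 log-linear points followed by a strongly curved tail: brute-force
  ## window search is the oracle
  ls <- 0:11
  lm_ <- c(-1.5 * (0:7), -1.5 * (8:11) - 2 * ((8:11) - 7)^2)
  curve <- scalingCurve(exp(ls), exp(lm_), "box")
  rng <- selectLinearRange(curve, 0.995)
  bf <- NULL
  for (len in length(ls):3) {
    for (s in 1:(length(ls) - len + 1)) {
      if (abs(cor(ls[s:(s + len - 1)], lm_[s:(s + len - 1)])) >= 0.995) {
        bf <- c(s, s + len - 1); break
      }
    }
    if (!is.null(bf)) break
  }
  expect_equal(c(rng@first, rng@last), as.integer(bf))
  expect_equal(c(rng@first, rng@last), c(1L, 8L))

  ## three points are always returned, flagged when below threshold
  bad <- scalingCurve(c(1, 2, 4), c(100, 90, 1), "box")
  rng3 <- selectLinearRange(bad, 0.9999)
  expect_equal(c(rng3@first, rng3@last), c(1L, 3L))
  expect_true(rng3@flagged)

  expect_error(selectLinearRange(cv, 1.5), "rThreshold")
})

test_that("fitDimension recovers analytic dimensions on prefractals", {
  carpet <- generatePrefractal("sierpinski_carpet", 5)
  expect_equal(foregroundCount(carpet), 8^5)
  dCarpet <- log(8) / log(3)
  expect_lt(abs(fdValue(boxDimension(carpet)) - dCarpet), 0.06)
  expect_lt(abs(fdValue(minkowskiDimension(carpet)) - dCarpet), 0.08)

  ## Koch prefractals, both estimators, depths 4 and 5
  dKoch <- log(4) / log(3)
  for (depth in 4:5) {
    koch <- generatePrefractal("koch_curve", depth)
    expect_lt(abs(fdValue(boxDimension(koch)) - dKoch), 0.08)
    expect_lt(abs(fdValue(minkowskiDimension(koch)) - dKoch), 0.08)
  }

  ## Sierpinski triangle: a third self-similar oracle
  tri <- generatePrefractal("sierpinski_triangle", 8)
  dTri <- log(3) / log(2)
  expect_lt(abs(fdValue(boxDimension(tri)) - dTri), 0.06)
  expect_lt(abs(fdValue(minkowskiDimension(tri)) - dTri), 0.08)

  ## a range reaching past the curve is rejected
  expect_error(fitDimension(scalingCurve(c(1, 2, 4), c(8, 4, 2), "box"),
                            fixedWindow(1, 5)), "range")
})

test_that("estimates carry sensible fit metadata", {
  carpet <- generatePrefractal("sierpinski_carpet", 4)
  est <- boxDimension(carpet)
  expect_s4_class(est, "FDEstimate")
  expect_lte(abs(fitR(est)), 1)
  expect_gte(abs(fitR(est)), 0.995)
  expect_equal(est@method, "box")
  ## intercept + slope reproduce the fitted line at the first in-range point
  idx <- est@range@first
  pred <- est@intercept - fdValue(est) * log(scales(est@curve)[idx])
  expect_lt(abs(pred - log(measures(est@curve)[idx])), 0.3)
})

test_that("Minkowski dimension is translation- and radius-scale-invariant", {
  ## translation within the canvas (dilations stay inside)
  base <- matrix(0L, 200, 200)
  blob <- randomBlob(H = 40, W = 40, seed = 4)
  base[61:100, 61:100] <- blob
  shifted <- matrix(0L, 200, 200)
  shifted[81:120, 96:135] <- blob
  e1 <- minkowskiDimension(BinaryImage(base), nMax = 8)
  e2 <- minkowskiDimension(BinaryImage(shifted), nMax = 8)
  expect_equal(fdValue(e1), fdValue(e2))

  ## rescaling all radii by a positive constant leaves the slope unchanged
  cv <- minkowskiAreas(BinaryImage(base), nMax = 8)
  cv2 <- scalingCurve(scales(cv) * 3.7, measures(cv), "minkowski")
  rng <- fixedWindow(1, length(scales(cv)))
  expect_equal(fdValue(fitDimension(cv, rng)), fdValue(fitDimension(cv2, rng)))
})

test_that("box counting is sensitive to the grid anchor on 364x436", {
  ## the grid-origin dependence for non-power-of-two images: the anchored
  ## and shifted grids give different dimension estimates
  img <- generateDLA364x436(seed = 77)
  d0 <- fdValue(boxDimension(img, anchor = c(0L, 0L)))
  d1 <- fdValue(boxDimension(img, anchor = c(7L, 13L)))
  expect_gt(abs(d0 - d1), 0)
})
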