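test_that("mip projects maxima along the requested axis", {
  ## singleton axis: projection is the identity
  v <- array(runif(4), dim = c(1, 2, 2))
  expect_equal(pixels(mip(Volume3D(v))), v[1, , ])

  ## a single bright voxel survives projection
  v <- array(0, dim = c(4, 5, 6)); v[2, 3, 4] <- 7
  img <- mip(Volume3D(v))
  expect_equal(sum(pixels(img)), 7)
  expect_equal(dim(img), c(5L, 6L))

  ## exhaustive per-pixel max oracle on a random volume, all three axes
  v <- withr::with_seed(7, array(runif(8 * 16 * 16), dim = c(8, 16, 16)))
  vol <- Volume3D(v)
  for (ax in 1:3) {
    got <- pixels(mip(vol, axis = ax))
    keep <- setdiff(1:3, ax)
    expected <- matrix(NA_real_, dim(v)[keep[1]], dim(v)[keep[2]])
    for (i in seq_len(nrow(expected))) for (j in seq_len(ncol(expected))) {
      idx <- c(NA, NA, NA); idx[keep] <- c(i, j)
      expected[i, j] <- max(vapply(seq_len(dim(v)[ax]), function(k) {
        idx[ax] <- k; v[idx[1], idx[2], idx[3]]
      }, numeric(1)))
    }
    expect_equal(got, expected)
  }

  expect_error(mip(vol, axis = "oblique"), "unknown axis")
  ## commutes with monotone voxelwise transforms
  expect_equal(pixels(mip(Volume3D(v^2))), pixels(mip(vol))^2)
})

test_that("kmeansBinarize finds the exact 1-D two-means split", {
  g <- GrayImage(matrix(c(10, 10, 200, 10, 200, 200), 2, 3))
  expect_equal(pixels(kmeansBinarize(g)),
               matrix(c(0L, 0L, 1L, 0L, 1L, 1L), 2, 3))

  ## {0, 100, 101}: enumeration over all 2-partitions of the sorted values
  ## puts the boundary between 0 and {100, 101}
  x <- matrix(c(0, 100, 101, 0, 0, 100), 2, 3)
  vals <- sort(unique(as.vector(x)))
  sse <- vapply(seq_len(length(vals) - 1), function(k) {
    lo <- x[x <= vals[k]]; hi <- x[x > vals[k]]
    sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
  }, numeric(1))
  bestThr <- vals[which.min(sse)]
  expect_equal(bestThr, 0)  # the oracle's split
  expect_equal(pixels(kmeansBinarize(GrayImage(x))),
               matrix(as.integer(x > bestThr), 2, 3))

  ## inverted contrast gives the complement
  inv <- GrayImage(max(x) - x)
  expect_equal(pixels(kmeansBinarize(inv)),
               1L - pixels(kmeansBinarize(GrayImage(x))))

  ## invariant to positive affine rescaling
  r <- withr::with_seed(3, matrix(runif(400), 20, 20))
  expect_equal(pixels(kmeansBinarize(GrayImage(2.7 * r + 5))),
               pixels(kmeansBinarize(GrayImage(r))))

  expect_error(kmeansBinarize(GrayImage(matrix(3, 4, 4))), "no contrast")
})

test_that("skeletonize thins to 1-pixel curves preserving components", {
  ## a 1-pixel line is already a skeleton
  line <- matrix(0L, 9, 30); line[5, 3:27] <- 1L
  expect_equal(pixels(skeletonize(BinaryImage(line))), line)

  ## filled square: nonempty connected skeleton
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  sk <- skeletonize(BinaryImage(sq))
  expect_gte(foregroundCount(sk), 1)
  expect_lte(foregroundCount(sk), 100)
  expect_equal(componentCount(sk), 1L)

  ## 3-pixel-wide bar of length 50 thins to a path of about that length
  ## (parallel thinning erodes up to 2 px per free end)
  bar <- matrix(0L, 11, 60); bar[5:7, 6:55] <- 1L
  skb <- pixels(skeletonize(BinaryImage(bar)))
  expect_gte(sum(skb), 46)
  expect_lte(sum(skb), 52)
  ## one pixel wide: no 2x2 all-foreground block remains
  nr <- nrow(skb); nc <- ncol(skb)
  blocks <- skb[-1, -1] == 1 & skb[-nr, -1] == 1 &
    skb[-1, -nc] == 1 & skb[-nr, -nc] == 1
  expect_false(any(blocks))

  ## isolated 2x2 block: the component survives as a single pixel
  blk <- matrix(0L, 6, 6); blk[3:4, 3:4] <- 1L
  skblk <- skeletonize(BinaryImage(blk))
  expect_equal(componentCount(skblk), 1L)
  expect_lte(foregroundCount(skblk), 4)

  ## properties on random connected blobs: foreground never grows,
  ## component count preserved, idempotent
  for (s in 1:5) {
    blob <- BinaryImage(randomBlob(seed = s))
    sk <- skeletonize(blob)
    expect_lte(foregroundCount(sk), foregroundCount(blob))
    expect_true(all(pixels(sk) <= pixels(blob)))
    expect_equal(componentCount(sk), componentCount(blob))
    expect_equal(pixels(skeletonize(sk)), pixels(sk))
  }

  ## empty image passes through
  expect_equal(foregroundCount(skeletonize(BinaryImage(matrix(0L, 5, 5)))), 0L)
})

test_that("splitHemispheres halves the width and partitions foreground", {
  img <- BinaryImage(withr::with_seed(1, matrix(rbinom(364 * 436, 1, 0.05),
                                               436, 364)))
  h <- splitHemispheres(img)
  expect_equal(dim(h$left), c(436L, 182L))
  expect_equal(dim(h$right), c(436L, 182L))
  expect_equal(foregroundCount(h$left) + foregroundCount(h$right),
               foregroundCount(img))
  ## split then re-concatenate reproduces the input
  expect_equal(cbind(pixels(h$left), pixels(h$right)), pixels(img))

  ## mirror-symmetric image: equal halves
  half <- withr::with_seed(2, matrix(rbinom(60, 1, 0.4), 6, 10))
  sym <- BinaryImage(cbind(half, half[, ncol(half):1]))
  hs <- splitHemispheres(sym)
  expect_equal(foregroundCount(hs$left), foregroundCount(hs$right))

  ## all mass in column 1 leaves the right half empty
  m <- matrix(0L, 4, 8); m[, 1] <- 1L
  expect_equal(foregroundCount(splitHemispheres(BinaryImage(m))$right), 0L)

  expect_error(splitHemispheres(BinaryImage(matrix(0L, 4, 7))), "even")
})

test_that("raster and volume I/O round-trips", {
  img <- BinaryImage(randomBlob(seed = 9))
  path <- file.path(tempdir(), "blob.png")
  writeBinaryImage(img, path)
  back <- readVesselImage(path)
  expect_s4_class(back, "GrayImage")
  expect_equal(pixels(back), pixels(img) * 1.0)
  file.remove(path)

  ## NIfTI volume read feeds mip directly
  a <- withr::with_seed(5, array(runif(4 * 5 * 6), dim = c(4, 5, 6)))
  np <- file.path(tempdir(), "vol.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(a), np)
  vol <- readVolume(np)
  expect_equal(dim(vol), c(4L, 5L, 6L))
  expect_equal(pixels(mip(vol)), apply(a, c(2, 3), max), tolerance = 1e-6)
  file.remove(np)
})
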