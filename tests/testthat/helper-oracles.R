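## Brute-force oracles and small fixture builders. The oracles are written
## as plain double loops, independent of the package's vectorized paths.

## occupied-box count by explicit iteration over every grid cell
bfBoxCount <- function(px, eps, anchor = c(0L, 0L)) {
  H <- nrow(px); W <- ncol(px)
  n <- 0L
  r0 <- -anchor[1L]
  while (r0 < H) {
    c0 <- -anchor[2L]
    while (c0 < W) {
      if (r0 + eps >= 1L && c0 + eps >= 1L) {
        rows <- max(1L, r0 + 1L):min(H, r0 + eps)
        cols <- max(1L, c0 + 1L):min(W, c0 + eps)
        if (any(px[rows, cols, drop = FALSE] == 1)) n <- n + 1L
      }
      c0 <- c0 + eps
    }
    r0 <- r0 + eps
  }
  n
}

## box masses by explicit iteration (top-left anchored)
bfBoxMasses <- function(px, eps) {
  H <- nrow(px); W <- ncol(px)
  out <- numeric(0)
  r0 <- 0L
  while (r0 < H) {
    c0 <- 0L
    while (c0 < W) {
      m <- sum(px[(r0 + 1L):min(H, r0 + eps),
                  (c0 + 1L):min(W, c0 + eps), drop = FALSE])
      if (m > 0) out <- c(out, m)
      c0 <- c0 + eps
    }
    r0 <- r0 + eps
  }
  out
}

## dilated area by testing, per pixel, whether any foreground pixel lies
## within Chebyshev distance n
bfDilatedArea <- function(px, n) {
  H <- nrow(px); W <- ncol(px)
  fg <- which(px == 1, arr.ind = TRUE)
  a <- 0L
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (any(abs(fg[, 1L] - i) <= n & abs(fg[, 2L] - j) <= n)) a <- a + 1L
    }
  }
  a
}

randomImage <- function(H, W, p = 0.2, seed = 1) {
  withr::with_seed(seed, matrix(rbinom(H * W, 1L, p), H, W))
}

## random connected blob: union of disks along a random walk
randomBlob <- function(H = 48, W = 48, steps = 12, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(0L, H, W)
    x <- W / 2; y <- H / 2
    for (s in seq_len(steps)) {
      r <- sample(2:4, 1)
      for (i in max(1, round(y - r)):min(H, round(y + r)))
        for (j in max(1, round(x - r)):min(W, round(x + r)))
          if ((i - y)^2 + (j - x)^2 <= r^2) m[i, j] <- 1L
      ang <- runif(1, 0, 2 * pi)
      step <- runif(1, 2, 5)
      x <- min(W - 3, max(3, x + step * cos(ang)))
      y <- min(H - 3, max(3, y + step * sin(ang)))
    }
    m
  })
}

fixedWindow <- function(first, last) {
  new("RegressionRange", first = as.integer(first), last = as.integer(last),
      flagged = FALSE)
}
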