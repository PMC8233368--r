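## Independent oracles and fixture builders shared across the suite.
## These deliberately do not reuse the package's vectorized internals.

## brute-force Kapur entropy scan over all 255 candidate thresholds
bruteKapur <- function(counts) {
  p <- counts / sum(counts)
  best <- -Inf
  bestT <- NA_integer_
  for (t in 0:254) {
    pb <- p[1:(t + 1)]
    pf <- p[(t + 2):256]
    Pb <- sum(pb); Pf <- sum(pf)
    if (Pb <= 0 || Pf <= 0) next
    qb <- pb[pb > 0] / Pb
    qf <- pf[pf > 0] / Pf
    crit <- -sum(qb * log(qb)) - sum(qf * log(qf))
    if (crit > best + 1e-12) {
      best <- crit
      bestT <- t
    }
  }
  bestT
}

## even-odd ray-casting point-in-polygon (single point)
brutePointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

## random convex polygon (convex hull of random points; convexity
## guarantees simplicity) with non-integer vertices so no pixel center
## falls on an edge
randomConvexPolygon <- function(n, cx, cy, rmax) {
  repeat {
    x <- cx + runif(n + 4, -rmax, rmax) + 0.07
    y <- cy + runif(n + 4, -rmax, rmax) + 0.07
    hull <- grDevices::chull(x, y)
    if (length(hull) >= 3) return(RoiPolygon(cbind(x[hull], y[hull])))
  }
}

## histogram of a 2-3 component discretized Gaussian mixture
randomMixtureHistogram <- function() {
  k <- sample(2:3, 1)
  counts <- integer(256)
  for (i in seq_len(k)) {
    mu <- runif(1, 10, 245)
    sd <- runif(1, 3, 40)
    v <- pmin(pmax(round(rnorm(sample(50:500, 1), mu, sd)), 0), 255)
    counts <- counts + tabulate(v + 1L, nbins = 256L)
  }
  counts
}

## grayscale frame filled with one value except a chosen pixel set
flatFrame <- function(h, w, value = 0L) {
  UltrasoundFrame(matrix(as.integer(value), h, w), modality = "bmode")
}

## RGB frame with R=G=B from a gray matrix
grayAsRgbFrame <- function(g) {
  px <- array(0L, c(nrow(g), ncol(g), 3L))
  for (k in 1:3) px[, , k] <- g
  UltrasoundFrame(px, modality = "doppler")
}

squareRoi <- function(x0, y0, side) {
  RoiPolygon(cbind(c(x0, x0 + side, x0 + side, x0),
                   c(y0, y0, y0 + side, y0 + side)))
}

## doppler test frame: gray background with given pixel index sets
## painted in fixed colors (list of list(idx=, rgb=))
paintedDopplerFrame <- function(h, w, gray, paints) {
  px <- array(as.integer(gray), c(h, w, 3L))
  for (p in paints) {
    for (k in 1:3) {
      ch <- px[, , k]
      ch[p$idx] <- as.integer(p$rgb[k])
      px[, , k] <- ch
    }
  }
  UltrasoundFrame(px, modality = "doppler")
}
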