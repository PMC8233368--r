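test_that("channel splitting preserves intensities and rejects grayscale input", {
  f <- paintedDopplerFrame(2, 2, 0, list(list(idx = 1L, rgb = c(10, 20, 30))))
  ch <- splitRGB(f)
  expect_identical(c(ch$R[1, 1], ch$G[1, 1], ch$B[1, 1]), c(10L, 20L, 30L))

  set.seed(31)
  g <- matrix(sample(0:255, 25, TRUE), 5, 5)
  ch2 <- splitRGB(grayAsRgbFrame(g))
  expect_identical(ch2$R, ch2$G)
  expect_identical(ch2$G, ch2$B)

  expect_error(splitRGB(UltrasoundFrame(g, modality = "bmode")),
               class = "sq_modality_error")
})

test_that("difference maps implement saturating channel subtraction", {
  f <- paintedDopplerFrame(1, 3, 120, list(
    list(idx = 2L, rgb = c(0, 200, 255)),    # cyan overlay
    list(idx = 3L, rgb = c(150, 40, 30))))   # dark-red overlay
  ch <- splitRGB(f)
  m <- dopplerDifferenceMaps(ch$R, ch$G, ch$B)
  ## gray pixel is null in all four maps
  for (w in c("lightBlue", "darkBlue", "lightRed", "darkRed"))
    expect_identical(dopplerMap(m, w)[1, 1], 0L)
  ## cyan: G-R = 200, B-G = 55, others clamp to 0
  expect_identical(dopplerMap(m, "lightBlue")[1, 2], 200L)
  expect_identical(dopplerMap(m, "darkBlue")[1, 2], 55L)
  expect_identical(dopplerMap(m, "lightRed")[1, 2], 0L)
  expect_identical(dopplerMap(m, "darkRed")[1, 2], 0L)
  ## dark red: R-G = 110, G-B = 10, blue maps clamp to 0
  expect_identical(dopplerMap(m, "darkRed")[1, 3], 110L)
  expect_identical(dopplerMap(m, "lightRed")[1, 3], 10L)
  expect_identical(dopplerMap(m, "lightBlue")[1, 3], 0L)
  expect_identical(dopplerMap(m, "darkBlue")[1, 3], 0L)
})

test_that("maximum projection is the pixel-wise max with an identity element", {
  set.seed(32)
  A <- matrix(sample(0:255, 30, TRUE), 5, 6)
  zero <- matrix(0L, 5, 6)
  expect_identical(maxProject(A, zero), A)
  expect_identical(maxProject(A, A), A)
  B <- matrix(sample(0:255, 30, TRUE), 5, 6)
  expect_identical(maxProject(A, B)[2, 3], max(A[2, 3], B[2, 3]))
  expect_error(maxProject(A, matrix(0L, 6, 5)), class = "sq_validation_error")
})

test_that("signal selection thresholds within the ROI and filters particles", {
  roiM <- matrix(FALSE, 40, 50); roiM[1:20, 1:50] <- TRUE  # 1000 px
  map <- matrix(0L, 40, 50)
  sel0 <- selectSignal(map, roiM)
  expect_true(sel0@degenerate)
  expect_equal(areaPx(sel0), 0)

  ## 450 px at 200 as one solid block: exact two-level separation
  map[1:15, 1:30] <- 200L
  sel <- selectSignal(map, roiM)
  expect_equal(areaPx(sel), 450)
  expect_false(sel@degenerate)

  ## a 450-px component dies under a 500-px particle filter
  expect_equal(areaPx(selectSignal(map, roiM, minParticlePx = 500L)), 0)
  expect_equal(areaPx(selectSignal(map, roiM, minParticlePx = 450L)), 450)
})

test_that("component labeling is 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[cbind(c(1, 2, 3), c(1, 2, 3))] <- TRUE  # diagonal chain
  lab <- labelComponents(m)
  expect_equal(max(lab), 1)
  m[5, 5] <- TRUE
  expect_equal(max(labelComponents(m)), 2)
})

test_that("low-velocity correction is the set difference low \\ high", {
  low <- matrix(FALSE, 4, 4); low[1:2, ] <- TRUE       # 8 px
  high <- matrix(FALSE, 4, 4); high[1, 1:3] <- TRUE    # subset, 3 px
  expect_equal(areaPx(correctLowVelocity(low, high)), 5)
  expect_equal(areaPx(correctLowVelocity(low, low)), 0)
  expect_identical(maskPixels(correctLowVelocity(low, matrix(FALSE, 4, 4))), low)
})

## noiseless perfusion fixture: 100 px cyan (high, away) and 50 px deep
## blue (low, away) in a 1000-px ROI on gray background
noiselessPerfusion <- function() {
  roi <- RoiPolygon(cbind(c(0, 50, 50, 0), c(0, 0, 20, 20)))
  m <- maskPixels(rasterizeRoi(roi, c(40, 50)))
  idx <- which(m)
  frame <- paintedDopplerFrame(40, 50, 120, list(
    list(idx = idx[1:100], rgb = c(0, 200, 255)),
    list(idx = idx[101:150], rgb = c(30, 25, 200))))
  list(frame = frame, roi = roi)
}

test_that("perfusion areas are exact on a noiseless two-class frame", {
  fx <- noiselessPerfusion()
  r <- computePerfusion(fx$frame, fx$roi)
  expect_equal(r@roiAreaPx, 1000L)
  expect_equal(r@highAreaPx, 100L)
  expect_equal(r@lowCorrectedAreaPx, 50L)
  expect_equal(r@totalAreaPx, 150L)
  expect_equal(r@vrPercent, 15)
  expect_equal(r@highVelocityProportion, 100 / 150)
})

test_that("intensity-domain correction agrees on the noiseless fixture", {
  fx <- noiselessPerfusion()
  a <- computePerfusion(fx$frame, fx$roi)
  b <- computePerfusion(fx$frame, fx$roi, correctIntensities = TRUE)
  expect_equal(b@highAreaPx, a@highAreaPx)
  expect_equal(b@totalAreaPx, a@totalAreaPx)
})

test_that("grayscale frames yield zero VR and an undefined proportion", {
  set.seed(33)
  roi <- squareRoi(2, 2, 20)
  for (i in 1:5) {
    g <- matrix(sample(0:255, 30 * 30, TRUE), 30, 30)
    r <- computePerfusion(grayAsRgbFrame(g), roi)
    expect_equal(r@vrPercent, 0)
    expect_equal(r@totalAreaPx, 0L)
    expect_true(is.na(r@highVelocityProportion))
    expect_true(all(r@degenerate))
  }
})

test_that("the partition high + corrected low = total holds on simulated frames", {
  roi <- circularRoi(96, 32)
  for (s in 1:5) {
    sim <- simulateDopplerFrame(roi, runif(1, 0.05, 0.5), runif(1, 0.1, 0.9),
                                runif(1), seed = 600 + s, dim = c(96, 96))
    r <- computePerfusion(sim$frame, roi)
    expect_identical(r@highAreaPx + r@lowCorrectedAreaPx, r@totalAreaPx)
  }
})

test_that("VR is invariant under a joint geometric permutation of frame and ROI", {
  roi <- circularRoi(96, 30)
  sim <- simulateDopplerFrame(roi, 0.25, 0.4, 0.5, seed = 61, dim = c(96, 96))
  r0 <- computePerfusion(sim$frame, roi)
  ## vertical flip of the frame with the matching ROI flip
  px <- framePixels(sim$frame)
  flipped <- px[nrow(px):1, , , drop = FALSE]
  v <- roiVertices(roi)
  roiFlip <- RoiPolygon(cbind(v[, 1], 96 - v[, 2]))
  r1 <- computePerfusion(UltrasoundFrame(flipped, modality = "doppler"), roiFlip)
  expect_equal(r1@vrPercent, r0@vrPercent)
  expect_equal(r1@highVelocityProportion, r0@highVelocityProportion)
})

test_that("mirrored red/blue overlays give identical VR and proportion", {
  roi <- circularRoi(96, 32)
  for (s in 1:3) {
    away <- simulateDopplerFrame(roi, 0.3, 0.4, towardFraction = 0,
                                 seed = 700 + s, dim = c(96, 96))
    toward <- simulateDopplerFrame(roi, 0.3, 0.4, towardFraction = 1,
                                   seed = 700 + s, dim = c(96, 96))
    ra <- computePerfusion(away$frame, roi)
    rt <- computePerfusion(toward$frame, roi)
    expect_identical(rt@highAreaPx, ra@highAreaPx)
    expect_identical(rt@totalAreaPx, ra@totalAreaPx)
    expect_equal(rt@vrPercent, ra@vrPercent)
    expect_equal(rt@highVelocityProportion, ra@highVelocityProportion)
  }
})
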