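test_that("generators are deterministic in the seed and leave the RNG alone", {
  roi <- circularRoi(96, 30)
  set.seed(99); before <- runif(1)
  set.seed(99)
  a <- simulateBmodeNerve(roi, 0.4, seed = 5, dim = c(96, 96))
  mid <- runif(1)
  b <- simulateBmodeNerve(roi, 0.4, seed = 5, dim = c(96, 96))
  expect_identical(framePixels(a$frame), framePixels(b$frame))
  expect_identical(a$truth@masks, b$truth@masks)
  expect_identical(before, mid)  # caller's RNG stream untouched

  d1 <- simulateDopplerFrame(roi, 0.3, 0.5, 0.5, seed = 8, dim = c(96, 96))
  d2 <- simulateDopplerFrame(roi, 0.3, 0.5, 0.5, seed = 8, dim = c(96, 96))
  expect_identical(framePixels(d1$frame), framePixels(d2$frame))
  d3 <- simulateDopplerFrame(roi, 0.3, 0.5, 0.5, seed = 9, dim = c(96, 96))
  expect_false(identical(framePixels(d1$frame), framePixels(d3$frame)))
})

test_that("painted areas match the requested fractions exactly", {
  roi <- circularRoi(128, 44)
  nroi <- areaPx(rasterizeRoi(roi, c(128, 128)))
  sim <- simulateBmodeNerve(roi, 0.3, seed = 7, dim = c(128, 128))
  expect_equal(sum(sim$truth@masks$fascicle), round(0.3 * nroi))
  expect_true(abs(sim$truth@fractions[["fascicle"]] - 0.3) < 0.003)

  d <- simulateDopplerFrame(roi, 0.45, 0.56, 0.5, seed = 3, dim = c(128, 128))
  painted <- Reduce(`+`, lapply(d$truth@masks, sum))
  expect_equal(painted, round(0.45 * nroi))
  high <- sum(d$truth@masks$lightBlue) + sum(d$truth@masks$lightRed)
  expect_equal(high, round(0.56 * round(0.45 * nroi)))
})

test_that("zero fractions give empty truth and a pure grayscale Doppler frame", {
  roi <- circularRoi(96, 30)
  b <- simulateBmodeNerve(roi, 0, seed = 2, dim = c(96, 96))
  expect_equal(sum(b$truth@masks$fascicle), 0)

  d <- simulateDopplerFrame(roi, 0, 0.5, 0.5, seed = 2, dim = c(96, 96))
  px <- framePixels(d$frame)
  expect_identical(px[, , 1], px[, , 2])
  expect_identical(px[, , 2], px[, , 3])
  r <- computePerfusion(d$frame, roi)
  expect_equal(r@vrPercent, 0)
})

test_that("painted pixels satisfy the class-defining channel orderings", {
  roi <- circularRoi(96, 32)
  for (s in 1:4) {
    d <- simulateDopplerFrame(roi, 0.35, 0.5, runif(1), seed = 40 + s,
                              dim = c(96, 96))
    px <- framePixels(d$frame)
    R <- px[, , 1]; G <- px[, , 2]; B <- px[, , 3]
    mk <- d$truth@masks
    expect_true(all(G[mk$lightBlue] > R[mk$lightBlue]))
    expect_true(all(B[mk$darkBlue] > G[mk$darkBlue]))
    expect_true(all(G[mk$lightRed] > B[mk$lightRed]))
    expect_true(all(R[mk$darkRed] > G[mk$darkRed]))
    ## class masks are pairwise disjoint
    expect_true(max(Reduce(`+`, lapply(mk, function(m) m * 1L))) <= 1)
  }
})

test_that("re-measuring painted masks through the difference maps matches truth", {
  roi <- circularRoi(96, 32)
  d <- simulateDopplerFrame(roi, 0.25, 0.4, 0.5, seed = 77, dim = c(96, 96))
  ch <- splitRGB(d$frame)
  maps <- dopplerDifferenceMaps(ch$R, ch$G, ch$B)
  mk <- d$truth@masks
  highTruth <- mk$lightBlue | mk$lightRed
  highMap <- maxProject(dopplerMap(maps, "lightBlue"), dopplerMap(maps, "lightRed"))
  expect_identical(highMap > 0, highTruth)
  lowTruth <- mk$darkBlue | mk$darkRed
  lowMap <- maxProject(dopplerMap(maps, "darkBlue"), dopplerMap(maps, "darkRed"))
  ## the low map responds to dark classes and to high-velocity bleed-through
  expect_identical(lowMap > 0, lowTruth | highTruth)
})

test_that("cohort manifests have the declared bookkeeping and reproduce by seed", {
  sites <- data.frame(site = c("neuroma", "healthy_control"), metric = "vr",
                      nSubjects = c(9L, 4L), fracMean = c(0.43, 0.18),
                      fracSd = c(0.08, 0.04), highMean = c(0.36, 0.33),
                      highSd = c(0.15, 0.08))
  man <- simulateCohort(sites, framesPerSite = 6L, seed = 12)
  expect_equal(nrow(man), (9 + 4) * 6)
  expect_equal(length(unique(man$subject_id)), 13)
  expect_true(all(table(man$subject_id) == 6))
  man2 <- simulateCohort(sites, framesPerSite = 6L, seed = 12)
  expect_identical(man, man2)

  bad <- sites; bad$nSubjects[2] <- 1L
  expect_error(simulateCohort(bad, seed = 1), class = "sq_validation_error")
  expect_error(simulateCohort(data.frame(site = "x"), seed = 1),
               class = "sq_validation_error")
})

test_that("rendered cohort frames round-trip: files equal in-memory regeneration", {
  sites <- data.frame(site = "neuroma", metric = "vr", nSubjects = 2L,
                      fracMean = 0.3, fracSd = 0.05, highMean = 0.4,
                      highSd = 0.1)
  dir <- withr::local_tempdir()
  man <- simulateCohort(sites, framesPerSite = 2L, seed = 3, outDir = dir,
                        frameSize = 64L, roiRadius = 20)
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  fromDisk <- measureCohort(man)
  man$path <- NA_character_
  regenerated <- measureCohort(man)
  expect_equal(fromDisk$value, regenerated$value)
})
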