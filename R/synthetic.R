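## Synthetic ultrasound frames with known ground truth.
##
## The generator emulates just the image features the quantification
## reacts to: multiplicative Rayleigh-like speckle, hypoechogenic
## fascicles as dark blob unions of an exactly known area, and Doppler
## color overlays drawn from four palette classes whose channel
## orderings reproduce the difference-map class structure. It makes no
## attempt at physically accurate ultrasound simulation.

## Rayleigh variate with mean 1
.rayleigh1 <- function(n) sqrt(2 / pi) * sqrt(-2 * log(runif(n)))

## Spatially correlated, Rayleigh-shaped speckle field standardized to
## mean 0 / sd 1: an i.i.d. Rayleigh field smoothed to grain-sized
## blobs (ultrasound speckle is grainy, not pixel-white). Displayed
## B-mode data are log-compressed, which flattens the raw
## multiplicative speckle to a roughly constant depth on the display
## intensity scale, so the generator applies the field additively with
## one depth everywhere. The spatial correlation is what makes a
## morphological background estimate meaningful: pointwise-independent
## noise would drive the rolling-ball envelope to the extreme order
## statistics.
.speckleField <- function(h, w, grain = 1.0) {
  x <- matrix(.rayleigh1(h * w), h, w)
  if (grain > 0) x <- EBImage::gblur(x, sigma = grain)
  mu <- mean(x); sd <- stats::sd(x)
  if (sd == 0) return(matrix(0, h, w))
  (x - mu) / sd
}

## speckled intensity matrix: mean map plus speckle of depth
## s * 255 gray levels
.speckleMatrix <- function(muMap, field, s) {
  m <- .clamp8(.roundHalfUp(muMap + s * 255 * field))
  storage.mode(m) <- "integer"
  m
}

## logical mask of an axis-rotated ellipse, pixel-center inclusion
.ellipseMask <- function(h, w, cx, cy, a, b, theta) {
  x0 <- max(0L, floor(cx - max(a, b) - 1)); x1 <- min(w - 1L, ceiling(cx + max(a, b) + 1))
  y0 <- max(0L, floor(cy - max(a, b) - 1)); y1 <- min(h - 1L, ceiling(cy + max(a, b) + 1))
  m <- matrix(FALSE, h, w)
  if (x0 > x1 || y0 > y1) return(m)
  xs <- seq.int(x0, x1) + 0.5; ys <- seq.int(y0, y1) + 0.5
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  m[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)] <- inside
  m
}

.neighbors4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  out[-1, ] <- out[-1, ] | mask[-h, ]
  out[-h, ] <- out[-h, ] | mask[-1, ]
  out[, -1] <- out[, -1] | mask[, -w]
  out[, -w] <- out[, -w] | mask[, -1]
  out
}

## Paint random elliptical blobs inside `allowed` until `target` pixels
## are covered, then adjust to the exact count by growing the blob
## frontier or trimming blob boundary pixels. Exactness by construction
## is what lets every downstream test compare against the truth without
## a rounding budget.
.paintBlobs <- function(allowed, target, axesRange, maxBlobs) {
  h <- nrow(allowed); w <- ncol(allowed)
  mask <- matrix(FALSE, h, w)
  nAllowed <- sum(allowed)
  if (target <= 0L) return(mask)
  if (target > nAllowed)
    .sqError("requested area fraction exceeds the available region", "sq_generation_error")
  allowedIdx <- which(allowed)
  blobs <- 0L
  while (sum(mask) < target && blobs < maxBlobs) {
    ctr <- allowedIdx[sample.int(length(allowedIdx), 1L)]
    cy <- (ctr - 1L) %% h; cx <- (ctr - 1L) %/% h
    ab <- runif(2L, axesRange[1], axesRange[2])
    ell <- .ellipseMask(h, w, cx + 0.5, cy + 0.5, ab[1], ab[2], runif(1L, 0, pi))
    mask <- mask | (ell & allowed)
    blobs <- blobs + 1L
  }
  ## grow to the exact target
  while (sum(mask) < target) {
    frontier <- which(allowed & !mask & .neighbors4(mask))
    if (length(frontier) == 0L) {
      free <- which(allowed & !mask)
      frontier <- free[sample.int(length(free), 1L)]
    }
    need <- target - sum(mask)
    take <- if (length(frontier) <= need) frontier
            else sample(frontier, need)
    mask[take] <- TRUE
  }
  ## trim to the exact target
  while (sum(mask) > target) {
    boundary <- which(mask & .neighbors4(!mask | !allowed))
    if (length(boundary) == 0L) boundary <- which(mask)
    excess <- sum(mask) - target
    drop <- if (length(boundary) <= excess) boundary
            else sample(boundary, excess)
    mask[drop] <- FALSE
  }
  mask
}

#' Simulate a B-mode nerve cross-section with known fascicular fraction
#'
#' Paints a bright speckled background (epineurium and surroundings)
#' and dark speckled fascicle blobs inside the ROI whose union covers
#' exactly \code{round(fascicleFraction * ROI area)} pixels: random
#' ellipses are drawn first and the blob frontier is then grown or
#' trimmed pixel-wise to the exact count. The same seed reproduces the
#' frame bit-identically.
#'
#' @param roi \linkS4class{RoiPolygon}; fascicles are confined to it.
#' @param fascicleFraction target hypoechogenic area fraction in [0, 1].
#' @param speckleScale depth of the multiplicative Rayleigh speckle
#'   (0 = noiseless).
#' @param nFascicles number of seed ellipses drawn before the exact
#'   adjustment.
#' @param seed integer RNG seed; the caller's RNG state is untouched.
#' @param dim frame shape \code{c(H, W)}; default fits the ROI bounding
#'   box plus an 8-px margin.
#' @return list with elements \code{frame}
#'   (\linkS4class{UltrasoundFrame}) and \code{truth}
#'   (\linkS4class{SyntheticTruth} with mask \code{fascicle}).
#' @export
simulateBmodeNerve <- function(roi, fascicleFraction, speckleScale = 0.06,
                               nFascicles = 12L, seed = 1L, dim = NULL) {
  stopifnot(is(roi, "RoiPolygon"))
  if (fascicleFraction < 0 || fascicleFraction > 1)
    .sqError("fascicleFraction must lie in [0, 1]", "sq_validation_error")
  v <- roi@vertices
  if (is.null(dim))
    dim <- c(ceiling(max(v[, 2])) + 9L, ceiling(max(v[, 1])) + 9L)
  h <- dim[1]; w <- dim[2]
  roiMask <- maskPixels(rasterizeRoi(roi, dim))
  nroi <- sum(roiMask)
  if (nroi < 1L) .sqError("ROI rasterizes to an empty mask", "sq_empty_region")
  target <- round(fascicleFraction * nroi)
  .withSeed(seed, {
    fasc <- .paintBlobs(roiMask, target, axesRange = c(4, 12),
                        maxBlobs = nFascicles)
    muMap <- matrix(200, h, w)
    muMap[fasc] <- 40
    px <- .speckleMatrix(muMap, .speckleField(h, w), s = speckleScale)
    truth <- new("SyntheticTruth", masks = list(fascicle = fasc),
                 fractions = c(fascicle = sum(fasc) / nroi),
                 seed = as.integer(seed))
    list(frame = UltrasoundFrame(px, modality = "bmode"), truth = truth)
  })
}

## Overlay colors in the "away" (blue) convention: high velocity =
## cyan-like anchor (15, 190, 230), low velocity = deep blue anchor
## (30, 22, 200). Per-pixel jitter is common-mode — the same offset on
## all three channels — modeling the underlying echo brightness
## shining through the overlay. Common-mode jitter preserves every
## channel ordering strictly and leaves the channel differences at
## their anchor values, so the difference-map classes stay pure.
## "Toward" (red) pixels are the same draws with R and B swapped, which
## mirrors the channel-difference structure exactly: G - R of a blue
## pixel equals G - B of its red counterpart, and B - G equals R - G.
.drawBlueHigh <- function(n) {
  j <- floor(runif(n, -15, 21))
  cbind(15 + j, 190 + j, 230 + j)
}

.drawBlueLow <- function(n) {
  j <- floor(runif(n, -15, 21))
  cbind(30 + j, 22 + j, 200 + j)
}

#' Simulate a color-Doppler frame with known class composition
#'
#' Paints a grayscale speckle background (R = G = B everywhere) and
#' vessel-like blob overlays from the four Doppler palette classes.
#' The painted area is exactly \code{round(dopplerFraction * ROI
#' area)} pixels, of which \code{round(highClassFraction * painted)}
#' belong to the high-velocity (light) classes; within each velocity
#' tier, a \code{towardFraction} share is drawn in the red (toward)
#' direction. Overlay colors are idealized palette anchors with bounded
#' per-pixel jitter that preserves the class-defining channel orderings
#' (light blue G > R, dark blue B > G, light red G > B, dark red
#' R > G). Red-class pixels are the channel-mirrored (R <-> B) images
#' of blue-class draws, so the merged difference maps — and therefore
#' VR and the high-velocity proportion — are independent of
#' \code{towardFraction} by construction, matching the
#' direction-independence of the method.
#'
#' @param roi \linkS4class{RoiPolygon}.
#' @param dopplerFraction fraction of the ROI covered by color overlay.
#' @param highClassFraction fraction of the overlay in the high-velocity
#'   classes.
#' @param towardFraction fraction of each velocity tier flowing toward
#'   the transducer (red classes).
#' @param speckleScale background speckle depth.
#' @param seed integer RNG seed.
#' @param dim frame shape \code{c(H, W)}; default fits the ROI.
#' @return list with elements \code{frame} (3-channel
#'   \linkS4class{UltrasoundFrame}) and \code{truth}
#'   (\linkS4class{SyntheticTruth} with the four class masks).
#' @export
simulateDopplerFrame <- function(roi, dopplerFraction, highClassFraction,
                                 towardFraction = 0.5, speckleScale = 0.06,
                                 seed = 1L, dim = NULL) {
  stopifnot(is(roi, "RoiPolygon"))
  for (f in c(dopplerFraction, highClassFraction, towardFraction))
    if (f < 0 || f > 1)
      .sqError("fractions must lie in [0, 1]", "sq_validation_error")
  v <- roi@vertices
  if (is.null(dim))
    dim <- c(ceiling(max(v[, 2])) + 9L, ceiling(max(v[, 1])) + 9L)
  h <- dim[1]; w <- dim[2]
  roiMask <- maskPixels(rasterizeRoi(roi, dim))
  nroi <- sum(roiMask)
  if (nroi < 1L) .sqError("ROI rasterizes to an empty mask", "sq_empty_region")
  nPaint <- round(dopplerFraction * nroi)
  nHigh <- round(highClassFraction * nPaint)
  nLow <- nPaint - nHigh
  .withSeed(seed, {
    highMask <- .paintBlobs(roiMask, nHigh, axesRange = c(1.5, 5), maxBlobs = 400L)
    lowMask <- .paintBlobs(roiMask & !highMask, nLow, axesRange = c(1.5, 5),
                           maxBlobs = 400L)
    gray <- .speckleMatrix(matrix(90, h, w), .speckleField(h, w), s = speckleScale)
    R <- gray; G <- gray; B <- gray
    paintClass <- function(mask, drawFun, towardFrac) {
      idx <- which(mask)
      n <- length(idx)
      toward <- logical(n)
      if (n > 0L) {
        ord <- sample.int(n)                 # consumed regardless of towardFrac
        toward[ord[seq_len(round(towardFrac * n))]] <- TRUE
        col <- drawFun(n)
        r <- col[, 1]; g <- col[, 2]; b <- col[, 3]
        ## mirror R <-> B for toward-flow pixels
        rr <- ifelse(toward, b, r); bb <- ifelse(toward, r, b)
        R[idx] <<- as.integer(rr); G[idx] <<- as.integer(g); B[idx] <<- as.integer(bb)
      }
      toward
    }
    towardHigh <- paintClass(highMask, .drawBlueHigh, towardFraction)
    towardLow <- paintClass(lowMask, .drawBlueLow, towardFraction)
    mk <- function(base, toward, want) {
      m <- matrix(FALSE, h, w)
      idx <- which(base)
      m[idx[toward == want]] <- TRUE
      m
    }
    masks <- list(lightBlue = mk(highMask, towardHigh, FALSE),
                  darkBlue = mk(lowMask, towardLow, FALSE),
                  lightRed = mk(highMask, towardHigh, TRUE),
                  darkRed = mk(lowMask, towardLow, TRUE))
    px <- array(0L, c(h, w, 3L))
    px[, , 1L] <- R; px[, , 2L] <- G; px[, , 3L] <- B
    nPainted <- sum(highMask) + sum(lowMask)
    truth <- new("SyntheticTruth", masks = masks,
                 fractions = c(doppler = nPainted / nroi,
                               high = if (nPainted > 0L) sum(highMask) / nPainted else NA_real_,
                               toward = if (nPainted > 0L)
                                 (sum(masks$lightRed) + sum(masks$darkRed)) / nPainted
                               else NA_real_),
                 seed = as.integer(seed))
    list(frame = UltrasoundFrame(px, modality = "doppler"), truth = truth)
  })
}

#' Default synthetic cohort composition
#'
#' Site-level generator parameters of the default synthetic cohort: one
#' row per site x metric with the number of subjects and the mean/sd of
#' the truth fraction (VR/MPR: painted Doppler fraction; FR: fascicular
#' fraction) and of the high-velocity class mix. The area-fraction means
#' mirror the magnitudes reported for traumatic neuroma cohorts
#' (neuroma VR about 43\%, unaffected nerve about 14\%, healthy control
#' about 18\%, denervated muscle MPR about 14\% versus about 54\%
#' contralateral; neuroma FR about 88\% versus about 51\%/54\%); the
#' spreads are plausible choices, as only group means are available.
#'
#' @return data.frame with columns \code{site}, \code{metric},
#'   \code{nSubjects}, \code{fracMean}, \code{fracSd}, \code{highMean},
#'   \code{highSd}.
#' @export
cohortSiteDefaults <- function() {
  data.frame(
    site = c("neuroma", "unaffected", "healthy_control",
             "muscle_denervated", "muscle_control",
             "neuroma", "unaffected", "healthy_control"),
    metric = c("vr", "vr", "vr", "mpr", "mpr", "fr", "fr", "fr"),
    nSubjects = c(9L, 9L, 4L, 9L, 9L, 9L, 9L, 4L),
    fracMean = c(0.4326, 0.1414, 0.1772, 0.1422, 0.5415,
                 0.8787, 0.5066, 0.5431),
    fracSd = c(0.08, 0.04, 0.04, 0.05, 0.10, 0.06, 0.06, 0.06),
    highMean = c(0.36, 0.390, 0.328, 0.454, 0.875, NA, NA, NA),
    highSd = c(0.15, 0.08, 0.08, 0.10, 0.06, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rnorm(1L, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Simulate a measurement cohort of synthetic frames
#'
#' Draws per-subject truth fractions from truncated normal
#' distributions given by the site table (see
#' \code{\link{cohortSiteDefaults}}), then per-frame truths around the
#' subject value, and returns a manifest with one row per frame. Each
#' frame is reproducible from its manifest row alone (site parameters
#' are not needed), so frames can either be written to \code{outDir}
#' as PNG + JSON-ROI pairs or regenerated on the fly by
#' \code{\link{measureCohort}}.
#'
#' @param sites site parameter table; default
#'   \code{\link{cohortSiteDefaults}()}. Every site needs at least two
#'   subjects.
#' @param framesPerSite frames acquired per subject and site (the
#'   reference acquisition protocol uses 6).
#' @param seed master seed; per-frame seeds are derived from it.
#' @param outDir if non-NULL, frames and ROIs are written there along
#'   with \code{manifest.csv}.
#' @param frameSize side length of the square frames, pixels.
#' @param roiRadius radius of the circular (16-gon) ROI, pixels.
#' @return the manifest data.frame: \code{subject_id}, \code{site},
#'   \code{metric}, \code{frame}, \code{truth_frac},
#'   \code{truth_high}, \code{toward}, \code{frame_seed},
#'   \code{frame_size}, \code{roi_radius}, \code{path},
#'   \code{roi_path}.
#' @export
simulateCohort <- function(sites = cohortSiteDefaults(), framesPerSite = 6L,
                           seed = 1L, outDir = NULL, frameSize = 128L,
                           roiRadius = 44) {
  need <- c("site", "metric", "nSubjects", "fracMean", "fracSd")
  if (!is.data.frame(sites) || !all(need %in% names(sites)))
    .sqError("sites must be a data.frame with columns site, metric, nSubjects, fracMean, fracSd",
             "sq_validation_error")
  if (any(sites$nSubjects < 2L))
    .sqError("every site needs at least 2 subjects", "sq_validation_error")
  okSites <- c("neuroma", "unaffected", "healthy_control",
               "muscle_denervated", "muscle_control")
  if (!all(sites$site %in% okSites))
    .sqError(paste0("site must be one of: ", paste(okSites, collapse = ", ")),
             "sq_validation_error")
  rows <- .withSeed(seed, {
    out <- list()
    for (i in seq_len(nrow(sites))) {
      s <- sites[i, ]
      subjMeans <- .rtruncnorm(s$nSubjects, s$fracMean, s$fracSd, 0.01, 0.97)
      subjHigh <- if (!is.na(s$highMean))
        .rtruncnorm(s$nSubjects, s$highMean, s$highSd, 0.02, 0.98)
      else rep(NA_real_, s$nSubjects)
      for (j in seq_len(s$nSubjects)) {
        fr <- .rtruncnorm(framesPerSite, subjMeans[j], s$fracSd / 3, 0.005, 0.98)
        hi <- if (!is.na(subjHigh[j]))
          .rtruncnorm(framesPerSite, subjHigh[j], max(0.02, (s$highSd %||% 0.05) / 3), 0.01, 0.99)
        else rep(NA_real_, framesPerSite)
        tow <- runif(framesPerSite, 0.3, 0.7)
        fs <- sample.int(2147483646L, framesPerSite)
        out[[length(out) + 1L]] <- data.frame(
          subject_id = sprintf("%s_%s_s%02d", s$metric, s$site, j),
          site = s$site, metric = s$metric, frame = seq_len(framesPerSite),
          truth_frac = fr, truth_high = hi, toward = tow, frame_seed = fs,
          frame_size = as.integer(frameSize), roi_radius = roiRadius,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  rows$path <- NA_character_
  rows$roi_path <- NA_character_
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    roi <- circularRoi(frameSize, roiRadius)
    for (k in seq_len(nrow(rows))) {
      sim <- .simulateManifestRow(rows[k, ])
      base <- sprintf("%s_f%d", rows$subject_id[k], rows$frame[k])
      rows$path[k] <- file.path(outDir, paste0(base, ".png"))
      rows$roi_path[k] <- file.path(outDir, paste0(base, ".roi.json"))
      writeFrame(sim$frame, rows$path[k])
      writeRoiJson(roi, rows$roi_path[k])
    }
    utils::write.csv(rows, file.path(outDir, "manifest.csv"), row.names = FALSE)
  }
  rows
}

#' Circular (16-gon) ROI centered in a square frame
#'
#' @param frameSize side length of the frame, pixels.
#' @param radius polygon radius, pixels.
#' @param label region label.
#' @return a \linkS4class{RoiPolygon}.
#' @export
circularRoi <- function(frameSize, radius, label = "") {
  ang <- seq(0, 2 * pi, length.out = 17L)[-17L]
  c0 <- frameSize / 2
  RoiPolygon(cbind(c0 + radius * cos(ang), c0 + radius * sin(ang)), label = label)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a

.simulateManifestRow <- function(row) {
  roi <- circularRoi(row$frame_size, row$roi_radius)
  dim <- c(row$frame_size, row$frame_size)
  if (row$metric == "fr") {
    simulateBmodeNerve(roi, fascicleFraction = row$truth_frac,
                       seed = row$frame_seed, dim = dim)
  } else {
    simulateDopplerFrame(roi, dopplerFraction = row$truth_frac,
                         highClassFraction = row$truth_high,
                         towardFraction = row$toward,
                         seed = row$frame_seed, dim = dim)
  }
}

#' Measure a simulated cohort
#'
#' Runs the quantification on every frame of a cohort manifest — FR
#' for B-mode rows, VR/MPR (plus the high-velocity proportion) for
#' Doppler rows — and returns the per-frame measurement table expected
#' by \code{\link{aggregatePerSubject}}. Frames are read from their
#' manifest paths when present and regenerated deterministically from
#' the manifest seeds otherwise.
#'
#' @param manifest manifest as returned by \code{\link{simulateCohort}}.
#' @param radius rolling-ball radius for the FR pipeline.
#' @param minParticlePx particle-size filter of the Doppler pipeline.
#' @return data.frame \code{subject_id}, \code{site}, \code{metric},
#'   \code{value} (one extra \code{high_prop} row block for Doppler
#'   metrics).
#' @export
measureCohort <- function(manifest, radius = 50, minParticlePx = 1L) {
  out <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    row <- manifest[k, ]
    roi <- circularRoi(row$frame_size, row$roi_radius)
    frame <- if (!is.na(row$path) && file.exists(row$path)) readFrame(row$path)
             else .simulateManifestRow(row)$frame
    if (row$metric == "fr") {
      res <- computeFR(frame, roi, radius = radius)
      out[[k]] <- data.frame(subject_id = row$subject_id, site = row$site,
                             metric = "fr", value = res@frPercent,
                             stringsAsFactors = FALSE)
    } else {
      res <- computePerfusion(frame, roi, minParticlePx = minParticlePx)
      out[[k]] <- data.frame(
        subject_id = rep(row$subject_id, 2L), site = rep(row$site, 2L),
        metric = c(row$metric, paste0(row$metric, "_high_prop")),
        value = c(res@vrPercent, res@highVelocityProportion),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[!is.na(res$value), , drop = FALSE]
}
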