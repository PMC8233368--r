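#' Split an RGB Doppler frame into its channels
#'
#' @param frame 3-channel \linkS4class{UltrasoundFrame}.
#' @return named list of integer matrices \code{R}, \code{G}, \code{B},
#'   intensities preserved bit-exactly.
#' @export
splitRGB <- function(frame) {
  stopifnot(is(frame, "UltrasoundFrame"))
  px <- frame@pixels
  if (length(dim(px)) != 3L)
    .sqError("splitRGB expects a 3-channel (color-Doppler) frame", "sq_modality_error")
  ch <- lapply(1:3, function(k) {
    m <- px[, , k]
    dim(m) <- dim(px)[1:2]   # single-row frames must stay matrices
    m
  })
  names(ch) <- c("R", "G", "B")
  ch
}

#' Channel-difference decomposition of a color-Doppler overlay
#'
#' Classifies Doppler overlay pixels into four velocity/direction
#' classes by saturating 8-bit channel subtraction: light blue (high
#' velocity away from the transducer) = G - R, dark blue (low velocity
#' away) = B - G, light red (high velocity toward) = G - B, dark red
#' (low velocity toward) = R - G, negatives clamped to 0. Grayscale
#' pixels (R = G = B), i.e. the B-mode background under the overlay,
#' are exactly 0 in all four maps.
#'
#' @param R,G,B integer matrices of one shape (see
#'   \code{\link{splitRGB}}).
#' @return a \linkS4class{DopplerMaps}.
#' @export
dopplerDifferenceMaps <- function(R, G, B) {
  if (!identical(dim(R), dim(G)) || !identical(dim(G), dim(B)))
    .sqError("R, G, B must share one shape", "sq_validation_error")
  sat <- function(a, b) {
    m <- pmax(a - b, 0L)
    dim(m) <- dim(a)
    storage.mode(m) <- "integer"
    m
  }
  new("DopplerMaps",
      lightBlue = sat(G, R), darkBlue = sat(B, G),
      lightRed = sat(G, B), darkRed = sat(R, G))
}

#' Pixel-wise maximum projection of intensity maps
#'
#' Merges two or more same-shape intensity maps into their pixel-wise
#' maximum — the direction-independent merge of the light (or dark)
#' class pair.
#'
#' @param ... two or more integer matrices of one shape.
#' @return integer matrix.
#' @export
maxProject <- function(...) {
  maps <- list(...)
  if (length(maps) < 2L)
    .sqError("maxProject needs at least two maps", "sq_validation_error")
  d <- dim(maps[[1L]])
  for (m in maps) if (!identical(dim(m), d))
    .sqError("all maps must share one shape", "sq_validation_error")
  out <- Reduce(pmax, maps)
  dim(out) <- d
  storage.mode(out) <- "integer"
  out
}

#' Select the Doppler signal within a ROI
#'
#' Thresholds the map with the maximum-entropy criterion computed on the
#' ROI histogram, binarizes (foreground = above threshold), labels
#' 8-connected components and keeps those of at least
#' \code{minParticlePx} pixels (particle analysis; the default of 1
#' keeps everything), intersecting the result with the ROI.
#'
#' A map that is constant within the ROI — typically all zero, i.e. no
#' flow signal — has a degenerate histogram; absent flow is a valid
#' observation, so the result is an empty mask with the
#' \code{degenerate} flag set, not an error.
#'
#' @param map integer intensity matrix (a merged difference map).
#' @param roiMask \linkS4class{BinaryMask} or logical matrix.
#' @param minParticlePx minimum component area kept, in pixels.
#' @return a \linkS4class{BinaryMask} carrying the threshold used.
#' @export
selectSignal <- function(map, roiMask, minParticlePx = 1L) {
  m <- .asMaskMatrix(roiMask)
  if (!identical(dim(map), dim(m)))
    .sqError("map and ROI mask must share one shape", "sq_validation_error")
  if (!any(m))
    .sqError("ROI mask is empty", "sq_empty_region")
  hist <- histogram256(map, m)
  if (.occupiedBins(hist@counts) < 2L)
    return(BinaryMask(matrix(FALSE, nrow(map), ncol(map)),
                      threshold = NA_real_, degenerate = TRUE))
  t <- maxEntropyThreshold(hist)
  fg <- m & map > t
  if (minParticlePx > 1L && any(fg)) {
    lab <- labelComponents(fg)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= minParticlePx)
    fg <- matrix(lab %in% keep, nrow(fg), ncol(fg))
  }
  BinaryMask(fg, threshold = t)
}

#' Correct the low-velocity signal for high-velocity bleed-through
#'
#' The low-velocity difference maps also respond to high-velocity
#' overlay pixels (e.g. the B - G residue of a cyan pixel), so the raw
#' low-velocity mask contains the high-velocity signal. The correction
#' removes it by set difference: low \\ high.
#'
#' @param lowMask,highMask \linkS4class{BinaryMask} or logical matrices
#'   of one shape.
#' @return a \linkS4class{BinaryMask}.
#' @export
correctLowVelocity <- function(lowMask, highMask) {
  lo <- .asMaskMatrix(lowMask); hi <- .asMaskMatrix(highMask)
  if (!identical(dim(lo), dim(hi)))
    .sqError("masks must share one shape", "sq_validation_error")
  BinaryMask(lo & !hi)
}

#' Vascular / muscle-perfusion ratio of a color-Doppler frame
#'
#' Runs the full Doppler quantification: split the RGB frame, build the
#' four channel-difference maps, merge the light classes (high
#' velocity) and the dark classes (low velocity) as maximum
#' projections, select the signal of each merged map within the ROI,
#' correct the low-velocity mask by subtracting the high-velocity mask,
#' and take the union as the total perfusion signal. The vascular
#' ratio VR (identically, the muscle perfusion ratio MPR on muscle
#' frames) is 100 x total signal area / ROI area; the high-velocity
#' proportion is high area / total area, undefined (NA) when there is
#' no signal.
#'
#' With \code{correctIntensities = TRUE} the bleed-through correction is
#' instead applied in the intensity domain — the merged high map is
#' subtracted (saturating) from the merged low map before signal
#' selection — an alternative reading of the correction step kept for
#' sensitivity analysis.
#'
#' @param frame 3-channel \linkS4class{UltrasoundFrame}.
#' @param roi \linkS4class{RoiPolygon}.
#' @param minParticlePx minimum particle size kept by signal selection.
#' @param correctIntensities apply the low-velocity correction to
#'   intensity maps before thresholding instead of to binarized masks.
#' @return a \linkS4class{PerfusionResult}.
#' @export
computePerfusion <- function(frame, roi, minParticlePx = 1L,
                             correctIntensities = FALSE) {
  stopifnot(is(frame, "UltrasoundFrame"), is(roi, "RoiPolygon"))
  roiMask <- rasterizeRoi(roi, frameDim(frame))
  nroi <- areaPx(roiMask)
  if (nroi < 1L)
    .sqError("ROI rasterizes to an empty mask", "sq_empty_region")
  ch <- splitRGB(frame)
  maps <- dopplerDifferenceMaps(ch$R, ch$G, ch$B)
  highMap <- maxProject(maps@lightBlue, maps@lightRed)
  lowMap <- maxProject(maps@darkBlue, maps@darkRed)
  high <- selectSignal(highMap, roiMask, minParticlePx = minParticlePx)
  if (correctIntensities) {
    lowMap <- pmax(lowMap - highMap, 0L)
    storage.mode(lowMap) <- "integer"
  }
  low <- selectSignal(lowMap, roiMask, minParticlePx = minParticlePx)
  lowCorr <- correctLowVelocity(low, high)
  total <- maskPixels(high) | maskPixels(lowCorr)
  nHigh <- areaPx(high); nLow <- areaPx(lowCorr); nTot <- sum(total)
  new("PerfusionResult",
      roiAreaPx = nroi, highAreaPx = nHigh, lowCorrectedAreaPx = nLow,
      totalAreaPx = nTot,
      vrPercent = 100 * nTot / nroi,
      highVelocityProportion = if (nTot > 0L) nHigh / nTot else NA_real_,
      thresholdsUsed = c(high = high@threshold, low = low@threshold),
      degenerate = c(high = high@degenerate, low = low@degenerate))
}
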