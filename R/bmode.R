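#' Invert a grayscale frame
#'
#' Maps every intensity v to 255 - v, so that hypoechogenic (dark)
#' fascicles become the bright foreground that thresholding selects.
#'
#' @param frame grayscale \linkS4class{UltrasoundFrame}.
#' @return the inverted frame.
#' @export
invertFrame <- function(frame) {
  stopifnot(is(frame, "UltrasoundFrame"))
  if (length(dim(frame@pixels)) != 2L)
    .sqError("invertFrame expects a grayscale frame", "sq_modality_error")
  px <- 255L - frame@pixels
  UltrasoundFrame(px, pixelArea = frame@pixelArea, modality = frame@modality)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale morphological opening of
#' the image with a flat disk structuring element of the given radius
#' (the flat rolling-ball estimate) and subtracts it, clamping at 0.
#' Features narrower than the ball survive the subtraction; smooth
#' large-scale intensity drifts are removed. The image is padded by edge
#' replication before the morphology so border pixels are treated
#' deterministically.
#'
#' @param frame grayscale \linkS4class{UltrasoundFrame}.
#' @param radius disk radius in pixels (>= 1). The default of 50 px is
#'   the common background-subtraction default of raster image tools.
#' @return frame with the background removed; pixel-wise \code{<=} the
#'   input.
#' @export
rollingBallBackground <- function(frame, radius = 50) {
  stopifnot(is(frame, "UltrasoundFrame"))
  img <- .asGrayMatrix(frame)
  radius <- as.integer(radius)
  if (radius < 1L)
    .sqError("rolling-ball radius must be >= 1", "sq_parameter_error")
  h <- nrow(img); w <- ncol(img)
  if (radius > h && radius > w)
    .sqError("rolling-ball radius exceeds both image dimensions", "sq_parameter_error")
  pad <- radius
  rows <- c(rep(1L, pad), seq_len(h), rep(h, pad))
  cols <- c(rep(1L, pad), seq_len(w), rep(w, pad))
  padded <- img[rows, cols] / 255
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  bg <- EBImage::dilate(EBImage::erode(padded, brush), brush)
  bg <- bg[pad + seq_len(h), pad + seq_len(w)]
  out <- pmax(img - .roundHalfUp(bg * 255), 0L)
  storage.mode(out) <- "integer"
  UltrasoundFrame(out, pixelArea = frame@pixelArea, modality = frame@modality)
}

#' Fascicular ratio of a B-mode frame
#'
#' Runs the B-mode quantification pipeline: convert to 8-bit grayscale,
#' invert, enhance contrast by rolling-ball background subtraction,
#' threshold the ROI histogram with the maximum-entropy criterion, and
#' report the fraction of ROI pixels above threshold — the
#' hypoechogenic (fascicular) area fraction FR in percent.
#'
#' A ROI whose processed histogram occupies a single bin (a uniform
#' region, e.g. a saturated or signal-free frame) cannot be thresholded;
#' such frames report FR = 0 with the \code{degenerate} flag set rather
#' than failing, so batch runs survive pathological frames while
#' remaining auditable.
#'
#' @param frame \linkS4class{UltrasoundFrame} (grayscale, or RGB which
#'   is converted first).
#' @param roi \linkS4class{RoiPolygon} covering the nerve cross-section.
#' @param radius rolling-ball radius in pixels (see
#'   \code{\link{rollingBallBackground}}).
#' @return a \linkS4class{FascicleResult}.
#' @export
computeFR <- function(frame, roi, radius = 50) {
  stopifnot(is(frame, "UltrasoundFrame"), is(roi, "RoiPolygon"))
  mask <- rasterizeRoi(roi, frameDim(frame))
  nroi <- areaPx(mask)
  if (nroi < 1L)
    .sqError("ROI rasterizes to an empty mask", "sq_empty_region")
  enhanced <- rollingBallBackground(invertFrame(toGray8(frame)), radius = radius)
  hist <- histogram256(enhanced, mask)
  if (.occupiedBins(hist@counts) < 2L) {
    return(new("FascicleResult", hypoechoicAreaPx = 0L, roiAreaPx = nroi,
               frPercent = 0, thresholdUsed = NA_real_, degenerate = TRUE))
  }
  t <- maxEntropyThreshold(hist)
  fg <- applyThreshold(enhanced, t, mask)
  nfg <- areaPx(fg)
  new("FascicleResult", hypoechoicAreaPx = nfg, roiAreaPx = nroi,
      frPercent = 100 * nfg / nroi, thresholdUsed = as.numeric(t),
      degenerate = FALSE)
}

#' Calibrated cross-section area of a ROI
#'
#' Counts the pixels of the rasterized ROI and converts to mm^2 with the
#' pixel-area calibration of the acquisition (for the reference probe
#' setting, 0.004017 mm^2 per pixel).
#'
#' @param roi \linkS4class{RoiPolygon}.
#' @param dim frame shape \code{c(H, W)}.
#' @param pixelArea mm^2 per pixel (> 0); must be supplied — there is no
#'   silent default, because CSA without calibration is meaningless.
#' @return a \linkS4class{CsaResult}.
#' @export
computeCSA <- function(roi, dim, pixelArea) {
  if (missing(pixelArea) || is.null(pixelArea) || is.na(pixelArea))
    .sqError("pixel-area calibration is required for CSA; supply pixelArea (CLI: --pixel-area-mm2)",
             "sq_missing_calibration")
  if (pixelArea <= 0)
    .sqError("pixelArea must be > 0", "sq_parameter_error")
  n <- suppressWarnings(areaPx(rasterizeRoi(roi, dim)))
  new("CsaResult", roiAreaPx = n, pixelArea = as.numeric(pixelArea),
      csaMm2 = n * pixelArea)
}

#' Cross-section ratio of affected to unaffected nerve
#'
#' CSR = mean(affected CSAs) / mean(unaffected CSAs), the per-patient
#' enlargement factor of the lesioned nerve segment. Any number of
#' frames per side (>= 1) is accepted; the study design of six frames
#' per site is the common special case.
#'
#' @param affectedCsas numeric vector of CSAs (mm^2) of the affected
#'   site.
#' @param unaffectedCsas numeric vector of CSAs (mm^2) of the unaffected
#'   site.
#' @return the ratio (numeric scalar).
#' @examples
#' computeCSR(c(4, 4, 4), c(2, 2, 2))  # 2
#' @export
computeCSR <- function(affectedCsas, unaffectedCsas) {
  if (length(affectedCsas) < 1L || length(unaffectedCsas) < 1L)
    .sqError("both CSA lists must be non-empty", "sq_validation_error")
  mu <- mean(unaffectedCsas)
  if (mu == 0)
    .sqError("mean unaffected CSA is zero; CSR undefined", "sq_division_error")
  mean(affectedCsas) / mu
}
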