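#' @import methods
NULL

.validIntensities <- function(px) {
  if (!is.numeric(px)) return("pixels must be numeric")
  if (anyNA(px)) return("pixels must not contain NA")
  if (any(px < 0 | px > 255)) return("pixel intensities must lie in [0, 255]")
  if (any(px != floor(px))) return("pixel intensities must be whole numbers (8-bit)")
  NULL
}

#' UltrasoundFrame: an 8-bit ultrasound raster frame
#'
#' Container for a single transverse-view ultrasound frame. Grayscale
#' (B-mode) frames hold an H x W integer matrix, color-Doppler frames an
#' H x W x 3 integer array, all intensities in [0, 255]. The frame
#' optionally carries the pixel-area calibration (mm^2 per pixel) used to
#' convert pixel counts to cross-section areas.
#'
#' The coordinate convention throughout the package is x = column,
#' y = row, origin at the top-left corner, zero-based: pixel (x, y)
#' covers the unit square [x, x+1) x [y, y+1) and corresponds to matrix
#' element \code{pixels[y + 1, x + 1]}.
#'
#' @slot pixels integer matrix (grayscale) or H x W x 3 array (RGB),
#'   values in [0, 255].
#' @slot pixelArea numeric(1), mm^2 covered by one pixel; \code{NA} when
#'   no calibration is available.
#' @slot modality \code{"bmode"} or \code{"doppler"}; Doppler frames must
#'   have three channels.
#'
#' @examples
#' f <- UltrasoundFrame(matrix(0L, 4, 4), modality = "bmode")
#' frameDim(f)
#' @export
setClass("UltrasoundFrame",
  representation(pixels = "array", pixelArea = "numeric", modality = "character"),
  prototype(pixels = matrix(0L, 1, 1), pixelArea = NA_real_, modality = "bmode")
)

setValidity("UltrasoundFrame", function(object) {
  px <- object@pixels
  d <- dim(px)
  if (!(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    return("pixels must be H x W (grayscale) or H x W x 3 (RGB)")
  if (d[1] < 1L || d[2] < 1L) return("frame must have H >= 1 and W >= 1")
  msg <- .validIntensities(px)
  if (!is.null(msg)) return(msg)
  if (length(object@modality) != 1L ||
      !object@modality %in% c("bmode", "doppler"))
    return("modality must be 'bmode' or 'doppler'")
  if (object@modality == "doppler" && length(d) != 3L)
    return("a doppler frame must have 3 channels")
  pa <- object@pixelArea
  if (length(pa) != 1L) return("pixelArea must have length 1")
  if (!is.na(pa) && pa <= 0) return("pixelArea must be > 0")
  TRUE
})

#' @param pixels integer matrix or H x W x 3 array of 8-bit intensities.
#' @param pixelArea mm^2 per pixel, or \code{NA}.
#' @param modality \code{"bmode"} or \code{"doppler"}; by default inferred
#'   from the number of channels.
#' @rdname UltrasoundFrame-class
#' @export
UltrasoundFrame <- function(pixels, pixelArea = NA_real_, modality = NULL) {
  if (is.null(dim(pixels))) stop("pixels must be a matrix or 3-d array")
  storage.mode(pixels) <- "integer"
  if (is.null(modality))
    modality <- if (length(dim(pixels)) == 3L) "doppler" else "bmode"
  new("UltrasoundFrame", pixels = pixels,
      pixelArea = as.numeric(pixelArea), modality = modality)
}

#' RoiPolygon: a region of interest as a pixel-coordinate polygon
#'
#' Ordered polygon vertices in the frame coordinate system (x = column,
#' y = row, origin top-left, zero-based). The polygon must be simple
#' (non-self-intersecting) and have at least 3 vertices, matching the
#' hand-drawn nerve/muscle outlines the quantification operates on.
#'
#' @slot vertices n x 2 numeric matrix of (x, y) vertices, n >= 3.
#' @slot label free-text label (e.g. \code{"neuroma"}, \code{"muscle"}).
#' @export
setClass("RoiPolygon",
  representation(vertices = "matrix", label = "character"),
  prototype(vertices = cbind(c(0, 1, 0), c(0, 0, 1)), label = "")
)

.segIntersects <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

.isSimplePolygon <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n)) {
    a1 <- v[i, ]; a2 <- v[if (i == n) 1L else i + 1L, ]
    for (j in seq_len(n)) {
      if (j == i) next
      jn <- if (j == n) 1L else j + 1L
      if (jn == i || j == (if (i == n) 1L else i + 1L)) next
      b1 <- v[j, ]; b2 <- v[jn, ]
      if (.segIntersects(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

setValidity("RoiPolygon", function(object) {
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L)
    return("vertices must be an n x 2 numeric matrix")
  if (nrow(v) < 3L) return("a polygon needs at least 3 vertices")
  if (anyNA(v)) return("vertices must not contain NA")
  if (!.isSimplePolygon(v)) return("polygon must be simple (non-self-intersecting)")
  if (length(object@label) != 1L) return("label must have length 1")
  TRUE
})

#' @param vertices n x 2 matrix (or list of pairs) of (x, y) vertices.
#' @param label free-text region label.
#' @rdname RoiPolygon-class
#' @export
RoiPolygon <- function(vertices, label = "") {
  v <- as.matrix(vertices)
  dimnames(v) <- NULL
  new("RoiPolygon", vertices = v, label = as.character(label))
}

#' BinaryMask: a pixel mask over a frame
#'
#' Logical H x W matrix marking a pixel set (rasterized ROI, or selected
#' signal). Masks produced by signal selection carry the threshold that
#' generated them and a degenerate flag raised when the underlying
#' histogram had fewer than two occupied bins (e.g. no Doppler signal in
#' the ROI), in which case the mask is empty by definition rather than
#' by thresholding.
#'
#' @slot pixels logical H x W matrix.
#' @slot threshold the 8-bit threshold used to produce the mask
#'   (\code{NA} for masks not born from thresholding).
#' @slot degenerate \code{TRUE} when the source histogram was degenerate.
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", threshold = "numeric", degenerate = "logical"),
  prototype(pixels = matrix(FALSE, 1, 1), threshold = NA_real_, degenerate = FALSE)
)

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels)) return("mask pixels must be logical")
  if (anyNA(object@pixels)) return("mask pixels must not contain NA")
  if (length(object@threshold) != 1L) return("threshold must have length 1")
  if (length(object@degenerate) != 1L || is.na(object@degenerate))
    return("degenerate must be TRUE or FALSE")
  TRUE
})

#' @param pixels logical matrix.
#' @param threshold threshold that produced the mask, if any.
#' @param degenerate degenerate-histogram flag.
#' @rdname BinaryMask-class
#' @export
BinaryMask <- function(pixels, threshold = NA_real_, degenerate = FALSE) {
  new("BinaryMask", pixels = pixels, threshold = as.numeric(threshold),
      degenerate = degenerate)
}

#' Histogram256: a 256-bin intensity histogram
#'
#' Counts of 8-bit intensities 0..255 over a masked pixel set; the input
#' to maximum-entropy thresholding.
#'
#' @slot counts integer vector of length 256; \code{counts[v + 1]} is the
#'   number of pixels with intensity v.
#' @export
setClass("Histogram256",
  representation(counts = "integer"),
  prototype(counts = integer(256))
)

setValidity("Histogram256", function(object) {
  if (length(object@counts) != 256L) return("counts must have length 256")
  if (anyNA(object@counts) || any(object@counts < 0L))
    return("counts must be non-negative")
  TRUE
})

#' @param counts integer vector of length 256.
#' @rdname Histogram256-class
#' @export
Histogram256 <- function(counts) {
  counts <- as.integer(counts)
  new("Histogram256", counts = counts)
}

#' DopplerMaps: channel-difference intensity maps of a color-Doppler frame
#'
#' The four saturating channel-difference maps that classify Doppler
#' overlay pixels by velocity tier and flow direction: light blue
#' (high velocity, away; G - R), dark blue (low velocity, away; B - G),
#' light red (high velocity, toward; G - B) and dark red (low velocity,
#' toward; R - G), each clamped at 0. Pixels with R = G = B (the
#' grayscale B-mode background under the color overlay) are exactly 0 in
#' all four maps.
#'
#' @slot lightBlue,darkBlue,lightRed,darkRed integer H x W matrices in
#'   [0, 255].
#' @export
setClass("DopplerMaps",
  representation(lightBlue = "matrix", darkBlue = "matrix",
                 lightRed = "matrix", darkRed = "matrix")
)

setValidity("DopplerMaps", function(object) {
  maps <- list(object@lightBlue, object@darkBlue, object@lightRed, object@darkRed)
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), d)) return("all four maps must share one shape")
    msg <- .validIntensities(m)
    if (!is.null(msg)) return(msg)
  }
  TRUE
})

#' FascicleResult: fascicular-ratio measurement of one B-mode frame
#'
#' @slot hypoechoicAreaPx pixels classified as hypoechogenic fascicle.
#' @slot roiAreaPx pixels in the rasterized ROI.
#' @slot frPercent fascicular ratio, 100 * hypoechoic / ROI.
#' @slot thresholdUsed maximum-entropy threshold applied (\code{NA} when
#'   degenerate).
#' @slot degenerate \code{TRUE} when the ROI histogram had a single
#'   occupied bin, in which case FR is reported as 0.
#' @export
setClass("FascicleResult",
  representation(hypoechoicAreaPx = "integer", roiAreaPx = "integer",
                 frPercent = "numeric", thresholdUsed = "numeric",
                 degenerate = "logical")
)

#' CsaResult: calibrated cross-section area of one ROI
#'
#' @slot roiAreaPx pixels in the rasterized ROI.
#' @slot pixelArea mm^2 per pixel used for calibration.
#' @slot csaMm2 cross-section area in mm^2.
#' @export
setClass("CsaResult",
  representation(roiAreaPx = "integer", pixelArea = "numeric", csaMm2 = "numeric")
)

#' PerfusionResult: Doppler area-fraction measurement of one frame
#'
#' Holds the signal areas and derived ratios of the color-Doppler
#' pipeline. \code{vrPercent} is the vascular ratio (or, on muscle
#' frames, the muscle perfusion ratio — the computation is identical),
#' \code{highVelocityProportion} the share of the total perfusion signal
#' carried by the high-velocity classes (\code{NA} when there is no
#' signal at all).
#'
#' @slot roiAreaPx,highAreaPx,lowCorrectedAreaPx,totalAreaPx pixel areas.
#' @slot vrPercent 100 * totalAreaPx / roiAreaPx.
#' @slot highVelocityProportion highAreaPx / totalAreaPx in [0, 1], or
#'   \code{NA} when totalAreaPx is 0.
#' @slot thresholdsUsed named numeric, thresholds of the high and low
#'   merged maps (\code{NA} when the respective histogram was degenerate).
#' @slot degenerate named logical, degenerate flags for the two maps.
#' @export
setClass("PerfusionResult",
  representation(roiAreaPx = "integer", highAreaPx = "integer",
                 lowCorrectedAreaPx = "integer", totalAreaPx = "integer",
                 vrPercent = "numeric", highVelocityProportion = "numeric",
                 thresholdsUsed = "numeric", degenerate = "logical")
)

setValidity("PerfusionResult", function(object) {
  if (object@totalAreaPx > object@roiAreaPx)
    return("total signal area cannot exceed the ROI area")
  if (object@highAreaPx > object@totalAreaPx)
    return("high-velocity area cannot exceed the total signal area")
  if (object@vrPercent < 0 || object@vrPercent > 100)
    return("vrPercent must lie in [0, 100]")
  p <- object@highVelocityProportion
  if (!is.na(p) && (p < 0 || p > 1))
    return("highVelocityProportion must lie in [0, 1]")
  TRUE
})

#' SyntheticTruth: ground truth attached to a simulated frame
#'
#' @slot masks named list of logical matrices, the painted pixel masks
#'   (B-mode: \code{fascicle}; Doppler: \code{lightBlue}, \code{darkBlue},
#'   \code{lightRed}, \code{darkRed}).
#' @slot fractions named numeric vector of realized area fractions.
#' @slot seed integer seed the frame was generated from.
#' @export
setClass("SyntheticTruth",
  representation(masks = "list", fractions = "numeric", seed = "integer")
)
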