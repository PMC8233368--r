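#' Accessors for SonoQuant objects
#'
#' Small accessor generics used across the package's S4 classes:
#' \code{framePixels} returns the raw intensity array, \code{frameDim}
#' the (H, W) shape, \code{pixelArea} the mm^2-per-pixel calibration,
#' \code{modality} the frame modality, \code{maskPixels} the logical
#' matrix of a mask, \code{areaPx} the number of selected pixels, and
#' \code{dopplerMap} one of the four named channel-difference maps.
#'
#' @param x an object of the documented classes.
#' @param which for \code{dopplerMap}: one of \code{"lightBlue"},
#'   \code{"darkBlue"}, \code{"lightRed"}, \code{"darkRed"}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("framePixels", function(x) standardGeneric("framePixels"))
#' @rdname accessors
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))
#' @rdname accessors
#' @export
setGeneric("pixelArea", function(x) standardGeneric("pixelArea"))
#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setGeneric("maskPixels", function(x) standardGeneric("maskPixels"))
#' @rdname accessors
#' @export
setGeneric("areaPx", function(x) standardGeneric("areaPx"))
#' @rdname accessors
#' @export
setGeneric("dopplerMap", function(x, which) standardGeneric("dopplerMap"))
#' @rdname accessors
#' @export
setGeneric("roiVertices", function(x) standardGeneric("roiVertices"))
#' @rdname accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))
#' @rdname accessors
#' @export
setGeneric("histCounts", function(x) standardGeneric("histCounts"))

#' @rdname accessors
#' @export
setMethod("framePixels", "UltrasoundFrame", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("frameDim", "UltrasoundFrame", function(x) dim(x@pixels)[1:2])
#' @rdname accessors
#' @export
setMethod("pixelArea", "UltrasoundFrame", function(x) x@pixelArea)
#' @rdname accessors
#' @export
setMethod("modality", "UltrasoundFrame", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("maskPixels", "BinaryMask", function(x) x@pixels)
#' @rdname accessors
#' @export
setMethod("areaPx", "BinaryMask", function(x) sum(x@pixels))
#' @rdname accessors
#' @export
setMethod("roiVertices", "RoiPolygon", function(x) x@vertices)
#' @rdname accessors
#' @export
setMethod("roiLabel", "RoiPolygon", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("histCounts", "Histogram256", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("dopplerMap", "DopplerMaps", function(x, which) {
  which <- match.arg(which, c("lightBlue", "darkBlue", "lightRed", "darkRed"))
  slot(x, which)
})

setMethod("show", "UltrasoundFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("UltrasoundFrame: %d x %d, %s, %s\n", d[1], d[2],
              if (length(d) == 3L) "RGB" else "grayscale", object@modality))
  if (!is.na(object@pixelArea))
    cat(sprintf("  pixel area: %g mm^2\n", object@pixelArea))
})

setMethod("show", "RoiPolygon", function(object) {
  cat(sprintf("RoiPolygon: %d vertices%s\n", nrow(object@vertices),
              if (nzchar(object@label)) paste0(", label '", object@label, "'") else ""))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask: %d x %d, %d px selected", nrow(object@pixels),
              ncol(object@pixels), sum(object@pixels)))
  if (!is.na(object@threshold))
    cat(sprintf(" (threshold %d)", as.integer(object@threshold)))
  if (object@degenerate) cat(" [degenerate histogram]")
  cat("\n")
})

setMethod("show", "DopplerMaps", function(object) {
  d <- dim(object@lightBlue)
  cat(sprintf("DopplerMaps: %d x %d; nonzero px LB %d, DB %d, LR %d, DR %d\n",
              d[1], d[2], sum(object@lightBlue > 0), sum(object@darkBlue > 0),
              sum(object@lightRed > 0), sum(object@darkRed > 0)))
})

setMethod("show", "FascicleResult", function(object) {
  cat(sprintf("FascicleResult: FR %.2f%% (%d / %d px)", object@frPercent,
              object@hypoechoicAreaPx, object@roiAreaPx))
  if (object@degenerate) cat(" [degenerate ROI histogram]")
  else cat(sprintf(", threshold %d", as.integer(object@thresholdUsed)))
  cat("\n")
})

setMethod("show", "CsaResult", function(object) {
  cat(sprintf("CsaResult: %d px x %g mm^2/px = %g mm^2\n",
              object@roiAreaPx, object@pixelArea, object@csaMm2))
})

setMethod("show", "PerfusionResult", function(object) {
  cat(sprintf("PerfusionResult: VR/MPR %.2f%% (total %d / ROI %d px)\n",
              object@vrPercent, object@totalAreaPx, object@roiAreaPx))
  cat(sprintf("  high %d px, corrected low %d px, high-velocity proportion %s\n",
              object@highAreaPx, object@lowCorrectedAreaPx,
              if (is.na(object@highVelocityProportion)) "undefined"
              else sprintf("%.3f", object@highVelocityProportion)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", paste(sprintf("%s=%.4f", names(object@fractions),
                                       object@fractions), collapse = ", "),
      sprintf("(seed %d)\n", object@seed))
})
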