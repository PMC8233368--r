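#' Read an 8-bit ultrasound frame from PNG or TIFF
#'
#' Reads an 8-bit, 1- or 3-channel raster image bit-exactly into an
#' \linkS4class{UltrasoundFrame}. Higher bit depths are rejected rather
#' than silently rescaled, because rescaling would shift every
#' histogram-based threshold downstream; alpha channels are likewise
#' rejected so that no hidden premultiplication can alter intensities.
#'
#' @param path path to a \code{.png}, \code{.tif} or \code{.tiff} file.
#' @param pixelArea mm^2 per pixel calibration to attach, or \code{NA}.
#' @param modality \code{"bmode"} or \code{"doppler"}; default inferred
#'   from the channel count (3 channels = doppler).
#' @return an \linkS4class{UltrasoundFrame}.
#' @examples
#' p <- tempfile(fileext = ".png")
#' writeFrame(UltrasoundFrame(matrix(0L, 4, 4)), p)
#' readFrame(p)
#' @export
readFrame <- function(path, pixelArea = NA_real_, modality = NULL) {
  if (!file.exists(path))
    .sqError(paste0("cannot read image: file not found: ", path), "sq_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    hdr <- readBin(path, "raw", n = 26L)
    bitDepth <- as.integer(hdr[25])
    colorType <- as.integer(hdr[26])
    if (bitDepth != 8L)
      .sqError(sprintf("unsupported PNG bit depth %d (only 8-bit supported)", bitDepth),
               "sq_format_error")
    if (!colorType %in% c(0L, 2L, 3L))
      .sqError(sprintf("unsupported PNG color type %d (alpha channels not supported)", colorType),
               "sq_format_error")
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(arr, "bits.per.sample")
    if (!is.null(bits) && bits != 8L)
      .sqError(sprintf("unsupported TIFF bit depth %d (only 8-bit supported)", bits),
               "sq_format_error")
    attributes(arr) <- list(dim = dim(arr))
  } else {
    .sqError(paste0("unsupported image format: .", ext, " (PNG or TIFF expected)"),
             "sq_format_error")
  }
  d <- dim(arr)
  if (length(d) == 3L) {
    if (d[3] == 3L) {
      ## keep
    } else if (d[3] == 1L) {
      arr <- arr[, , 1L]
    } else {
      .sqError(sprintf("unsupported channel count %d (1 or 3 channels expected)", d[3]),
               "sq_format_error")
    }
  }
  px <- .roundHalfUp(arr * 255)
  storage.mode(px) <- "integer"
  UltrasoundFrame(px, pixelArea = pixelArea, modality = modality)
}

#' Write an 8-bit frame to PNG or TIFF
#'
#' Lossless counterpart of \code{\link{readFrame}}: intensities survive a
#' write/read round trip bit-exactly.
#'
#' @param frame an \linkS4class{UltrasoundFrame}.
#' @param path output path ending in \code{.png}, \code{.tif} or
#'   \code{.tiff}.
#' @return \code{path}, invisibly.
#' @export
writeFrame <- function(frame, path) {
  stopifnot(is(frame, "UltrasoundFrame"))
  ext <- tolower(tools::file_ext(path))
  arr <- frame@pixels / 255
  if (ext == "png") png::writePNG(arr, path)
  else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  else .sqError(paste0("unsupported output format: .", ext), "sq_format_error")
  invisible(path)
}

#' Collapse an RGB frame to 8-bit grayscale
#'
#' RGB frames are collapsed by the unweighted channel mean, rounded
#' half-up and clamped to [0, 255] — the plain 8-bit conversion of
#' general-purpose raster tools, not the luma-weighted one, so that a
#' frame with R = G = B everywhere maps exactly onto any single channel.
#' Grayscale frames are returned unchanged.
#'
#' @param frame an \linkS4class{UltrasoundFrame}.
#' @return a grayscale \linkS4class{UltrasoundFrame} (modality
#'   \code{"bmode"}).
#' @export
toGray8 <- function(frame) {
  stopifnot(is(frame, "UltrasoundFrame"))
  px <- frame@pixels
  if (length(dim(px)) == 2L) return(frame)
  g <- .clamp8(.roundHalfUp((px[, , 1L] + px[, , 2L] + px[, , 3L]) / 3))
  dim(g) <- dim(px)[1:2]
  storage.mode(g) <- "integer"
  UltrasoundFrame(g, pixelArea = frame@pixelArea, modality = "bmode")
}
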