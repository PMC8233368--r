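#' Read a region of interest
#'
#' Reads a polygon ROI either from a JSON file
#' (\code{{"vertices": [[x, y], ...], "label": "..."}}) or from an
#' ImageJ \code{.roi} file (binary, polygon or freehand subtype). Vertex
#' order is preserved. ImageJ stores polygon vertices as integer pixel
#' offsets in the same top-left, x = column convention this package
#' uses, so coordinates are taken over as-is.
#'
#' @param path path to a \code{.json} or \code{.roi} file.
#' @return a \linkS4class{RoiPolygon}.
#' @examples
#' p <- tempfile(fileext = ".json")
#' writeRoiJson(RoiPolygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))), p)
#' readRoi(p)
#' @export
readRoi <- function(path) {
  if (!file.exists(path))
    .sqError(paste0("cannot read ROI: file not found: ", path), "sq_io_error")
  magic <- readBin(path, "raw", n = 4L)
  if (identical(rawToChar(magic), "Iout")) return(.readRoiImageJ(path))
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$vertices))
    .sqError("JSON ROI must contain a 'vertices' field", "sq_validation_error")
  v <- as.matrix(obj$vertices)
  if (nrow(v) < 3L)
    .sqError("a polygon ROI needs at least 3 vertices", "sq_validation_error")
  RoiPolygon(v, label = if (is.null(obj$label)) "" else obj$label)
}

## ImageJ .roi type codes
.IJ_POLYGON <- 0L
.IJ_FREEHAND <- 7L

.readRoiImageJ <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 4L)                               # "Iout"
  readBin(con, "integer", 1L, size = 2L, endian = "big")    # version
  type <- readBin(con, "integer", 1L, size = 1L, signed = FALSE)
  readBin(con, "raw", 1L)                                   # unused
  top <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  left <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  readBin(con, "integer", 2L, size = 2L, endian = "big")    # bottom, right
  n <- readBin(con, "integer", 1L, size = 2L, endian = "big")
  if (!type %in% c(.IJ_POLYGON, .IJ_FREEHAND))
    .sqError(sprintf("unsupported ImageJ ROI subtype (type code %d); only polygon and freehand ROIs are supported", type),
             "sq_unsupported_subtype")
  if (n < 3L)
    .sqError("a polygon ROI needs at least 3 vertices", "sq_validation_error")
  readBin(con, "raw", n = 64L - 18L)                        # rest of header
  x <- readBin(con, "integer", n, size = 2L, endian = "big") + left
  y <- readBin(con, "integer", n, size = 2L, endian = "big") + top
  RoiPolygon(cbind(x, y), label = sub("\\.roi$", "", basename(path)))
}

#' Write a polygon ROI as JSON
#'
#' @param roi a \linkS4class{RoiPolygon}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRoiJson <- function(roi, path) {
  stopifnot(is(roi, "RoiPolygon"))
  v <- roi@vertices
  dimnames(v) <- NULL
  jsonlite::write_json(list(vertices = v, label = roi@label), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a polygon ROI in the ImageJ .roi binary format
#'
#' Writes the minimal polygon-subtype \code{.roi} file ImageJ (and
#' \code{\link{readRoi}}) can read back. Vertices are rounded to integer
#' pixel coordinates, as the format stores 16-bit offsets.
#'
#' @param roi a \linkS4class{RoiPolygon}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRoiImageJ <- function(roi, path) {
  stopifnot(is(roi, "RoiPolygon"))
  v <- round(roi@vertices)
  left <- min(v[, 1]); top <- min(v[, 2])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("Iout"), con)
  writeBin(227L, con, size = 2L, endian = "big")            # version
  writeBin(as.raw(c(.IJ_POLYGON, 0L)), con)                 # type, unused
  writeBin(as.integer(c(top, left, max(v[, 2]), max(v[, 1]))), con,
           size = 2L, endian = "big")
  writeBin(as.integer(nrow(v)), con, size = 2L, endian = "big")
  writeBin(raw(64L - 18L), con)                             # zeroed header rest
  writeBin(as.integer(v[, 1] - left), con, size = 2L, endian = "big")
  writeBin(as.integer(v[, 2] - top), con, size = 2L, endian = "big")
  invisible(path)
}

#' Rasterize a polygon ROI to a pixel mask
#'
#' A pixel (x, y) belongs to the mask iff its center (x + 0.5, y + 0.5)
#' lies strictly inside the polygon; centers on the boundary are
#' excluded. This center-inclusion rule is deterministic and matches a
#' brute-force point-in-polygon test over every pixel center.
#'
#' @param roi a \linkS4class{RoiPolygon}.
#' @param dim frame shape \code{c(H, W)}.
#' @return a \linkS4class{BinaryMask}. A polygon lying entirely outside
#'   the frame yields an empty mask with a warning, not an error.
#' @examples
#' sq <- RoiPolygon(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' areaPx(rasterizeRoi(sq, c(20, 20)))  # 100
#' @export
rasterizeRoi <- function(roi, dim) {
  stopifnot(is(roi, "RoiPolygon"))
  dim <- as.integer(dim)
  if (length(dim) < 2L || any(dim[1:2] < 1L))
    .sqError("frame shape must be positive (H, W)", "sq_validation_error")
  h <- dim[1]; w <- dim[2]
  v <- roi@vertices
  ## restrict the center test to the polygon's bounding box
  x0 <- max(0L, floor(min(v[, 1]))); x1 <- min(w - 1L, ceiling(max(v[, 1])))
  y0 <- max(0L, floor(min(v[, 2]))); y1 <- min(h - 1L, ceiling(max(v[, 2])))
  m <- matrix(FALSE, h, w)
  if (x0 <= x1 && y0 <= y1) {
    xs <- seq.int(x0, x1); ys <- seq.int(y0, y1)
    cx <- rep(xs + 0.5, each = length(ys))
    cy <- rep(ys + 0.5, times = length(xs))
    inside <- pracma::inpolygon(cx, cy, v[, 1], v[, 2], boundary = FALSE)
    m[cbind(rep(ys, times = length(xs)) + 1L, rep(xs, each = length(ys)) + 1L)] <- inside
  }
  if (!any(m))
    warning("ROI polygon rasterizes to an empty mask within the frame")
  BinaryMask(m)
}
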