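#' Intensity histogram of a masked region
#'
#' Counts the 8-bit intensities of the pixels selected by \code{mask}.
#' Thresholds in this package are always computed from the histogram of
#' the region of interest, not the whole frame, mirroring the manual-ROI
#' workflow the quantification is built around.
#'
#' @param image grayscale \linkS4class{UltrasoundFrame} or integer
#'   matrix.
#' @param mask \linkS4class{BinaryMask} or logical matrix of the same
#'   shape.
#' @return a \linkS4class{Histogram256}.
#' @export
histogram256 <- function(image, mask) {
  img <- .asGrayMatrix(image)
  m <- .asMaskMatrix(mask)
  if (!identical(dim(img), dim(m)))
    .sqError("mask and image must share one shape", "sq_validation_error")
  if (!any(m))
    .sqError("cannot build a histogram of an empty region", "sq_empty_region")
  Histogram256(tabulate(img[m] + 1L, nbins = 256L))
}

.occupiedBins <- function(counts) sum(counts > 0L)

## Kapur criterion H_b(t) + H_f(t) for every candidate t, vectorized.
## Returns a length-255 vector over t = 0..254; invalid splits (one side
## empty) are -Inf.
.kapurCriterion <- function(counts) {
  total <- sum(counts)
  p <- counts / total
  plogp <- ifelse(p > 0, p * log(p), 0)
  P <- cumsum(p)[1:255]          # P(t), t = 0..254
  S <- cumsum(-plogp)[1:255]     # -sum_{i<=t} p_i log p_i
  Stot <- sum(-plogp)
  Pb <- P; Pf <- 1 - P
  crit <- rep(-Inf, 255)
  ok <- Pb > 0 & Pf > 0
  Hb <- ifelse(ok, S / Pb + log(Pb), -Inf)
  Hf <- ifelse(ok, (Stot - S) / Pf + log(Pf), -Inf)
  crit[ok] <- Hb[ok] + Hf[ok]
  crit
}

#' Maximum-entropy (Kapur) threshold of a 256-bin histogram
#'
#' Selects the threshold t in [0, 254] maximizing the sum of the Shannon
#' entropies of the background class (bins 0..t) and the foreground
#' class (bins t+1..255), each normalized to its own class probability;
#' zero-probability bins contribute nothing. Foreground means intensity
#' strictly greater than t. Ties are broken toward the smallest t so the
#' result is identical across platforms. The entropy is computed with
#' the natural logarithm; the base does not affect the argmax.
#'
#' @param hist a \linkS4class{Histogram256}, or an integer vector of 256
#'   counts.
#' @return integer threshold in [0, 254].
#' @examples
#' maxEntropyThreshold(rep(1L, 256))  # 127
#' @export
maxEntropyThreshold <- function(hist) {
  counts <- if (is(hist, "Histogram256")) hist@counts else as.integer(hist)
  if (length(counts) != 256L)
    .sqError("histogram must have 256 bins", "sq_validation_error")
  if (sum(counts) < 1L)
    .sqError("histogram is empty", "sq_empty_region")
  if (.occupiedBins(counts) < 2L)
    .sqError("degenerate histogram: fewer than 2 occupied bins",
             "sq_degenerate_histogram")
  crit <- .kapurCriterion(counts)
  as.integer(which.max(crit) - 1L)   # which.max returns the first maximum
}

#' Binarize a masked image at a threshold
#'
#' Output pixels are \code{TRUE} exactly where the mask is \code{TRUE}
#' and the intensity is strictly greater than t (foreground = above
#' threshold).
#'
#' @param image grayscale \linkS4class{UltrasoundFrame} or integer
#'   matrix.
#' @param t integer threshold in [0, 254].
#' @param mask \linkS4class{BinaryMask} or logical matrix.
#' @return a \linkS4class{BinaryMask} carrying \code{t}.
#' @export
applyThreshold <- function(image, t, mask) {
  img <- .asGrayMatrix(image)
  m <- .asMaskMatrix(mask)
  if (length(t) != 1L || is.na(t) || t < 0 || t > 254)
    .sqError("threshold must be a single value in [0, 254]", "sq_validation_error")
  if (!identical(dim(img), dim(m)))
    .sqError("mask and image must share one shape", "sq_validation_error")
  BinaryMask(m & img > t, threshold = t)
}
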