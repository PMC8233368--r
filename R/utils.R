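## shared internal helpers

.sqError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "SonoQuantError")))
}

.clamp8 <- function(x) pmin(pmax(x, 0), 255)

## round-half-up on non-negative values (base round() is round-half-even)
.roundHalfUp <- function(x) floor(x + 0.5)

## evaluate expr under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.asMaskMatrix <- function(mask) {
  if (is(mask, "BinaryMask")) mask@pixels else mask
}

.asGrayMatrix <- function(image) {
  if (is(image, "UltrasoundFrame")) {
    if (length(dim(image@pixels)) != 2L)
      .sqError("expected a grayscale image", "sq_modality_error")
    image@pixels
  } else image
}

#' Label connected components of a binary mask
#'
#' 8-connected component labeling by iterative label propagation
#' (each pixel repeatedly takes the minimum label among itself and its
#' 8 neighbours until a fixed point). Returns an integer matrix with 0
#' for background and 1..k for the k components, numbered by their
#' minimal linear index.
#'
#' @param mask logical matrix or \linkS4class{BinaryMask}.
#' @return integer matrix of component labels.
#' @export
labelComponents <- function(mask) {
  m <- .asMaskMatrix(mask)
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  if (!any(m)) return(lab)
  lab[m] <- seq_len(sum(m))
  idx <- matrix(NA_integer_, h, w)
  idx[m] <- lab[m]
  ## pad with NA border so shifts are cheap
  big <- matrix(NA_integer_, h + 2L, w + 2L)
  repeat {
    big[2:(h + 1L), 2:(w + 1L)] <- idx
    nb <- idx
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      sh <- big[(2L + dy):(h + 1L + dy), (2L + dx):(w + 1L + dx)]
      nb <- pmin(nb, sh, na.rm = TRUE)
    }
    nb[!m] <- NA_integer_
    if (identical(nb, idx)) break
    idx <- nb
  }
  labs <- sort(unique(idx[m]))
  lab[m] <- match(idx[m], labs)
  lab
}

#' Significance star coding
#'
#' Maps a p-value to the star coding used throughout the reports:
#' \code{"*"} for p <= 0.05, \code{"**"} for p <= 0.01, \code{"***"} for
#' p <= 0.001, otherwise \code{""} (boundaries inclusive).
#'
#' @param p numeric vector of p-values.
#' @return character vector of stars.
#' @examples
#' pSignifStars(c(0.2, 0.05, 0.01, 0.001))
#' @export
pSignifStars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi <= 0.001) "***" else if (pi <= 0.01) "**" else if (pi <= 0.05) "*" else ""
  }, character(1))
}
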