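#' Validate or coerce a grayscale image matrix
#'
#' The package represents a grayscale image as a plain integer matrix with
#' \code{m} rows and \code{n} columns, gray levels in \code{0..levels-1}
#' (8-bit by default, \code{levels = 256}). Rows index the vertical direction
#' (the direction along which illumination is assumed to vary); columns index
#' the horizontal direction. Pixel indices are 1-based as usual in R; gray
#' levels are 0-based.
#'
#' @param x numeric matrix of gray levels.
#' @param levels number of gray levels L (default 256).
#' @return an integer matrix satisfying the gray-image invariants.
#' @export
as_gray_image <- function(x, levels = 256L) {
  if (!is.matrix(x)) stop("a gray image must be a matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("image must have at least one pixel")
  if (anyNA(x)) stop("image contains missing values")
  v <- as.integer(round_half_up(x))
  if (min(v) < 0L || max(v) > levels - 1L)
    stop("gray levels must lie in [0, ", levels - 1L, "]")
  matrix(v, nrow(x), ncol(x))
}

#' @rdname as_gray_image
#' @export
is_gray_image <- function(x, levels = 256L) {
  is.matrix(x) && is.numeric(x) && nrow(x) >= 1L && ncol(x) >= 1L &&
    !anyNA(x) && all(x == floor(x)) && min(x) >= 0 && max(x) <= levels - 1
}

# round half away from zero (positive inputs: half-up); base round() is
# round-half-even, which would make the filter outputs depend on parity
round_half_up <- function(x) floor(x + 0.5)

#' Threshold a gray image into a binary mask
#'
#' Pixels at or above \code{cutoff} become foreground (1), the rest
#' background (0). Used mainly to ingest ground-truth masks stored as
#' 0/255 images.
#'
#' @param img gray image matrix (see [as_gray_image()]).
#' @param cutoff gray level; default 128.
#' @return integer 0/1 matrix of the same shape.
#' @export
mask_from_gray <- function(img, cutoff = 128L) {
  stopifnot(is.matrix(img))
  m <- matrix(as.integer(img >= cutoff), nrow(img), ncol(img))
  m
}

# validate a binary mask
check_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask) || !all(mask %in% c(0L, 1L)))
    stop(what, " must be a 0/1 matrix")
  invisible(mask)
}
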