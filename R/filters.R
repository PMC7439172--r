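#' Neighbourhood filters used to build the 2D histogram
#'
#' \code{average_filter()} replaces each pixel by the arithmetic mean of its
#' \code{k x k} neighbourhood, rounded half-up to an integer gray level;
#' \code{median_filter()} replaces it by the neighbourhood median. Borders
#' are replicate-padded so the output has the shape of the input and stays
#' inside the gray-level range. \code{k} must be odd so the window has a
#' centre and the median of its k^2 values is an observed level.
#'
#' The 2D Otsu histogram pairs each pixel with a smoothed version of itself;
#' the average filter supplies the classical smoothed coordinate, and the
#' median filter, applied first, is what removes salt-and-pepper impulses
#' before they contaminate either coordinate.
#'
#' @param img gray image matrix (see [as_gray_image()]).
#' @param k odd window size in pixels, default 3.
#' @return gray image matrix of the same shape.
#' @export
average_filter <- function(img, k = 3L) {
  check_window(k)
  p <- pad_replicate(img, (k - 1L) %/% 2L)
  acc <- neighbourhood_reduce(p, k, nrow(img), ncol(img), sum = TRUE)
  as_gray_image(round_half_up(acc / (k * k)), levels = 256L)
}

#' @rdname average_filter
#' @export
median_filter <- function(img, k = 3L) {
  check_window(k)
  p <- pad_replicate(img, (k - 1L) %/% 2L)
  nb <- neighbourhood_reduce(p, k, nrow(img), ncol(img), sum = FALSE)
  mid <- (k * k + 1L) %/% 2L
  med <- apply(nb, 1L, function(r) sort.int(r, partial = mid)[mid])
  matrix(as.integer(med), nrow(img), ncol(img))
}

check_window <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1L || k %% 2L == 0L)
    stop("window size k must be a positive odd integer, got ", k)
  invisible(k)
}

pad_replicate <- function(img, r) {
  if (r == 0L) return(img)
  ri <- c(rep(1L, r), seq_len(nrow(img)), rep(nrow(img), r))
  ci <- c(rep(1L, r), seq_len(ncol(img)), rep(ncol(img), r))
  img[ri, ci, drop = FALSE]
}

# collect the k^2 shifted copies of the padded image; either sum them
# (average filter) or stack them as an (m*n) x k^2 matrix (median filter)
neighbourhood_reduce <- function(padded, k, m, n, sum = TRUE) {
  if (sum) {
    acc <- matrix(0, m, n)
  } else {
    acc <- matrix(0L, m * n, k * k)
    col <- 0L
  }
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      shifted <- padded[dr:(dr + m - 1L), dc:(dc + n - 1L), drop = FALSE]
      if (sum) {
        acc <- acc + shifted
      } else {
        col <- col + 1L
        acc[, col] <- as.vector(shifted)
      }
    }
  }
  acc
}

#' Coordinate image pair for a 2D-histogram strategy
#'
#' The 2D histogram bins pixels by a pair (i, j) of gray levels. The three
#' strategies are:
#' \describe{
#'   \item{\code{"avg_only"}}{(original 2D Otsu) i = raw pixel, j = average
#'     of the raw image.}
#'   \item{\code{"orig_medavg"}}{i = raw pixel, j = average of the median
#'     image ("median-average" image).}
#'   \item{\code{"med_medavg"}}{(default; the robust variant) i = median
#'     image, j = median-average image.}
#' }
#' Filters are always computed on the whole image; region restriction for
#' part-wise histograms happens afterwards, so no artificial edge is created
#' along a splitting line.
#'
#' @param img gray image matrix.
#' @param strategy histogram strategy, see Details.
#' @param k odd filter window size, default 3.
#' @return list with elements \code{first} and \code{smooth}, the two
#'   coordinate images, plus the strategy and k.
#' @export
coordinate_images <- function(img,
                              strategy = c("med_medavg", "orig_medavg",
                                           "avg_only"),
                              k = 3L) {
  strategy <- match.arg(strategy)
  out <- switch(strategy,
    avg_only = list(first = img, smooth = average_filter(img, k)),
    orig_medavg = list(first = img,
                       smooth = average_filter(median_filter(img, k), k)),
    med_medavg = {
      med <- median_filter(img, k)
      list(first = med, smooth = average_filter(med, k))
    })
  out$strategy <- strategy
  out$k <- as.integer(k)
  out
}

#' Build the 2D gray-level histogram
#'
#' Counts pixels by the gray-level pair (i, j) given by the chosen strategy
#' (see [coordinate_images()]) and normalises to a joint probability table
#' p with sum 1, together with the grand mean vector (u_Ti, u_Tj). An
#' optional logical region restricts the count to a subset of pixels (the
#' filters still see the whole image).
#'
#' @param img gray image matrix.
#' @inheritParams coordinate_images
#' @param region optional logical matrix (same shape) selecting the pixels
#'   to tabulate; default all pixels.
#' @param levels number of gray levels L.
#' @param pair optionally, a precomputed [coordinate_images()] result to
#'   reuse across several regions of the same image.
#' @return an object of class \code{"histogram2d"}: list with \code{counts}
#'   (L x L integer), \code{p} (L x L, sums to 1), \code{total},
#'   \code{mean} (named vector \code{c(i, j)}), \code{levels},
#'   \code{strategy}, \code{k}.
#' @export
build_histogram2d <- function(img,
                              strategy = c("med_medavg", "orig_medavg",
                                           "avg_only"),
                              k = 3L, region = NULL, levels = 256L,
                              pair = NULL) {
  if (is.null(pair)) pair <- coordinate_images(img, strategy, k)
  histogram2d_from_pair(pair, region = region, levels = levels)
}

histogram2d_from_pair <- function(pair, region = NULL, levels = 256L) {
  i <- pair$first
  j <- pair$smooth
  if (!is.null(region)) {
    region <- region != 0
    if (!any(region)) stop("empty pixel region")
    i <- i[region]
    j <- j[region]
  }
  total <- length(i)
  idx <- as.vector(i) * levels + as.vector(j) + 1L
  counts <- matrix(tabulate(idx, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  p <- counts / total
  lv <- 0:(levels - 1L)
  structure(list(
    counts = counts, p = p, total = total,
    mean = c(i = sum(lv * rowSums(p)), j = sum(lv * colSums(p))),
    levels = as.integer(levels),
    strategy = pair$strategy, k = pair$k
  ), class = "histogram2d")
}

#' @export
print.histogram2d <- function(x, ...) {
  cat("2D gray-level histogram (", x$levels, "x", x$levels, " levels)\n",
      sep = "")
  cat("  strategy: ", x$strategy %||% "?", ", k = ", x$k %||% "?",
      ", pixels: ", x$total, "\n", sep = "")
  cat(sprintf("  mean vector: (%.3f, %.3f)\n", x$mean["i"], x$mean["j"]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Off-diagonal spread of a 2D histogram
#'
#' Mean squared distance of the histogram mass from the diagonal i = j:
#' \code{sum(p_ij * (i - j)^2)}. A compact histogram (mass hugging the
#' diagonal) indicates little disagreement between the raw and smoothed
#' coordinates, i.e. little noise; median-based strategies yield smaller
#' values on impulse-corrupted images.
#'
#' @param h a \code{"histogram2d"} object.
#' @return nonnegative number; 0 iff all mass lies on the diagonal.
#' @export
histogram_compactness <- function(h) {
  stopifnot(inherits(h, "histogram2d"))
  lv <- 0:(h$levels - 1L)
  d2 <- outer(lv, lv, function(i, j) (i - j)^2)
  sum(h$p * d2)
}

#' Export a 2D histogram as a data frame
#'
#' One row per nonzero cell: i, j, count, p. Convenient for TSV dumps.
#'
#' @param h a \code{"histogram2d"} object.
#' @return data frame with columns i, j, count, p.
#' @export
histogram2d_table <- function(h) {
  stopifnot(inherits(h, "histogram2d"))
  nz <- which(h$counts > 0L, arr.ind = TRUE)
  data.frame(i = nz[, 1] - 1L, j = nz[, 2] - 1L,
             count = h$counts[nz], p = h$p[nz])[order(nz[, 1], nz[, 2]), ]
}
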