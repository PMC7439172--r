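#' Partition-based thresholding schemes
#'
#' Given a splitting line dividing the image into two parts with roughly
#' uniform illumination, two schemes turn per-part 2D histograms into a
#' final mask:
#' \describe{
#'   \item{scheme 1 (\code{scheme1()})}{thresholds the two parts
#'     independently: each part gets its own 2D histogram and optimal
#'     threshold pair, the two part masks are stitched along the line.}
#'   \item{scheme 2 (\code{scheme2()})}{finds one global pair (s, t)
#'     maximising the \emph{product} of the two parts' between-class
#'     variance traces, then binarizes the whole image with it.}
#' }
#' Filters are computed once on the whole image; the parts only restrict
#' which pixels are tabulated, so no artificial gradient appears at the cut.
#'
#' A part whose criterion is identically zero (e.g. constant) is labelled
#' all-background with a warning under scheme 1; under scheme 2 the other
#' part's trace is maximised alone (and if both parts are degenerate the
#' whole-image histogram decides).
#'
#' @param img gray image matrix (see [as_gray_image()]).
#' @param regions list of two logical membership matrices as returned by
#'   [partition()].
#' @param strategy,k histogram strategy and filter window, see
#'   [coordinate_images()].
#' @param offdiag assignment rule for histogram quadrants II/III, see
#'   [binarize()].
#' @param pair optional precomputed [coordinate_images()] result.
#' @param levels number of gray levels.
#' @return an object of class \code{"scheme_result"}: list with
#'   \code{mask} (0/1 matrix), \code{thresholds} (list of one or two
#'   \code{"threshold_pair"}s), \code{scheme} ("s1" or "s2"), and
#'   \code{degenerate} flags per part.
#' @export
scheme1 <- function(img, regions, strategy = "med_medavg", k = 3L,
                    offdiag = "smoothed", pair = NULL, levels = 256L) {
  if (is.null(pair)) pair <- coordinate_images(img, strategy, k)
  mask <- matrix(0L, nrow(img), ncol(img))
  tps <- vector("list", 2L)
  degen <- logical(2L)
  for (q in 1:2) {
    region <- regions[[q]]
    if (!any(region)) {
      warning("part ", q, " of the partition is empty; left as background")
      degen[q] <- TRUE
      tps[[q]] <- structure(list(s = NA_integer_, t = NA_integer_,
                                 criterion = 0, degenerate = TRUE),
                            class = "threshold_pair")
      next
    }
    h <- histogram2d_from_pair(pair, region = region, levels = levels)
    tp <- withCallingHandlers(
      find_threshold(h),
      warning = function(w) {
        warning("part ", q, ": ", conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
    tps[[q]] <- tp
    if (tp$degenerate) {
      degen[q] <- TRUE  # constant part: background, per the degenerate rule
      next
    }
    part_mask <- binarize(pair, tp, offdiag = offdiag,
                          stats = class_stats(h, tp$s, tp$t))
    mask[region] <- part_mask[region]
  }
  structure(list(mask = mask, thresholds = tps, scheme = "s1",
                 degenerate = degen),
            class = "scheme_result")
}

#' @rdname scheme1
#' @export
scheme2 <- function(img, regions, strategy = "med_medavg", k = 3L,
                    offdiag = "smoothed", pair = NULL, levels = 256L) {
  if (is.null(pair)) pair <- coordinate_images(img, strategy, k)
  nonempty <- vapply(regions, any, logical(1L))
  hs <- lapply(which(nonempty), function(q)
    histogram2d_from_pair(pair, region = regions[[q]], levels = levels))
  crits <- lapply(hs, criterion_matrix)
  alive <- vapply(crits, function(cm) max(cm) > 0, logical(1L))
  degen <- !alive
  if (sum(alive) == 2L) {
    objective <- crits[[1L]] * crits[[2L]]
  } else if (sum(alive) == 1L) {
    warning("one part is degenerate; maximising the other part's criterion")
    objective <- crits[[which(alive)]]
  } else {
    warning("both parts are degenerate; falling back to the whole image")
    objective <- criterion_matrix(
      histogram2d_from_pair(pair, levels = levels))
  }
  best <- max(objective)
  if (best <= 0) {
    tp <- suppressWarnings(
      find_threshold(histogram2d_from_pair(pair, levels = levels)))
    warning("whole image is degenerate; criterion is identically 0")
  } else {
    hits <- which(objective == best, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    tp <- structure(list(s = as.integer(hits[1L, 1L] - 1L),
                         t = as.integer(hits[1L, 2L] - 1L),
                         criterion = best, degenerate = FALSE),
                    class = "threshold_pair")
  }
  hwhole <- histogram2d_from_pair(pair, levels = levels)
  mask <- binarize(pair, tp, offdiag = offdiag,
                   stats = class_stats(hwhole, tp$s, tp$t))
  structure(list(mask = mask, thresholds = list(tp), scheme = "s2",
                 degenerate = degen),
            class = "scheme_result")
}

#' @export
print.scheme_result <- function(x, ...) {
  cat("partition thresholding, scheme", if (x$scheme == "s1") "1" else "2",
      "\n")
  for (tp in x$thresholds)
    cat(sprintf("  (s, t) = (%s, %s), criterion %.4f\n",
                format(tp$s), format(tp$t), tp$criterion))
  cat(sprintf("  foreground fraction: %.3f\n", mean(x$mask)))
  invisible(x)
}
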