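#' Fit a robust 2D Otsu segmentation model to a grayscale image
#'
#' The main entry point of the package. Builds the noise-robust 2D
#' gray-level histogram of the image (median / median-average coordinates
#' by default), optionally cuts the image into two evenly lit parts along a
#' maximum-energy splitting line, and estimates the threshold pair(s)
#' maximising the between-class variance trace. Three estimators are
#' available and can be fitted together:
#' \describe{
#'   \item{\code{"global"}}{whole-image 2D Otsu on the chosen histogram
#'     strategy (with \code{strategy = "avg_only"} this is the classical
#'     2D Otsu method).}
#'   \item{\code{"split1"}}{scheme 1: the two parts are thresholded
#'     independently, see [scheme1()].}
#'   \item{\code{"split2"}}{scheme 2: one pair maximising the product of
#'     the per-part criteria, see [scheme2()].}
#' }
#' \code{scheme = "both"} (default) fits split1 and split2 and, when a
#' ground-truth mask is supplied, selects the one with lower
#' misclassification error (ties go to scheme 1). Without ground truth both
#' masks are kept and no selection is made — no unsupervised selection rule
#' is defined for this estimator.
#'
#' If the splitting line leaves one part empty the fit falls back to
#' whole-image thresholding with a warning.
#'
#' @param img gray image matrix, or a file path readable by [read_gray()].
#' @param scheme which estimator(s) to fit: \code{"both"}, \code{"split1"},
#'   \code{"split2"} or \code{"global"}.
#' @param strategy 2D-histogram strategy, see [coordinate_images()];
#'   default \code{"med_medavg"}.
#' @param k odd filter window size (pixels), default 3.
#' @param w_color,w_geom splitting-line energy weights, defaults 2 and 1,
#'   see [energy_map()].
#' @param sigma position-weight width mode, see [position_weight()].
#' @param energy_source image the energy is computed on, \code{"raw"}
#'   (default) or \code{"median"}.
#' @param offdiag histogram quadrant II/III assignment rule, see
#'   [binarize()].
#' @param truth optional ground-truth 0/1 mask for evaluation/selection.
#' @param levels number of gray levels, default 256.
#' @param keep_image keep a copy of the input image in the fit (needed by
#'   \code{plot}), default TRUE.
#' @return an object of class \code{"otsu2d"}; see
#'   [print.otsu2d()], [summary.otsu2d()], [coef.otsu2d()],
#'   [fitted.otsu2d()], [predict.otsu2d()], [plot.otsu2d()].
#' @examples
#' scene <- synth_preset("coins", seed = 1)
#' fit <- otsu2d(scene$image, truth = scene$mask)
#' fit
#' coef(fit)
#' @export
otsu2d <- function(img,
                   scheme = c("both", "split1", "split2", "global"),
                   strategy = c("med_medavg", "orig_medavg", "avg_only"),
                   k = 3L, w_color = 2, w_geom = 1,
                   sigma = c("half_m", "literal_2m"),
                   energy_source = c("raw", "median"),
                   offdiag = c("smoothed", "raw", "nearest"),
                   truth = NULL, levels = 256L, keep_image = TRUE) {
  cl <- match.call()
  scheme <- match.arg(scheme)
  strategy <- match.arg(strategy)
  sigma <- match.arg(sigma)
  energy_source <- match.arg(energy_source)
  offdiag <- match.arg(offdiag)
  if (is.character(img)) img <- read_gray(img, levels = levels)
  img <- as_gray_image(img, levels = levels)
  if (!is.null(truth)) {
    check_mask(truth, "truth")
    if (!all(dim(truth) == dim(img)))
      stop("truth mask shape does not match the image")
  }
  pair <- coordinate_images(img, strategy, k)

  split <- NULL
  regions <- NULL
  if (scheme != "global" && nrow(img) >= 2L) {
    split <- find_splitline(energy_map(img, w_color, w_geom, sigma,
                                       energy_source, k))
    regions <- partition(dim(img), split)
    if (!any(regions$part1) || !any(regions$part2)) {
      warning("splitting line leaves one part empty; ",
              "falling back to whole-image thresholding")
      scheme <- "global"
      split <- NULL
      regions <- NULL
    }
  } else if (scheme != "global") {
    scheme <- "global"  # single-row image cannot be split
  }

  fits <- list()
  if (scheme == "global") {
    h <- histogram2d_from_pair(pair, levels = levels)
    tp <- find_threshold(h)
    mask <- binarize(pair, tp, offdiag = offdiag,
                     stats = class_stats(h, tp$s, tp$t))
    fits$global <- structure(
      list(mask = mask, thresholds = list(tp), scheme = "global",
           degenerate = tp$degenerate),
      class = "scheme_result")
  }
  if (scheme %in% c("both", "split1"))
    fits$split1 <- scheme1(img, regions, strategy, k, offdiag, pair, levels)
  if (scheme %in% c("both", "split2"))
    fits$split2 <- scheme2(img, regions, strategy, k, offdiag, pair, levels)

  metrics <- NULL
  selected <- if (length(fits) == 1L) names(fits) else NA_character_
  if (!is.null(truth)) {
    metrics <- lapply(fits, function(f) evaluate_mask(f$mask, truth))
    if (length(fits) > 1L) {
      me <- vapply(metrics, function(ev) ev$me, numeric(1L))
      selected <- names(fits)[which.min(me)]  # first minimum: split1 on ties
    }
  }

  structure(list(
    call = cl, dim = dim(img), levels = as.integer(levels),
    scheme = scheme, strategy = strategy, k = as.integer(k),
    w_color = w_color, w_geom = w_geom, sigma = sigma,
    energy_source = energy_source, offdiag = offdiag,
    split = split, fits = fits, metrics = metrics, selected = selected,
    image = if (keep_image) img else NULL,
    truth = truth
  ), class = "otsu2d")
}

# the scheme whose mask represents the fit: the selected one, else split1,
# else whatever single fit exists
selected_fit <- function(object) {
  nm <- object$selected
  if (is.na(nm)) nm <- intersect(c("split1", "global"), names(object$fits))[1L]
  object$fits[[nm]]
}

#' @export
print.otsu2d <- function(x, ...) {
  cat("Robust 2D Otsu segmentation fit\n")
  cat("  image: ", x$dim[1L], "x", x$dim[2L], ", L = ", x$levels,
      ", histogram strategy: ", x$strategy, " (k = ", x$k, ")\n", sep = "")
  if (!is.null(x$split))
    cat(sprintf("  splitting line: rows %d..%d, mean energy %.2f\n",
                min(x$split$rows), max(x$split$rows), x$split$mean_energy))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    th <- vapply(f$thresholds,
                 function(tp) sprintf("(%s,%s)", format(tp$s), format(tp$t)),
                 character(1L))
    cat("  ", nm, ": threshold", if (length(th) > 1L) "s" else "", " ",
        paste(th, collapse = " "), sep = "")
    if (!is.null(x$metrics))
      cat(sprintf("  [ME %.4f, DSC %.4f]",
                  x$metrics[[nm]]$me, x$metrics[[nm]]$dsc))
    cat("\n")
  }
  if (!is.na(x$selected) && length(x$fits) > 1L)
    cat("  selected: ", x$selected, "\n", sep = "")
  invisible(x)
}

#' Summarise a robust 2D Otsu fit
#'
#' @param object an \code{"otsu2d"} fit.
#' @param ... unused.
#' @return a \code{"summary.otsu2d"} object: per-scheme table of
#'   thresholds, criterion values, foreground fractions and (if ground
#'   truth was supplied) ME/DSC.
#' @export
summary.otsu2d <- function(object, ...) {
  rows <- lapply(names(object$fits), function(nm) {
    f <- object$fits[[nm]]
    data.frame(
      scheme = nm,
      part = seq_along(f$thresholds),
      s = vapply(f$thresholds, function(tp) as.integer(tp$s), integer(1L)),
      t = vapply(f$thresholds, function(tp) as.integer(tp$t), integer(1L)),
      criterion = vapply(f$thresholds, function(tp) tp$criterion,
                         numeric(1L)),
      fg_fraction = mean(f$mask),
      me = if (is.null(object$metrics)) NA_real_ else object$metrics[[nm]]$me,
      dsc = if (is.null(object$metrics)) NA_real_
            else object$metrics[[nm]]$dsc)
  })
  structure(list(call = object$call, dim = object$dim,
                 strategy = object$strategy, selected = object$selected,
                 table = do.call(rbind, rows)),
            class = "summary.otsu2d")
}

#' @export
print.summary.otsu2d <- function(x, ...) {
  cat("Robust 2D Otsu segmentation (", x$dim[1L], "x", x$dim[2L],
      ", strategy ", x$strategy, ")\n\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  if (!is.na(x$selected)) cat("\nselected scheme:", x$selected, "\n")
  invisible(x)
}

#' Threshold estimates of a fit
#'
#' @param object an \code{"otsu2d"} fit.
#' @param ... unused.
#' @return matrix with one row per estimated threshold pair and columns
#'   \code{s}, \code{t}, \code{criterion}; row names identify the scheme
#'   (and part for scheme 1).
#' @export
coef.otsu2d <- function(object, ...) {
  rows <- list()
  for (nm in names(object$fits)) {
    tps <- object$fits[[nm]]$thresholds
    for (q in seq_along(tps)) {
      label <- if (length(tps) > 1L) paste0(nm, ".part", q) else nm
      rows[[label]] <- c(s = as.numeric(tps[[q]]$s),
                         t = as.numeric(tps[[q]]$t),
                         criterion = tps[[q]]$criterion)
    }
  }
  do.call(rbind, rows)
}

#' Fitted segmentation mask
#'
#' @param object an \code{"otsu2d"} fit.
#' @param scheme which scheme's mask to return; default the selected one
#'   (scheme 1 when no selection was made).
#' @param ... unused.
#' @return integer 0/1 mask matrix.
#' @export
fitted.otsu2d <- function(object, scheme = NULL, ...) {
  if (is.null(scheme)) return(selected_fit(object)$mask)
  if (!scheme %in% names(object$fits))
    stop("no fitted scheme '", scheme, "'")
  object$fits[[scheme]]$mask
}

#' Apply a fitted threshold model to a new image
#'
#' Recomputes the coordinate images (and, for the partition schemes, a new
#' splitting line) on the new image and applies the stored threshold
#' pair(s). This transfers the estimated gray-level thresholds, not the
#' original image's partition.
#'
#' @param object an \code{"otsu2d"} fit.
#' @param newdata gray image matrix or file path.
#' @param scheme which fitted scheme to apply; default the selected one.
#' @param ... unused.
#' @return integer 0/1 mask matrix for the new image.
#' @export
predict.otsu2d <- function(object, newdata, scheme = NULL, ...) {
  if (missing(newdata)) return(fitted(object, scheme = scheme))
  if (is.character(newdata)) newdata <- read_gray(newdata, object$levels)
  newdata <- as_gray_image(newdata, object$levels)
  if (is.null(scheme)) {
    scheme <- object$selected
    if (is.na(scheme))
      scheme <- intersect(c("split1", "global"), names(object$fits))[1L]
  }
  f <- object$fits[[scheme]]
  if (is.null(f)) stop("no fitted scheme '", scheme, "'")
  pair <- coordinate_images(newdata, object$strategy, object$k)
  if (scheme %in% c("global", "split2") || nrow(newdata) < 2L) {
    tp <- f$thresholds[[1L]]
    return(binarize(pair, tp, offdiag = min_offdiag(object)))
  }
  split <- find_splitline(energy_map(newdata, object$w_color, object$w_geom,
                                     object$sigma, object$energy_source,
                                     object$k))
  regions <- partition(dim(newdata), split)
  mask <- matrix(0L, nrow(newdata), ncol(newdata))
  for (q in 1:2) {
    tp <- f$thresholds[[q]]
    if (is.na(tp$s)) next
    pm <- binarize(pair, tp, offdiag = min_offdiag(object))
    mask[regions[[q]]] <- pm[regions[[q]]]
  }
  mask
}

# "nearest" needs class stats from the training histogram, which are not
# meaningful for new data; fall back to the smoothed rule there
min_offdiag <- function(object) {
  if (object$offdiag == "nearest") "smoothed" else object$offdiag
}

#' Misclassification map of a fit
#'
#' Only available when the fit was given a ground-truth mask: returns the
#' pixelwise difference \code{fitted - truth}, i.e. +1 for false positives,
#' -1 for false negatives and 0 for agreement.
#'
#' @param object an \code{"otsu2d"} fit with \code{truth}.
#' @param scheme which scheme's mask to compare; default the selected one.
#' @param ... unused.
#' @return integer matrix with values in \{-1, 0, 1\}.
#' @export
residuals.otsu2d <- function(object, scheme = NULL, ...) {
  if (is.null(object$truth))
    stop("residuals are only defined when the fit was given a truth mask")
  fitted(object, scheme = scheme) - object$truth
}

#' Plot a robust 2D Otsu fit
#'
#' Shows the input image with the splitting line overlaid (when one was
#' fitted) next to the fitted mask(s).
#'
#' @param x an \code{"otsu2d"} fit created with \code{keep_image = TRUE}.
#' @param ... passed to [graphics::image()].
#' @export
plot.otsu2d <- function(x, ...) {
  if (is.null(x$image))
    stop("refit with keep_image = TRUE to plot")
  panels <- 1L + length(x$fits)
  op <- graphics::par(mfrow = c(1L, panels), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  show_img(x$image, max = x$levels - 1L, main = "image", ...)
  if (!is.null(x$split))
    graphics::lines(seq_len(x$dim[2L]), x$dim[1L] + 1L - x$split$rows,
                    col = "red", lwd = 2)
  for (nm in names(x$fits))
    show_img(x$fits[[nm]]$mask, max = 1,
             main = paste0("mask: ", nm,
                           if (identical(nm, x$selected)) " (selected)"
                           else ""), ...)
  invisible(x)
}

# display a matrix in image orientation (row 1 on top)
show_img <- function(mat, max = 255, main = "", ...) {
  m <- nrow(mat)
  graphics::image(t(mat[m:1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, 0, 1),
                  zlim = c(0, max), axes = FALSE, main = main,
                  useRaster = TRUE, ...)
}
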