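#' Evaluate a predicted mask against ground truth
#'
#' Pixelwise confusion counts plus the two standard segmentation scores:
#' misclassification error \code{ME = 1 - (TP + TN) / N} (the fraction of
#' pixels assigned to the wrong class) and the Dice similarity coefficient
#' \code{DSC = 2 TP / (2 TP + FP + FN)} (foreground overlap). When both
#' masks have empty foreground the DSC is defined as 1.
#'
#' @param pred predicted 0/1 mask matrix.
#' @param truth ground-truth 0/1 mask matrix of the same shape.
#' @return an object of class \code{"mask_eval"}: list with \code{me},
#'   \code{dsc}, and integer counts \code{tp}, \code{fp}, \code{fn},
#'   \code{tn}.
#' @examples
#' truth <- matrix(c(1, 1, 0, 0), 2, 2)
#' pred <- matrix(c(1, 0, 0, 1), 2, 2)
#' evaluate_mask(pred, truth)
#' @export
evaluate_mask <- function(pred, truth) {
  check_mask(pred, "pred")
  check_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth)))
    stop("pred and truth masks differ in shape")
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  tn <- sum(pred == 0L & truth == 0L)
  n <- tp + fp + fn + tn
  dsc <- if (2 * tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(me = 1 - (tp + tn) / n, dsc = dsc,
                 tp = tp, fp = fp, fn = fn, tn = tn),
            class = "mask_eval")
}

#' @export
print.mask_eval <- function(x, ...) {
  cat(sprintf("ME %.4f  DSC %.4f  (TP %d  FP %d  FN %d  TN %d)\n",
              x$me, x$dsc, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}
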