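#' Class statistics of a threshold pair
#'
#' A pair (s, t) cuts the 2D histogram into four quadrants. Quadrant I
#' (i <= s, j <= t) is the background class C0 and quadrant IV
#' (i > s, j > t) the foreground class C1; the off-diagonal quadrants hold
#' edge and noise pixels and are ignored by the criterion. Returns the class
#' occurrence probabilities w0, w1 and class mean vectors u0, u1. A class
#' with zero mass is flagged degenerate and reports mean (0, 0).
#'
#' @param h a \code{"histogram2d"} object.
#' @param s,t gray-level thresholds in \code{0..levels-2}.
#' @return list with \code{w0}, \code{w1}, \code{u0}, \code{u1},
#'   \code{degenerate} (logical: either class empty).
#' @export
class_stats <- function(h, s, t) {
  stopifnot(inherits(h, "histogram2d"))
  L <- h$levels
  check_threshold(s, L); check_threshold(t, L)
  lv <- 0:(L - 1L)
  i0 <- seq_len(s + 1L); j0 <- seq_len(t + 1L)
  i1 <- (s + 2L):L;      j1 <- (t + 2L):L
  n0 <- sum(h$counts[i0, j0])
  n1 <- sum(h$counts[i1, j1])
  w0 <- n0 / h$total
  w1 <- n1 / h$total
  u0 <- if (n0 > 0L) {
    p0 <- h$p[i0, j0, drop = FALSE]
    c(i = sum(lv[i0] * rowSums(p0)), j = sum(lv[j0] * colSums(p0))) / w0
  } else c(i = 0, j = 0)
  u1 <- if (n1 > 0L) {
    p1 <- h$p[i1, j1, drop = FALSE]
    c(i = sum(lv[i1] * rowSums(p1)), j = sum(lv[j1] * colSums(p1))) / w1
  } else c(i = 0, j = 0)
  list(w0 = w0, w1 = w1, u0 = u0, u1 = u1, degenerate = n0 == 0L || n1 == 0L)
}

check_threshold <- function(s, L) {
  if (length(s) != 1L || is.na(s) || s < 0L || s > L - 2L)
    stop("threshold must lie in [0, ", L - 2L, "], got ", s)
  invisible(s)
}

#' Between-class variance trace of a threshold pair
#'
#' The 2D Otsu criterion: \code{w0 * ||u0 - uT||^2 + w1 * ||u1 - uT||^2},
#' the trace of the between-class scatter matrix, where uT is the grand
#' mean vector of the histogram. Defined as 0 when either class is empty.
#'
#' @inheritParams class_stats
#' @return nonnegative number.
#' @export
trace_criterion <- function(h, s, t) {
  cs <- class_stats(h, s, t)
  if (cs$degenerate) return(0)
  uT <- h$mean
  cs$w0 * sum((cs$u0 - uT)^2) + cs$w1 * sum((cs$u1 - uT)^2)
}

# Criterion evaluated at every (s, t) in [0, L-2]^2 at once via 2D
# cumulative sums of the count, i*count and j*count tables; O(L^2) total.
# Row r / column c of the result correspond to s = r-1, t = c-1.
criterion_matrix <- function(h) {
  L <- h$levels
  lv <- 0:(L - 1L)
  cum2 <- function(x) t(apply(apply(x, 2L, cumsum), 1L, cumsum))
  CN <- cum2(h$counts)
  CI <- cum2(lv * h$counts)          # recycles lv down the rows (i * f_ij)
  CJ <- cum2(t(lv * t(h$counts)))    # j * f_ij
  K <- L - 1L
  sub <- function(M) M[1:K, 1:K, drop = FALSE]
  corner <- function(M) {            # class-1 rectangle sums by inclusion-exclusion
    M[L, L] - matrix(M[1:K, L], K, K) - matrix(M[L, 1:K], K, K, byrow = TRUE) +
      sub(M)
  }
  n0 <- sub(CN); n1 <- corner(CN)
  w0 <- n0 / h$total; w1 <- n1 / h$total
  ok <- n0 > 0L & n1 > 0L
  u0i <- ifelse(ok, sub(CI) / n0, 0)
  u0j <- ifelse(ok, sub(CJ) / n0, 0)
  u1i <- ifelse(ok, corner(CI) / n1, 0)
  u1j <- ifelse(ok, corner(CJ) / n1, 0)
  uT <- h$mean
  crit <- w0 * ((u0i - uT["i"])^2 + (u0j - uT["j"])^2) +
          w1 * ((u1i - uT["i"])^2 + (u1j - uT["j"])^2)
  crit[!ok] <- 0
  crit
}

#' Optimal 2D Otsu threshold pair
#'
#' Exhaustively maximises the between-class variance trace over all pairs
#' (s, t) in \code{[0, L-2]^2}, evaluated in O(L^2) via cumulative-sum
#' tables. Ties are broken to the lexicographically smallest (s, t). For a
#' histogram whose criterion is identically zero (e.g. a constant image)
#' the pair (v, v) at the constant's level is returned with a warning.
#'
#' @param h a \code{"histogram2d"} object.
#' @return an object of class \code{"threshold_pair"}: list with integer
#'   \code{s}, \code{t}, the achieved \code{criterion}, and a
#'   \code{degenerate} flag.
#' @export
find_threshold <- function(h) {
  stopifnot(inherits(h, "histogram2d"))
  L <- h$levels
  crit <- criterion_matrix(h)
  best <- max(crit)
  if (best <= 0) {
    warning("degenerate histogram: between-class criterion is identically 0")
    v <- min(which(rowSums(h$counts) > 0L)) - 1L
    v <- min(v, L - 2L)
    return(structure(list(s = v, t = v, criterion = 0, degenerate = TRUE),
                     class = "threshold_pair"))
  }
  hits <- which(crit == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  structure(list(s = as.integer(hits[1L, 1L] - 1L),
                 t = as.integer(hits[1L, 2L] - 1L),
                 criterion = best, degenerate = FALSE),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf("2D Otsu threshold pair: (s, t) = (%d, %d), criterion = %.4f%s\n",
              x$s, x$t, x$criterion,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' Binarize a coordinate-image pair at a threshold pair
#'
#' Quadrant IV pixels (i > s and j > t) are foreground and quadrant I
#' pixels (i <= s and j <= t) background. The off-diagonal quadrants II/III
#' (edges and noise) need a rule of their own:
#' \describe{
#'   \item{\code{"smoothed"}}{(default) the smoothed coordinate decides,
#'     foreground iff j > t — the noise-robust choice;}
#'   \item{\code{"raw"}}{the raw coordinate decides, foreground iff i > s;}
#'   \item{\code{"nearest"}}{assign to the class whose mean vector is
#'     nearer in the (i, j) plane (requires \code{stats}).}
#' }
#'
#' @param pair a [coordinate_images()] result (or a list with \code{first}
#'   and \code{smooth} gray images of the same shape).
#' @param tp a \code{"threshold_pair"} (or list with \code{s} and \code{t}).
#' @param offdiag rule for quadrant II/III pixels, see Details.
#' @param stats optional [class_stats()] result, needed for
#'   \code{offdiag = "nearest"}.
#' @return integer 0/1 mask matrix of the image shape.
#' @export
binarize <- function(pair, tp, offdiag = c("smoothed", "raw", "nearest"),
                     stats = NULL) {
  offdiag <- match.arg(offdiag)
  i <- pair$first; j <- pair$smooth
  stopifnot(is.matrix(i), is.matrix(j), all(dim(i) == dim(j)))
  s <- tp$s; t <- tp$t
  fg <- i > s & j > t
  bg <- i <= s & j <= t
  mixed <- !fg & !bg
  if (any(mixed)) {
    fg[mixed] <- switch(offdiag,
      smoothed = (j > t)[mixed],
      raw      = (i > s)[mixed],
      nearest  = {
        if (is.null(stats)) stop("offdiag = \"nearest\" requires class stats")
        d0 <- (i - stats$u0["i"])^2 + (j - stats$u0["j"])^2
        d1 <- (i - stats$u1["i"])^2 + (j - stats$u1["j"])^2
        (d1 < d0)[mixed]
      })
  }
  matrix(as.integer(fg), nrow(i), ncol(i))
}
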