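#' Energy components of the splitting line
#'
#' A splitting line is a left-to-right 8-connected path (one row per
#' column) along which the vertical intensity change is large — the mark of
#' an illumination step — while texture-rich structure is avoided. Its
#' energy combines three terms:
#' \describe{
#'   \item{\code{color_energy()}}{squared difference between vertically
#'     adjacent pixels, \code{(I(x, y) - I(x-1, y))^2}; the first row is
#'     padded with itself so its energy is 0.}
#'   \item{\code{geometric_energy()}}{Sobel gradient magnitude
#'     \code{sqrt((I * Gx)^2 + (I * Gy)^2)} with replicate-padded borders;
#'     a penalty that keeps the line off edges of real objects.}
#'   \item{\code{position_weight()}}{a per-row Gaussian weight centred at
#'     m/2, pulling the line toward the middle so the two parts are of
#'     comparable size. With rows indexed x = 0..m-1:
#'     \code{sigma = "half_m"} (default) uses the stated width sigma = m/2,
#'     i.e. \code{exp(-(x - m/2)^2 / (2 (m/2)^2))}; \code{"literal_2m"}
#'     uses denominator 2m, \code{exp(-(x - m/2)^2 / (2 m))}, a much
#'     narrower bell for large m.}
#' }
#'
#' @param img gray image matrix.
#' @return \code{color_energy()}, \code{geometric_energy()}: numeric
#'   matrices of the image shape; \code{position_weight()}: numeric vector
#'   of length m with values in (0, 1].
#' @export
color_energy <- function(img) {
  stopifnot(is.matrix(img))
  m <- nrow(img)
  if (m == 1L) return(matrix(0, 1L, ncol(img)))
  up <- img[c(1L, seq_len(m - 1L)), , drop = FALSE]
  (img - up)^2
}

#' @rdname color_energy
#' @export
geometric_energy <- function(img) {
  stopifnot(is.matrix(img))
  gx <- sobel_filter(img, matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3))
  gy <- sobel_filter(img, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3))
  sqrt(gx^2 + gy^2)
}

# 3x3 cross-correlation with replicate padding
sobel_filter <- function(img, kern) {
  m <- nrow(img); n <- ncol(img)
  p <- pad_replicate(img, 1L)
  out <- matrix(0, m, n)
  for (a in 1:3) for (b in 1:3) {
    if (kern[a, b] != 0)
      out <- out + kern[a, b] * p[a:(a + m - 1L), b:(b + n - 1L), drop = FALSE]
  }
  out
}

#' @rdname color_energy
#' @param m number of image rows.
#' @param sigma \code{"half_m"} or \code{"literal_2m"}, see Details.
#' @export
position_weight <- function(m, sigma = c("half_m", "literal_2m")) {
  sigma <- match.arg(sigma)
  x <- 0:(m - 1L)
  denom <- switch(sigma, half_m = 2 * (m / 2)^2, literal_2m = 2 * m)
  exp(-(x - m / 2)^2 / denom)
}

#' Splitting-line energy map
#'
#' Combines the three components into
#' \code{E = W_position * (w_color * E_color - w_geom * E_geometrical)}.
#' Large positive energy marks rows where the intensity jumps (an
#' illumination step) away from object edges.
#'
#' @param img gray image matrix.
#' @param w_color weight of the intensity-change term, default 2.
#' @param w_geom weight of the gradient penalty, default 1.
#' @param sigma position-weight width mode, see [position_weight()].
#' @param source \code{"raw"} computes the energy on the input image (the
#'   default); \code{"median"} on its median-filtered version, useful for
#'   heavily impulse-corrupted inputs.
#' @param k window size for \code{source = "median"}.
#' @return an object of class \code{"energy_map"}: list with \code{E} and
#'   the components \code{color}, \code{geom}, \code{wpos}.
#' @export
energy_map <- function(img, w_color = 2, w_geom = 1,
                       sigma = c("half_m", "literal_2m"),
                       source = c("raw", "median"), k = 3L) {
  sigma <- match.arg(sigma)
  source <- match.arg(source)
  stopifnot(w_color >= 0, w_geom >= 0)
  if (source == "median") img <- median_filter(img, k)
  ec <- color_energy(img)
  eg <- geometric_energy(img)
  w <- position_weight(nrow(img), sigma)
  structure(list(E = w * (w_color * ec - w_geom * eg),
                 color = ec, geom = eg, wpos = w,
                 w_color = w_color, w_geom = w_geom, sigma = sigma),
            class = "energy_map")
}

#' Maximum-energy splitting line by dynamic programming
#'
#' Finds the 8-connected left-to-right path (one row per column, row moves
#' of at most one between adjacent columns) with maximum total energy.
#' Since every such path has exactly n steps, the maximum-total and
#' maximum-average paths coincide. The DP expands column by column:
#' \code{Ecum(x, y) = max(Ecum(x-1..x+1, y-1)) + E(x, y)}, predecessors
#' recorded and the path backtracked from the best last-column entry.
#' Ties prefer the same row, then the row above, then the row below; ties
#' in the last column prefer the smallest row, so the result is
#' deterministic.
#'
#' @param E an \code{"energy_map"} or a numeric energy matrix.
#' @return an object of class \code{"split_path"}: list with \code{rows}
#'   (integer vector, one 1-based row index per column),
#'   \code{total_energy} and \code{mean_energy}.
#' @export
find_splitline <- function(E) {
  if (inherits(E, "energy_map")) E <- E$E
  stopifnot(is.matrix(E), ncol(E) >= 1L)
  m <- nrow(E); n <- ncol(E)
  cum <- E[, 1L]
  pred <- matrix(0L, m, n)
  if (n > 1L) {
    for (y in 2:n) {
      stay <- cum
      best <- stay
      from <- seq_len(m)
      if (m > 1L) {
        above <- c(-Inf, cum[-m])   # predecessor x-1
        below <- c(cum[-1L], -Inf)  # predecessor x+1
        hit <- above > best
        best[hit] <- above[hit]; from[hit] <- from[hit] - 1L
        hit <- below > best
        best[hit] <- below[hit]; from[hit] <- which(hit) + 1L
      }
      pred[, y] <- from
      cum <- best + E[, y]
    }
  }
  rows <- integer(n)
  rows[n] <- which.max(cum)  # which.max takes the smallest index on ties
  if (n > 1L) for (y in n:2) rows[y - 1L] <- pred[rows[y], y]
  total <- sum(E[cbind(rows, seq_len(n))])
  structure(list(rows = rows, total_energy = total,
                 mean_energy = total / n),
            class = "split_path")
}

#' @export
print.split_path <- function(x, ...) {
  cat(sprintf(
    "splitting line over %d columns: rows %d..%d, mean energy %.3f\n",
    length(x$rows), min(x$rows), max(x$rows), x$mean_energy))
  invisible(x)
}

#' Partition an image along a splitting line
#'
#' Part 1 holds the pixels on or above the line (row <= path row for that
#' column), part 2 the rest. The parts are disjoint and cover the image;
#' part 2 is empty when the line runs along the bottom row.
#'
#' @param dim image dimensions \code{c(m, n)} (or a matrix, whose
#'   dimensions are used).
#' @param path a \code{"split_path"}.
#' @return list of two logical membership matrices, \code{part1} and
#'   \code{part2}.
#' @export
partition <- function(dim, path) {
  if (is.matrix(dim)) dim <- base::dim(dim)
  stopifnot(inherits(path, "split_path"), length(path$rows) == dim[2L])
  part1 <- outer(seq_len(dim[1L]), path$rows, `<=`)
  list(part1 = part1, part2 = !part1)
}
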