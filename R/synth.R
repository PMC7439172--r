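#' Generate a synthetic grayscale scene with ground truth
#'
#' Renders blob-like foreground objects (disks, ellipses, rectangles) on a
#' smooth background, modulates both by a vertical illumination field,
#' adds Gaussian sensor noise and finally salt-and-pepper impulses. These
#' are the two regimes in which plain global thresholding fails: impulse
#' corruption, and an illumination gradient strong enough that foreground
#' in the dark region is darker than background in the bright region.
#'
#' The illumination field multiplies the clean levels row-wise:
#' \code{"none"} is constant 1; \code{"linear"} interpolates from
#' \code{illum_top} (first row) to \code{illum_bottom} (last row);
#' \code{"sigmoid"} switches smoothly between the two around the middle
#' row with transition width \code{illum_tau} rows. Gaussian noise is
#' added before the impulses and clipping happens last, so the impulse
#' extremes 0 and L-1 stay exact.
#'
#' Everything is deterministic given \code{seed}; the caller's RNG state
#' is left untouched.
#'
#' @param m,n image dimensions (rows, columns).
#' @param objects list of object descriptors, each a list with
#'   \code{type} in \code{"disk"} (fields cx, cy, r), \code{"ellipse"}
#'   (cx, cy, rx, ry, theta in radians) or \code{"rect"} (x0, x1, y0, y1);
#'   cx/x are row coordinates, cy/y column coordinates (1-based).
#' @param fg,bg foreground and background gray levels before illumination.
#' @param illum illumination field type, see Details.
#' @param illum_top,illum_bottom field multipliers at the first and last
#'   row.
#' @param illum_tau sigmoid transition width in rows.
#' @param gauss_sd standard deviation of the additive Gaussian noise, in
#'   gray levels.
#' @param sp_delta salt-and-pepper density in [0, 1].
#' @param levels number of gray levels.
#' @param seed RNG seed; NULL uses (and advances) the current RNG state.
#' @return list with \code{image} (gray image matrix) and \code{mask}
#'   (0/1 ground truth).
#' @export
synth_scene <- function(m = 96L, n = 96L, objects = list(),
                        fg = 220, bg = 150,
                        illum = c("none", "linear", "sigmoid"),
                        illum_top = 1, illum_bottom = 1,
                        illum_tau = m / 16, gauss_sd = 0, sp_delta = 0,
                        levels = 256L, seed = NULL) {
  illum <- match.arg(illum)
  stopifnot(m >= 1L, n >= 1L, fg != bg, sp_delta >= 0, sp_delta <= 1,
            gauss_sd >= 0)
  mask <- render_objects(m, n, objects)
  x <- seq_len(m)
  field <- switch(illum,
    none = rep(1, m),
    linear = illum_top + (illum_bottom - illum_top) *
      (x - 1) / max(m - 1L, 1L),
    sigmoid = illum_bottom + (illum_top - illum_bottom) /
      (1 + exp((x - (m + 1) / 2) / illum_tau)))
  img <- field * (bg + (fg - bg) * mask)
  with_seed(seed, {
    if (gauss_sd > 0) img <- img + stats::rnorm(m * n, sd = gauss_sd)
    img <- pmin(pmax(round_half_up(img), 0), levels - 1L)
    img <- matrix(as.integer(img), m, n)
    if (sp_delta > 0)
      img <- add_salt_pepper(img, sp_delta, levels = levels)
    list(image = img, mask = mask)
  })
}

render_objects <- function(m, n, objects) {
  mask <- matrix(0L, m, n)
  if (length(objects) == 0L) return(mask)
  X <- matrix(seq_len(m), m, n)
  Y <- matrix(seq_len(n), m, n, byrow = TRUE)
  for (ob in objects) {
    inside <- switch(ob$type,
      disk = (X - ob$cx)^2 + (Y - ob$cy)^2 <= ob$r^2,
      ellipse = {
        dx <- X - ob$cx; dy <- Y - ob$cy
        th <- ob$theta %||% 0
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        (u / ob$rx)^2 + (v / ob$ry)^2 <= 1
      },
      rect = X >= ob$x0 & X <= ob$x1 & Y >= ob$y0 & Y <= ob$y1,
      stop("unknown object type: ", ob$type))
    if (!any(inside))
      stop("object of type '", ob$type, "' lies fully outside the frame")
    mask[inside] <- 1L
  }
  mask
}

#' Corrupt an image with salt-and-pepper noise
#'
#' Each pixel is independently replaced, with probability \code{delta},
#' by one of the extreme levels 0 or L-1 (chosen with equal probability).
#'
#' @param img gray image matrix.
#' @param delta corruption density in [0, 1].
#' @param seed RNG seed; NULL uses the current RNG state.
#' @param levels number of gray levels.
#' @return corrupted gray image matrix.
#' @export
add_salt_pepper <- function(img, delta, seed = NULL, levels = 256L) {
  stopifnot(is.matrix(img), delta >= 0, delta <= 1)
  with_seed(seed, {
    hit <- stats::runif(length(img)) < delta
    vals <- sample(c(0L, levels - 1L), length(img), replace = TRUE)
    out <- img
    out[hit] <- vals[hit]
    out
  })
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Canned synthetic scenes
#'
#' Two seeded fixture families used throughout the package's tests and
#' examples:
#' \describe{
#'   \item{\code{"coins"}}{a 96 x 96 evenly lit scene of nine disks
#'     (radius 10) on a darker background (foreground 190, background 80,
#'     Gaussian sd 4) — a grain/coin-like scene for noise-robustness
#'     studies; corrupt it with [add_salt_pepper()].}
#'   \item{\code{"uneven"}}{the contrast-inversion regime: one small disk
#'     in the bright half and six disks of radius 11 in the shadowed half
#'     (the rice-image layout, where most objects sit in the dark region)
#'     under
#'     a sigmoid vertical illumination field falling from 1.0 (top) to 0.5
#'     (bottom) with a sharp, shadow-like boundary at the middle row, with
#'     foreground 220 and background 150. Foreground in the dark half
#'     (about level 110) ends up darker than background in the bright half
#'     (about level 150), so no single global threshold can work, while
#'     each half on its own is cleanly separable.}
#' }
#'
#' @param name preset name.
#' @param seed RNG seed for the noise.
#' @param sp_delta optional salt-and-pepper density applied on top.
#' @return list with \code{image} and \code{mask}.
#' @export
synth_preset <- function(name = c("coins", "uneven"), seed = NULL,
                         sp_delta = 0) {
  name <- match.arg(name)
  centers <- c(16, 48, 80)
  grid <- expand.grid(cx = centers, cy = centers)
  switch(name,
    coins = {
      objects <- lapply(seq_len(nrow(grid)), function(i)
        list(type = "disk", cx = grid$cx[i], cy = grid$cy[i], r = 10))
      synth_scene(96L, 96L, objects, fg = 190, bg = 80, illum = "none",
                  gauss_sd = 4, sp_delta = sp_delta, seed = seed)
    },
    uneven = {
      centres <- rbind(c(16, 48, 9),                             # bright half
                       c(62, 16, 11), c(62, 48, 11), c(62, 80, 11),  # dark half
                       c(84, 24, 11), c(84, 56, 11), c(84, 84, 11))
      objects <- lapply(seq_len(nrow(centres)), function(i)
        list(type = "disk", cx = centres[i, 1], cy = centres[i, 2],
             r = centres[i, 3]))
      synth_scene(96L, 96L, objects, fg = 220, bg = 150, illum = "sigmoid",
                  illum_top = 1, illum_bottom = 0.5, illum_tau = 0.25,
                  gauss_sd = 4, sp_delta = sp_delta, seed = seed)
    })
}

#' Noise-robustness sweep
#'
#' Corrupts a scene with increasing salt-and-pepper density and evaluates
#' a set of thresholding methods at each level, reproducing the standard
#' ME-versus-density robustness experiment. At each density the same
#' corrupted image is fed to every method so methods are compared on
#' identical noise realisations.
#'
#' Available methods: \code{"otsu2d"} (whole-image 2D Otsu, raw/average
#' histogram), \code{"maotsu2d"} (whole image, raw/median-average),
#' \code{"mmaotsu2d"} (whole image, median/median-average),
#' \code{"scheme1"} and \code{"scheme2"} (partition-based, both on the
#' median/median-average histogram).
#'
#' @param image clean gray image matrix.
#' @param truth ground-truth 0/1 mask.
#' @param deltas vector of salt-and-pepper densities.
#' @param methods character vector of method names, see Details.
#' @param seed base RNG seed; density number i uses seed + i.
#' @param k filter window size.
#' @return data frame with columns \code{method}, \code{delta}, \code{me},
#'   \code{dsc}.
#' @export
noise_sweep <- function(image, truth,
                        deltas = seq(0, 0.5, by = 0.1),
                        methods = c("otsu2d", "mmaotsu2d"),
                        seed = 1L, k = 3L) {
  if (length(deltas) == 0L) stop("deltas must be nonempty")
  check_mask(truth, "truth")
  bad <- setdiff(methods, names(sweep_methods))
  if (length(bad) > 0L)
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  out <- vector("list", length(deltas) * length(methods))
  r <- 0L
  for (di in seq_along(deltas)) {
    noisy <- if (deltas[di] > 0)
      add_salt_pepper(image, deltas[di], seed = seed + di)
    else image
    for (meth in methods) {
      mask <- sweep_methods[[meth]](noisy, k)
      ev <- evaluate_mask(mask, truth)
      r <- r + 1L
      out[[r]] <- data.frame(method = meth, delta = deltas[di],
                             me = ev$me, dsc = ev$dsc)
    }
  }
  do.call(rbind, out)
}

sweep_methods <- list(
  otsu2d = function(img, k)
    fitted(otsu2d(img, scheme = "global", strategy = "avg_only", k = k,
                  keep_image = FALSE)),
  maotsu2d = function(img, k)
    fitted(otsu2d(img, scheme = "global", strategy = "orig_medavg", k = k,
                  keep_image = FALSE)),
  mmaotsu2d = function(img, k)
    fitted(otsu2d(img, scheme = "global", strategy = "med_medavg", k = k,
                  keep_image = FALSE)),
  scheme1 = function(img, k)
    fitted(otsu2d(img, scheme = "split1", strategy = "med_medavg", k = k,
                  keep_image = FALSE), scheme = "split1"),
  scheme2 = function(img, k)
    fitted(otsu2d(img, scheme = "split2", strategy = "med_medavg", k = k,
                  keep_image = FALSE), scheme = "split2")
)
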