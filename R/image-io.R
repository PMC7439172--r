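#' Read a grayscale image
#'
#' Reads PNG, TIFF or PGM (P2/P5) files and normalises them to the internal
#' 8-bit representation: an integer matrix with gray levels in 0..255.
#' RGB inputs are collapsed to luminance (0.299 R + 0.587 G + 0.114 B);
#' higher bit depths are rescaled to 0..255. Rounding is half-up.
#'
#' @param path file path; format inferred from the extension
#'   (.png, .tif/.tiff, .pgm/.pnm).
#' @param levels number of gray levels of the internal representation.
#' @return gray image matrix (see [as_gray_image()]).
#' @export
read_gray <- function(path, levels = 256L) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = ,
    pnm  = read_pgm(path),
    stop("unsupported image format: .", ext)
  )
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    y <- if (d[3] >= 3L) {
      0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else {
      x[, , 1]  # gray or gray+alpha
    }
    x <- matrix(y, d[1], d[2])  # guard against dropped length-1 dims
  }
  # png/tiff decoders return intensities in [0,1] regardless of bit depth
  if (ext %in% c("png", "tif", "tiff")) x <- x * (levels - 1)
  if (length(x) == 0L) stop("zero-sized image: ", path)
  as_gray_image(pmin(pmax(x, 0), levels - 1), levels = levels)
}

#' Write a binary mask to disk
#'
#' Foreground (1) is stored as gray level 255, background (0) as 0, so that
#' \code{mask_from_gray(read_gray(path))} reproduces the mask exactly.
#'
#' @param mask integer 0/1 matrix.
#' @param path output path (.png, .tif/.tiff, .pgm).
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(mask * 1.0, path),
    tif  = ,
    tiff = tiff::writeTIFF(mask * 1.0, path),
    pgm  = write_pgm(mask * 255L, path),
    stop("unsupported mask format: .", ext)
  )
  invisible(path)
}

#' Write a gray image to disk
#'
#' @param img gray image matrix.
#' @param path output path (.png, .tif/.tiff, .pgm).
#' @param levels number of gray levels.
#' @export
write_gray <- function(img, path, levels = 256L) {
  stopifnot(is.matrix(img))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(img / (levels - 1), path),
    tif  = ,
    tiff = tiff::writeTIFF(img / (levels - 1), path),
    pgm  = write_pgm(img, path, maxval = levels - 1L),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

# Minimal PGM (P2 ascii / P5 binary) reader; maxval up to 65535.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- pgm_tokenizer(con)
  magic <- tok()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  n <- as.integer(tok()); m <- as.integer(tok())
  maxval <- as.integer(tok())
  if (anyNA(c(m, n, maxval)) || m < 1L || n < 1L || maxval < 1L)
    stop("malformed PGM header in ", path)
  npix <- m * n
  v <- if (magic == "P2") {
    vapply(seq_len(npix), function(i) as.numeric(tok()), numeric(1))
  } else if (maxval < 256L) {
    as.numeric(readBin(con, "integer", n = npix, size = 1, signed = FALSE))
  } else {
    as.numeric(readBin(con, "integer", n = npix, size = 2, signed = FALSE,
                       endian = "big"))
  }
  if (length(v) < npix) stop("truncated PGM data in ", path)
  img <- matrix(v, nrow = m, ncol = n, byrow = TRUE)  # PGM is row-major
  if (maxval != 255L) img <- img * 255 / maxval
  img
}

# token reader that skips whitespace and '#' comments; after the maxval
# token exactly one whitespace byte separates header from P5 raster
pgm_tokenizer <- function(con) {
  function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
      } else if (!grepl("[[:space:]]", ch)) break
    }
    tok <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L || grepl("[[:space:]]", ch)) break
      tok <- paste0(tok, ch)
    }
    tok
  }
}

write_pgm <- function(img, path, maxval = 255L) {
  stopifnot(is.matrix(img), min(img) >= 0, max(img) <= maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(img), nrow(img), maxval), con,
            eos = NULL)
  writeBin(as.integer(t(img)), con, size = if (maxval < 256L) 1L else 2L,
           endian = "big")
  invisible(path)
}
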