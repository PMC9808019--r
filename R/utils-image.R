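#' Read a raster image as an RGB array
#'
#' Reads a PNG or TIFF image and returns a numeric `height x width x 3` array
#' on the 0--255 scale. Greyscale images are expanded to three identical
#' channels and an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric array of dimension `c(height, width, 3)` with values in
#'   `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF images requires the 'tiff' package")
      }
      tiff::readTIFF(path)
    },
    stop("unsupported image format: '", ext, "' (expected png/tif/tiff)")
  )
  if (length(dim(img)) == 2L) {
    img <- array(img, c(dim(img), 1L))
  }
  nc <- dim(img)[3]
  if (nc == 1L) {
    img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  } else if (nc >= 4L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (nc == 2L) { # grey + alpha
    img <- array(rep(img[, , 1], 3L), c(dim(img)[1:2], 3L))
  }
  img * 255
}

#' Write an RGB array to a PNG file
#'
#' @param image Numeric array `height x width x 3` on the 0--255 scale (or a
#'   matrix, written as greyscale).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  img <- pmin(pmax(image / 255, 0), 1)
  png::writePNG(img, target = path)
  invisible(path)
}

#' 8-bit luminance of an RGB image
#'
#' Rec. 601 luma, `0.299 R + 0.587 G + 0.114 B`, rounded to integer grey
#' levels. This is the single channel on which tissue/background separation
#' operates.
#'
#' @param image Numeric array `height x width x 3`, values in `[0, 255]`.
#' @return Integer-valued matrix of grey levels in `[0, 255]`.
#' @export
luminance <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 3L)
  round(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

# Bilinear resize of a matrix (corner-aligned sampling grid).
resize_bilinear <- function(m, out_h, out_w) {
  nr <- nrow(m)
  nc <- ncol(m)
  yi <- if (nr == 1L) rep(1, out_h) else seq(1, nr, length.out = out_h)
  xi <- if (nc == 1L) rep(1, out_w) else seq(1, nc, length.out = out_w)
  y0 <- pmin(floor(yi), nr - 1L)
  x0 <- pmin(floor(xi), nc - 1L)
  y0 <- pmax(y0, 1L)
  x0 <- pmax(x0, 1L)
  wy <- yi - y0
  wx <- xi - x0
  a <- m[y0, x0, drop = FALSE]
  b <- m[y0 + 1L, x0, drop = FALSE]
  cc <- m[y0, x0 + 1L, drop = FALSE]
  d <- m[y0 + 1L, x0 + 1L, drop = FALSE]
  wym <- matrix(wy, out_h, out_w)
  wxm <- matrix(wx, out_h, out_w, byrow = TRUE)
  a * (1 - wym) * (1 - wxm) + b * wym * (1 - wxm) +
    cc * (1 - wym) * wxm + d * wym * wxm
}

# Block-mean downsampling of an H x W x C array by an integer factor.
block_mean_downsample <- function(image, factor) {
  d <- dim(image)
  stopifnot(d[1] %% factor == 0, d[2] %% factor == 0)
  h2 <- d[1] %/% factor
  w2 <- d[2] %/% factor
  ch <- d[3]
  # average rows, then columns, one colMeans each
  a <- colMeans(array(image, c(factor, h2 * d[2] * ch)))    # -> (h2, W, C)
  a <- array(a, c(h2, d[2], ch))
  a <- aperm(a, c(2, 1, 3))                                 # (W, h2, C)
  b <- colMeans(array(a, c(factor, w2 * h2 * ch)))          # -> (w2, h2, C)
  aperm(array(b, c(w2, h2, ch)), c(2, 1, 3))
}
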