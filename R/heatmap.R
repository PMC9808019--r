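#' Render patch predictions as a slide heatmap
#'
#' Rasterises per-tile predictions at a downsampled slide resolution. Where
#' kept tiles overlap, each raster cell shows the *maximum* prediction among
#' the tiles covering it; regions covered by no kept tile carry an
#' out-of-band "discarded" sentinel (a mask channel), so a confidently
#' normal region (value 0) remains distinguishable from discarded
#' background, which renders black.
#'
#' @param tiles Data frame with 0-based tile origins `x`, `y` (kept tiles
#'   only, or with a logical `kept` column which will be applied).
#' @param predictions Numeric vector in `[0, 1]`, aligned with the kept
#'   tiles.
#' @param slide_width,slide_height Slide dimensions in pixels.
#' @param tile_size Tile side length in pixels.
#' @param downsample Integer raster downsampling factor.
#' @return An object of class `heatmap_raster`: list with `values` (matrix,
#'   `NA` outside coverage), `covered` (logical matrix) and the geometry
#'   fields.
#' @export
render_heatmap <- function(tiles, predictions, slide_width, slide_height,
                           tile_size = 256L, downsample = 32L) {
  if (!is.null(tiles$kept)) {
    predictions <- predictions[tiles$kept]
    tiles <- tiles[tiles$kept, , drop = FALSE]
  }
  if (nrow(tiles) != length(predictions)) {
    stop("predictions are not aligned with the kept tiles")
  }
  hh <- as.integer(ceiling(slide_height / downsample))
  ww <- as.integer(ceiling(slide_width / downsample))
  values <- matrix(-Inf, hh, ww)
  covered <- matrix(FALSE, hh, ww)
  if (nrow(tiles) == 0L) {
    warning("no kept tiles: heatmap is entirely discarded background")
    values[] <- NA_real_
    return(structure(list(values = values, covered = covered,
                          downsample = as.integer(downsample),
                          slide_width = slide_width,
                          slide_height = slide_height),
                     class = "heatmap_raster"))
  }
  for (i in seq_len(nrow(tiles))) {
    r0 <- floor(tiles$y[i] / downsample) + 1L
    r1 <- ceiling((tiles$y[i] + tile_size) / downsample)
    c0 <- floor(tiles$x[i] / downsample) + 1L
    c1 <- ceiling((tiles$x[i] + tile_size) / downsample)
    r1 <- min(r1, hh)
    c1 <- min(c1, ww)
    block <- values[r0:r1, c0:c1]
    values[r0:r1, c0:c1] <- pmax(block, predictions[i])
    covered[r0:r1, c0:c1] <- TRUE
  }
  values[!covered] <- NA_real_
  structure(list(values = values, covered = covered,
                 downsample = as.integer(downsample),
                 slide_width = slide_width, slide_height = slide_height),
            class = "heatmap_raster")
}

#' Blend a heatmap over a slide thumbnail
#'
#' Covered cells are alpha-blended between the thumbnail and a colormap of
#' the prediction value; discarded cells render black.
#'
#' @param heatmap A [render_heatmap()] result.
#' @param thumbnail RGB array (0--255) with the same dimensions as the
#'   heatmap raster.
#' @param colormap Either a vector of colours interpolated over `[0, 1]`,
#'   or a function mapping values in `[0, 1]` to an `n x 3` RGB matrix
#'   (0--255). Default: a perceptually uniform viridis ramp.
#' @param opacity Blend weight of the colormap in `[0, 1]`.
#' @return RGB array (0--255), PNG-writable via [write_image()].
#' @export
compose_overlay <- function(heatmap, thumbnail,
                            colormap = grDevices::hcl.colors(256, "viridis"),
                            opacity = 0.5) {
  stopifnot(inherits(heatmap, "heatmap_raster"), opacity >= 0, opacity <= 1)
  d <- dim(thumbnail)
  if (d[1] != nrow(heatmap$values) || d[2] != ncol(heatmap$values)) {
    stop("thumbnail dimensions do not match the heatmap raster")
  }
  cmap_fun <- if (is.function(colormap)) {
    colormap
  } else {
    ramp <- grDevices::colorRamp(colormap)
    function(v) ramp(v)
  }
  out <- array(0, d)
  cov <- heatmap$covered
  if (any(cov)) {
    vals <- heatmap$values[cov]
    cols <- cmap_fun(pmin(pmax(vals, 0), 1)) # n x 3, 0-255
    for (ch in 1:3) {
      plane <- out[, , ch]
      thumb <- thumbnail[, , ch]
      plane[cov] <- (1 - opacity) * thumb[cov] + opacity * cols[, ch]
      out[, , ch] <- plane
    }
  }
  pmin(pmax(out, 0), 255)
}
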