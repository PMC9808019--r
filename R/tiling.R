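#' Otsu's threshold from a 256-bin grey-level histogram
#'
#' Exhaustively maximises the between-class variance over all 256 candidate
#' grey levels. A threshold `t` places levels `0..t` in the dark (tissue)
#' class and levels `t+1..255` in the bright (background) class. Ties are
#' broken towards the lowest level, so the result is deterministic.
#'
#' @param histogram Numeric vector of length 256: counts per grey level
#'   (level 0 first). At least two bins must be non-empty.
#' @return An object of class `otsu_result`: a list with `threshold`
#'   (integer grey level in `[0, 255]`) and `between_class_variance`.
#' @export
compute_otsu <- function(histogram) {
  stopifnot(is.numeric(histogram), length(histogram) == 256L,
            all(histogram >= 0))
  if (sum(histogram) <= 0 || sum(histogram > 0) < 2L) {
    stop("degenerate histogram: need at least two non-empty grey levels")
  }
  p <- histogram / sum(histogram)
  lev <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256L]
  w1 <- 1 - w0
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * w1)
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_best <- which.max(sigma_b) - 1L # which.max returns the first maximum
  structure(
    list(threshold = t_best, between_class_variance = sigma_b[t_best + 1L]),
    class = "otsu_result"
  )
}

#' Build the sliding-window tile grid for a slide
#'
#' Enumerates, in row-major order (left-to-right, then top-to-bottom), every
#' fully contained `size x size` tile at the given stride. Tiles that would
#' overhang the slide are not emitted, so an image smaller than `size` in
#' either axis yields an empty grid. Coordinates are 0-based pixel offsets of
#' the tile's top-left corner.
#'
#' @param width,height Slide dimensions in pixels at working resolution.
#' @param size Tile side length in pixels.
#' @param stride Step between tile origins in pixels.
#' @param slide_id Optional slide identifier carried on the grid.
#' @return An object of class `tile_grid`: a list with the geometry fields
#'   and `tiles`, a data frame with columns `x`, `y`, `background_fraction`
#'   (NA until [filter_tiles()] runs) and `kept`.
#' @export
build_tile_grid <- function(width, height, size = 256L, stride = 128L,
                            slide_id = NA_character_) {
  stopifnot(size > 0, stride > 0, width >= 0, height >= 0)
  xs <- if (width >= size) seq(0L, by = stride, length.out = (width - size) %/% stride + 1L) else integer(0)
  ys <- if (height >= size) seq(0L, by = stride, length.out = (height - size) %/% stride + 1L) else integer(0)
  tiles <- expand.grid(x = as.integer(xs), y = as.integer(ys),
                       KEEP.OUT.ATTRS = FALSE)  # x varies fastest: row-major
  tiles$background_fraction <- rep(NA_real_, nrow(tiles))
  tiles$kept <- rep(NA, nrow(tiles))
  structure(
    list(slide_id = slide_id, width = as.integer(width),
         height = as.integer(height), size = as.integer(size),
         stride = as.integer(stride), tiles = tiles),
    class = "tile_grid"
  )
}

#' Background fraction of a patch
#'
#' Fraction of pixels whose 8-bit luminance is strictly above the Otsu
#' threshold. On H&E slides the background is bright (near white), so
#' "background" means brighter than the threshold.
#'
#' @param patch RGB array (`size x size x 3`, 0--255) or a precomputed
#'   luminance matrix.
#' @param otsu_threshold Grey-level threshold in `[0, 255]`.
#' @return A value in `[0, 1]`.
#' @export
background_fraction <- function(patch, otsu_threshold) {
  lum <- if (is.matrix(patch)) patch else luminance(patch)
  mean(lum > otsu_threshold)
}

#' Per-slide Otsu threshold from a downsampled luminance thumbnail
#'
#' Computes one global grey-level threshold per slide from a thumbnail
#' obtained by subsampling the luminance image. A single slide-level
#' threshold is more stable on near-empty tiles than per-patch thresholds.
#'
#' @param image RGB array at working resolution.
#' @param downsample Subsampling step for the thumbnail (defaults to the
#'   tile stride).
#' @return An `otsu_result` (see [compute_otsu()]).
#' @export
slide_otsu_threshold <- function(image, downsample = 128L) {
  lum <- luminance(image)
  step <- max(1L, as.integer(downsample))
  thumb <- lum[seq(1L, nrow(lum), by = step), seq(1L, ncol(lum), by = step)]
  compute_otsu(tabulate(as.integer(thumb) + 1L, nbins = 256L))
}

#' Annotate a tile grid with background fractions and keep flags
#'
#' Every tile is annotated with its background fraction at working
#' resolution; a tile is kept iff its background fraction is at most
#' `max_bg` (i.e. tiles with *more* than 75% background are discarded, by
#' default). Tile order is preserved and the operation is idempotent.
#'
#' @param grid A `tile_grid` built for the same slide dimensions.
#' @param image RGB array for the slide.
#' @param otsu_threshold Grey-level threshold; if `NULL`, computed from the
#'   slide via [slide_otsu_threshold()].
#' @param max_bg Maximum tolerated background fraction for a kept tile.
#' @return The grid with `tiles$background_fraction` and `tiles$kept` filled.
#' @export
filter_tiles <- function(grid, image, otsu_threshold = NULL, max_bg = 0.75) {
  stopifnot(inherits(grid, "tile_grid"))
  d <- dim(image)
  if (d[1] != grid$height || d[2] != grid$width) {
    stop("image dimensions do not match the tile grid")
  }
  if (is.null(otsu_threshold)) {
    otsu_threshold <- slide_otsu_threshold(image, grid$stride)$threshold
  } else if (inherits(otsu_threshold, "otsu_result")) {
    otsu_threshold <- otsu_threshold$threshold
  }
  lum <- luminance(image)
  n <- nrow(grid$tiles)
  bf <- numeric(n)
  sz <- grid$size
  for (i in seq_len(n)) {
    x0 <- grid$tiles$x[i]
    y0 <- grid$tiles$y[i]
    bf[i] <- mean(lum[(y0 + 1L):(y0 + sz), (x0 + 1L):(x0 + sz)] > otsu_threshold)
  }
  grid$tiles$background_fraction <- bf
  grid$tiles$kept <- bf <= max_bg
  grid$otsu_threshold <- as.integer(otsu_threshold)
  grid$max_bg <- max_bg
  grid
}

#' Tile a slide: grid construction, Otsu threshold and background filtering
#'
#' Convenience wrapper running [build_tile_grid()], [slide_otsu_threshold()]
#' and [filter_tiles()] in sequence.
#'
#' @inheritParams build_tile_grid
#' @inheritParams filter_tiles
#' @param image RGB array at working resolution.
#' @return A filtered `tile_grid`.
#' @export
tile_slide <- function(image, size = 256L, stride = 128L, max_bg = 0.75,
                       slide_id = NA_character_) {
  grid <- build_tile_grid(ncol(image), nrow(image), size = size,
                          stride = stride, slide_id = slide_id)
  if (nrow(grid$tiles) == 0L) {
    return(grid)
  }
  thr <- slide_otsu_threshold(image, stride)$threshold
  filter_tiles(grid, image, thr, max_bg = max_bg)
}

#' Extract one tile from a slide image
#'
#' @param image RGB array.
#' @param x,y 0-based pixel offsets of the tile's top-left corner.
#' @param size Tile side length.
#' @return `size x size x 3` array.
#' @export
extract_tile <- function(image, x, y, size = 256L) {
  image[(y + 1L):(y + size), (x + 1L):(x + size), , drop = FALSE]
}

#' Open a slide behind the region-reader contract
#'
#' Wraps a plain raster file (PNG/TIFF) behind the minimal interface the
#' pipeline needs from a slide: dimensions plus rectangular RGB region
#' access. Pyramidal WSI readers can implement the same contract for
#' deployment; the manifest's `image_uri` is assumed to point at the working
#' resolution.
#'
#' @param image_uri Path to the image.
#' @return An object of class `slide_reader`: list with `width`, `height`
#'   and `read_region(x, y, width, height)` (0-based offsets).
#' @export
slide_reader <- function(image_uri) {
  image <- read_image(image_uri)
  d <- dim(image)
  structure(
    list(
      width = d[2], height = d[1], image_uri = image_uri,
      read_region = function(x, y, width, height) {
        image[(y + 1L):(y + height), (x + 1L):(x + width), , drop = FALSE]
      },
      image = function() image
    ),
    class = "slide_reader"
  )
}

#' Read and validate a slide manifest
#'
#' A manifest is a CSV with one row per slide and columns `slide_id`,
#' `case_id`, `label` (`normal` or `coeliac`), `source` and `image_uri`
#' (plus, optionally, `mask_uri` for synthetic slides with ground truth).
#'
#' @param path CSV path.
#' @param base_dir If given, relative `image_uri`/`mask_uri` entries are
#'   resolved against it.
#' @return A validated data frame.
#' @export
read_manifest <- function(path, base_dir = NULL) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_manifest(m)
  if (!is.null(base_dir)) {
    for (col in intersect(c("image_uri", "mask_uri"), names(m))) {
      rel <- !grepl("^(/|[A-Za-z]:)", m[[col]]) & nzchar(m[[col]])
      m[[col]][rel] <- file.path(base_dir, m[[col]][rel])
    }
  }
  m
}

validate_manifest <- function(m) {
  req <- c("slide_id", "case_id", "label", "source", "image_uri")
  missing <- setdiff(req, names(m))
  if (length(missing)) {
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(m$slide_id)) stop("manifest slide_id values must be unique")
  if (any(!nzchar(m$case_id))) stop("manifest case_id values must be non-empty")
  bad <- setdiff(unique(m$label), c("normal", "coeliac"))
  if (length(bad)) {
    stop("manifest labels must be 'normal' or 'coeliac'; found: ",
         paste(bad, collapse = ", "))
  }
  invisible(m)
}
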