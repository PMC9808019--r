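#' Stain-normalisation configuration
#'
#' Constants of the Macenko estimator. `io_white` is the transmitted-light
#' white point; pixels whose optical-density (OD) vector magnitude falls
#' below `od_min` are treated as background and excluded from estimation;
#' the stain vectors are taken at the `angle_percentile`-th and
#' `(100 - angle_percentile)`-th percentiles of the projection angle in the
#' principal OD plane; `conc_percentile` gives the robust per-stain maximum
#' concentration.
#'
#' @param io_white White point on the 0--255 scale.
#' @param od_min OD magnitude below which pixels are considered unstained.
#' @param angle_percentile Percentile (in `(0, 50)`) for the angular extremes.
#' @param conc_percentile Percentile for per-stain maximum concentrations.
#' @return A `stain_norm_config` list.
#' @export
stain_norm_config <- function(io_white = 255, od_min = 0.15,
                              angle_percentile = 1, conc_percentile = 99) {
  stopifnot(od_min > 0, angle_percentile > 0, angle_percentile < 50,
            conc_percentile > 50, conc_percentile <= 100, io_white > 0)
  structure(list(io_white = io_white, od_min = od_min,
                 angle_percentile = angle_percentile,
                 conc_percentile = conc_percentile),
            class = "stain_norm_config")
}

#' RGB to optical density (Beer--Lambert)
#'
#' `od = -log10(max(pixel, 1) / io_white)`, elementwise. Pixel values are
#' floored at 1 so fully black pixels map to a finite OD.
#'
#' @param pixels Numeric RGB values on the 0--255 scale (any shape).
#' @param io_white White point.
#' @return OD values (non-negative), same shape as the input.
#' @export
rgb_to_od <- function(pixels, io_white = 255) {
  -log10(pmax(pixels, 1) / io_white)
}

#' Optical density back to 8-bit RGB
#'
#' Inverse of [rgb_to_od()] up to quantisation: `round(io_white * 10^-od)`,
#' clipped to `[0, 255]`.
#'
#' @param od Non-negative OD values (any shape).
#' @param io_white White point.
#' @return RGB values on the 0--255 scale, same shape.
#' @export
od_to_rgb <- function(od, io_white = 255) {
  pmin(pmax(round(io_white * 10^(-od)), 0), 255)
}

# Flatten an H x W x 3 patch into an N x 3 OD matrix.
as_od_matrix <- function(patch, io_white = 255) {
  stopifnot(length(dim(patch)) == 3L, dim(patch)[3] == 3L)
  rgb_to_od(matrix(patch, ncol = 3L), io_white)
}

#' Estimate a Macenko stain profile from a patch
#'
#' Implements the stain-vector estimator: (i) convert to OD and discard
#' pixels with OD magnitude below `od_min`; (ii) find the best-fit plane
#' through the OD cloud from the top two singular directions; (iii) project
#' the retained pixels onto that plane; (iv) take the directions at the 1st
#' and 99th percentile of the projection angle as the two stain vectors;
#' (v) order columns haematoxylin-then-eosin, haematoxylin being the column
#' with the larger blue-channel OD component. Per-stain reference maxima are
#' the 99th percentile of the unmixed concentrations.
#'
#' @param patch RGB array (`H x W x 3`, 0--255) or an `N x 3` matrix of RGB
#'   pixels.
#' @param config A [stain_norm_config()].
#' @return An object of class `stain_profile`: list with `stain_matrix`
#'   (3 x 2, unit non-negative columns, H first) and `max_concentrations`
#'   (length-2 vector).
#' @export
estimate_stain_profile <- function(patch, config = stain_norm_config()) {
  od <- if (is.matrix(patch) && ncol(patch) == 3L) {
    rgb_to_od(patch, config$io_white)
  } else {
    as_od_matrix(patch, config$io_white)
  }
  estimate_profile_from_od(od, config)
}

# Core Macenko estimator on an N x 3 OD matrix. Above 20k retained pixels a
# deterministic stride subsample is used; the percentile geometry is
# insensitive to this and it keeps per-tile estimation cheap.
estimate_profile_from_od <- function(od, config = stain_norm_config()) {
  mag <- sqrt(rowSums(od^2))
  odf <- od[mag > config$od_min, , drop = FALSE]
  if (nrow(odf) < 100L) {
    stop("no stainable tissue: fewer than 100 pixels above the OD cutoff")
  }
  if (nrow(odf) > 20000L) {
    odf <- odf[seq(1L, nrow(odf), length.out = 20000L), , drop = FALSE]
  }
  sv <- svd(odf, nu = 0)
  # a single stain leaves a rank-1 OD cloud (second singular value at the
  # quantisation-noise floor, ~0.2% of the first); genuine two-stain tissue
  # sits well above 2%
  if (sv$d[2] < 0.01 * sv$d[1]) {
    stop("degenerate stain distribution: rank-1 optical-density cloud")
  }
  v <- sv$v[, 1:2, drop = FALSE]
  proj <- odf %*% v
  if (mean(proj[, 1]) < 0) { # orient the plane axis towards the cloud
    v[, 1] <- -v[, 1]
    proj[, 1] <- -proj[, 1]
  }
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(
    phi, c(config$angle_percentile, 100 - config$angle_percentile) / 100,
    names = FALSE
  )
  if (diff(q) < 0.03) { # radians; quantisation noise alone gives ~0.01
    stop("degenerate stain distribution: no angular spread in the OD plane")
  }
  unit_nonneg <- function(ang) {
    u <- as.vector(v %*% c(cos(ang), sin(ang)))
    if (sum(u) < 0) u <- -u
    u <- pmax(u, 0)
    nrm <- sqrt(sum(u^2))
    if (nrm < 1e-8) {
      stop("degenerate stain distribution: stain vector collapsed to zero")
    }
    u / nrm
  }
  u1 <- unit_nonneg(q[1])
  u2 <- unit_nonneg(q[2])
  m <- if (u1[3] >= u2[3]) cbind(u1, u2) else cbind(u2, u1)
  dimnames(m) <- list(c("R", "G", "B"), c("H", "E"))
  conc <- od_to_concentrations(odf, m)
  maxc <- apply(conc, 2, stats::quantile, probs = config$conc_percentile / 100,
                names = FALSE)
  names(maxc) <- c("H", "E")
  structure(list(stain_matrix = m, max_concentrations = maxc),
            class = "stain_profile")
}

# Least-squares unmixing of an N x 3 OD matrix against a 3 x 2 stain matrix,
# clipped at zero.
od_to_concentrations <- function(od, stain_matrix) {
  sol <- od %*% stain_matrix %*% solve(crossprod(stain_matrix))
  pmax(sol, 0)
}

#' Per-pixel stain concentrations
#'
#' Least-squares solution of `od ~ stain_matrix %*% c` for every pixel,
#' clipped at zero.
#'
#' @param patch RGB array (`H x W x 3`) or `N x 3` RGB matrix.
#' @param profile A `stain_profile`.
#' @param io_white White point.
#' @return For array input, an `H x W x 2` array (H then E); for matrix
#'   input, an `N x 2` matrix.
#' @export
stain_concentrations <- function(patch, profile, io_white = 255) {
  is_arr <- length(dim(patch)) == 3L
  od <- if (is_arr) as_od_matrix(patch, io_white) else rgb_to_od(patch, io_white)
  conc <- od_to_concentrations(od, profile$stain_matrix)
  if (is_arr) array(conc, c(dim(patch)[1:2], 2L)) else conc
}

#' Normalise a patch into a reference stain basis
#'
#' Estimates the patch's own stain profile (or uses a supplied one), unmixes
#' every pixel into stain concentrations, rescales each stain by the ratio
#' of reference to source maximum concentrations, and re-renders through the
#' reference stain matrix:
#' `od' = M_ref %*% (c * max_ref / max_src)`.
#'
#' @param patch RGB array `H x W x 3` on the 0--255 scale.
#' @param reference Target `stain_profile` (defaults to the package
#'   reference, [reference_stain_profile()]).
#' @param config A [stain_norm_config()].
#' @param profile Optional pre-estimated source profile (e.g. a per-slide
#'   profile); if `NULL` the profile is estimated from the patch itself.
#' @return RGB array of the same shape, values in `[0, 255]`.
#' @export
normalize_patch <- function(patch, reference = reference_stain_profile(),
                            config = stain_norm_config(), profile = NULL) {
  od <- as_od_matrix(patch, config$io_white)
  src <- if (is.null(profile)) estimate_profile_from_od(od, config) else profile
  conc <- od_to_concentrations(od, src$stain_matrix)
  scale <- reference$max_concentrations / pmax(src$max_concentrations, 1e-8)
  conc <- sweep(conc, 2, scale, "*")
  od2 <- conc %*% t(reference$stain_matrix)
  array(od_to_rgb(od2, config$io_white), dim(patch))
}

#' Canonical H&E stain matrix
#'
#' The standard haematoxylin/eosin optical-density vectors (columns
#' normalised to unit length, haematoxylin first). Used as the reference
#' basis for normalisation and as the canonical rendering matrix of the
#' synthetic slide generator.
#'
#' @return A 3 x 2 matrix with unit, non-negative columns.
#' @export
canonical_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  m <- cbind(H = h / sqrt(sum(h^2)), E = e / sqrt(sum(e^2)))
  rownames(m) <- c("R", "G", "B")
  m
}

#' Package reference stain profile
#'
#' A fixed normalisation target: the canonical H&E stain matrix together
#' with reference maximum concentrations estimated once from the synthetic
#' generator's canonical rendering (base tissue concentrations plus their
#' smooth spatial variation). Override by passing your own profile to
#' [normalize_patch()].
#'
#' @return A `stain_profile`.
#' @export
reference_stain_profile <- function() {
  structure(
    list(
      stain_matrix = canonical_stain_matrix(),
      max_concentrations = c(H = 0.9, E = 0.9)
    ),
    class = "stain_profile"
  )
}

#' Serialise / read a stain profile as JSON
#'
#' @param profile A `stain_profile`.
#' @param path JSON path.
#' @return `write_stain_profile()` returns `path` invisibly;
#'   `read_stain_profile()` returns a `stain_profile`.
#' @export
write_stain_profile <- function(profile, path) {
  jsonlite::write_json(
    list(stain_matrix = as.numeric(profile$stain_matrix), # column-major 3x2
         max_concentrations = as.numeric(profile$max_concentrations)),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(as.numeric(x$stain_matrix), nrow = 3L)
  dimnames(m) <- list(c("R", "G", "B"), c("H", "E"))
  maxc <- as.numeric(x$max_concentrations)
  names(maxc) <- c("H", "E")
  structure(list(stain_matrix = m, max_concentrations = maxc),
            class = "stain_profile")
}
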