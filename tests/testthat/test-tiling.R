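test_that("Otsu threshold separates a two-point histogram at the lower mode", {
  h <- numeric(256)
  h[11] <- 500 # grey level 10
  h[201] <- 500 # grey level 200
  res <- compute_otsu(h)
  expect_s3_class(res, "otsu_result")
  expect_identical(res$threshold, 10L)
  expect_gt(res$between_class_variance, 0)
})

test_that("Otsu matches an exhaustive threshold search on random histograms", {
  set.seed(11)
  for (i in 1:25) {
    h <- stats::rpois(256, stats::rexp(256, 1 / 20))
    if (sum(h > 0) < 2) next
    expect_identical(compute_otsu(h)$threshold, brute_force_otsu(h))
  }
})

test_that("degenerate histograms are rejected", {
  h <- numeric(256)
  h[100] <- 1000
  expect_error(compute_otsu(h), "degenerate histogram")
  expect_error(compute_otsu(numeric(256)), "degenerate histogram")
})

test_that("tile grids enumerate fully contained tiles row-major", {
  g <- build_tile_grid(512, 512)
  expect_equal(nrow(g$tiles), 9L)
  # row-major: x varies fastest
  expect_equal(g$tiles$x[1:3], c(0L, 128L, 256L))
  expect_equal(g$tiles$y[1:3], c(0L, 0L, 0L))
  expect_equal(nrow(build_tile_grid(256, 256)$tiles), 1L)
  expect_equal(build_tile_grid(256, 256)$tiles[1, c("x", "y")],
               data.frame(x = 0L, y = 0L))
  expect_equal(nrow(build_tile_grid(255, 512)$tiles), 0L)
})

test_that("tile counts follow the closed form for random geometries", {
  set.seed(21)
  for (i in 1:50) {
    w <- sample(50:3000, 1)
    h <- sample(50:3000, 1)
    size <- sample(c(64L, 128L, 256L, 300L), 1)
    stride <- sample(c(32L, 64L, 128L, 256L), 1)
    g <- build_tile_grid(w, h, size = size, stride = stride)
    nx <- if (w >= size) (w - size) %/% stride + 1L else 0L
    ny <- if (h >= size) (h - size) %/% stride + 1L else 0L
    expect_equal(nrow(g$tiles), nx * ny)
    if (nrow(g$tiles)) {
      expect_true(all(g$tiles$x + size <= w))
      expect_true(all(g$tiles$y + size <= h))
      expect_true(all(g$tiles$x %% stride == 0))
    }
  }
})

test_that("background fraction counts pixels strictly above the threshold", {
  expect_equal(background_fraction(flat_patch(255, 256), 200), 1.0)
  expect_equal(background_fraction(flat_patch(0, 256), 200), 0.0)
  half <- flat_patch(0, 256)
  half[1:128, , ] <- 255
  expect_equal(background_fraction(half, 128), 0.5)
  # boundary: equal to the threshold is not background
  expect_equal(background_fraction(flat_patch(200, 64), 200), 0.0)
})

test_that("filter_tiles keeps everything on tissue and nothing on background", {
  dark <- flat_patch(40, 512)
  g <- filter_tiles(build_tile_grid(512, 512), dark, otsu_threshold = 128)
  expect_true(all(g$tiles$kept))
  white <- flat_patch(255, 512)
  g2 <- filter_tiles(build_tile_grid(512, 512), white, otsu_threshold = 128)
  expect_false(any(g2$tiles$kept))
})

test_that("the one-quadrant fixture matches a brute-force keep-set", {
  img <- flat_patch(255, 512)
  img[1:256, 1:256, ] <- 30 # top-left quadrant is tissue
  thr <- slide_otsu_threshold(img, downsample = 16)$threshold
  g <- filter_tiles(build_tile_grid(512, 512), img, thr, max_bg = 0.75)
  lum <- luminance(img)
  for (i in seq_len(nrow(g$tiles))) {
    x0 <- g$tiles$x[i]
    y0 <- g$tiles$y[i]
    bf <- mean(lum[(y0 + 1):(y0 + 256), (x0 + 1):(x0 + 256)] > thr)
    expect_equal(g$tiles$background_fraction[i], bf)
    expect_identical(g$tiles$kept[i], bf <= 0.75)
  }
  # tiles overlapping the tissue quadrant by more than 25% of their area
  overlap <- pmax(0, 256 - g$tiles$x) * pmax(0, 256 - g$tiles$y) / 256^2
  expect_identical(g$tiles$kept, overlap >= 0.25)
})

test_that("filter_tiles is idempotent and order-preserving", {
  set.seed(5)
  img <- array(sample(0:255, 512 * 512 * 3, TRUE), c(512, 512, 3))
  g1 <- filter_tiles(build_tile_grid(512, 512), img, 128)
  g2 <- filter_tiles(g1, img, 128)
  expect_identical(g1$tiles, g2$tiles)
})

test_that("manifests are validated", {
  m <- data.frame(slide_id = c("a", "a"), case_id = "c", label = "normal",
                  source = "s", image_uri = "x.png")
  expect_error(wsimil:::validate_manifest(m), "unique")
  m2 <- data.frame(slide_id = c("a", "b"), case_id = "c",
                   label = c("normal", "weird"), source = "s",
                   image_uri = "x.png")
  expect_error(wsimil:::validate_manifest(m2), "normal")
})
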