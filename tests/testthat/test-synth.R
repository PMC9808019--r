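# Small cohorts keep these tests quick; texture and contrast parameters stay
# at the package defaults throughout.

small_cfg <- function(...) {
  synth_config(n_normal = 2L, n_positive = 2L, n_cases = 2L, n_sources = 2L,
               slide_size = 512L, seed = 7L, ...)
}

test_that("dataset generation is deterministic per seed, byte for byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_dataset(small_cfg(), d1)
  m2 <- generate_dataset(small_cfg(), d2)
  f1 <- list.files(d1)
  expect_setequal(f1, list.files(d2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # and the generator does not disturb the caller's RNG stream
  set.seed(1)
  before <- stats::runif(1)
  set.seed(1)
  invisible(generate_dataset(small_cfg(), withr::local_tempdir()))
  expect_identical(stats::runif(1), before)
})

test_that("manifest structure matches the configuration exactly", {
  d <- withr::local_tempdir()
  cfg <- synth_config(n_normal = 3L, n_positive = 2L, n_cases = 3L,
                      n_sources = 2L, slide_size = 512L, seed = 9L)
  m <- generate_dataset(cfg, d)
  expect_equal(nrow(m), 5L)
  expect_equal(sum(m$label == "normal"), 3L)
  expect_equal(sum(m$label == "coeliac"), 2L)
  expect_equal(length(unique(m$case_id)), 3L)
  expect_setequal(unique(m$source), c("scanner_1", "scanner_2"))
  # a case never mixes labels
  expect_true(all(tapply(m$label, m$case_id,
                         function(x) length(unique(x))) == 1))
  expect_true(all(file.exists(m$image_uri)))
  expect_true(all(file.exists(m$mask_uri)))
  # the CSV on disk re-validates through the manifest reader
  m_csv <- read_manifest(file.path(d, "manifest.csv"), base_dir = d)
  expect_equal(m_csv$slide_id, m$slide_id)
})

test_that("slides respect label-conditional masks and rendering invariants", {
  cfg <- small_cfg()
  set.seed(3)
  s_norm <- generate_slide("normal", cfg)
  expect_equal(sum(s_norm$lesion_mask), 0)
  set.seed(3)
  s_pos <- generate_slide("coeliac", cfg, tissue_fraction = 0.45,
                          lesion_fraction = 0.3)
  frac <- sum(s_pos$lesion_mask) / sum(s_pos$tissue_mask)
  expect_equal(frac, 0.3, tolerance = 0.02)
  expect_true(all(s_pos$lesion_mask <= s_pos$tissue_mask))
  # valid 8-bit pixels; background bright, tissue clearly darker
  expect_true(all(s_pos$image >= 0 & s_pos$image <= 255))
  expect_true(all(s_pos$image == round(s_pos$image)))
  lum <- luminance(s_pos$image)
  expect_gte(mean(lum[s_pos$tissue_mask == 0]), 240)
  expect_lt(mean(lum[s_pos$tissue_mask == 1]), 150)
})

test_that("lesion fractions stay within the configured range across slides", {
  d <- withr::local_tempdir()
  m <- generate_dataset(small_cfg(), d)
  cfg <- small_cfg()
  for (i in which(m$label == "coeliac")) {
    mask <- read_image(m$mask_uri[i])[, , 1] / 255
    img <- read_image(m$image_uri[i])
    lum <- luminance(img)
    tissue_area <- sum(lum < 200) # conservative tissue proxy
    frac <- sum(mask) / tissue_area
    expect_gte(frac, cfg$lesion_fraction_range[1] * 0.8)
    expect_lte(frac, cfg$lesion_fraction_range[2] * 1.2)
  }
})

test_that("a hand-crafted statistic separates lesion from normal tiles", {
  d <- withr::local_tempdir()
  cfg <- synth_config(n_normal = 3L, n_positive = 3L, n_cases = 3L,
                      slide_size = 1024L, seed = 17L)
  m <- generate_dataset(cfg, d)
  sep <- separability_check(m)
  expect_gte(sep$auc, 0.9)
  expect_gt(sep$n_lesion, 5)

  # with the lesion contrast switched off the statistic is uninformative
  cfg0 <- synth_config(n_normal = 3L, n_positive = 3L, n_cases = 3L,
                       slide_size = 1024L, seed = 17L,
                       lesion_h_boost = 0, dot_amplitude = 0)
  d0 <- withr::local_tempdir()
  m0 <- generate_dataset(cfg0, d0)
  sep0 <- separability_check(m0)
  expect_lt(abs(sep0$auc - 0.5), 0.2)

  # doubling the dot density cannot weaken the signal
  cfg2 <- synth_config(n_normal = 3L, n_positive = 3L, n_cases = 3L,
                       slide_size = 1024L, seed = 17L,
                       dot_density = cfg$dot_density * 2)
  d2 <- withr::local_tempdir()
  m2 <- generate_dataset(cfg2, d2)
  expect_gte(separability_check(m2)$auc, sep$auc - 0.02)
})
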