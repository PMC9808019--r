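#' Tile, normalise and preprocess one slide for the classifier
#'
#' Runs the full per-slide preprocessing: sliding-window tiling with
#' Otsu-based background rejection, per-patch Macenko normalisation into
#' the reference stain basis, and downsampling to the backbone input size.
#' Tiles whose stain profile cannot be estimated (e.g. almost no stained
#' tissue above the OD cutoff) fall back to the unnormalised patch with a
#' warning counter in the result.
#'
#' @param image RGB slide array (0--255) at working resolution.
#' @param size,stride,max_bg Tiling parameters.
#' @param reference Reference `stain_profile` for normalisation; `NULL`
#'   skips stain normalisation.
#' @param stain_config A [stain_norm_config()].
#' @param stain_mode Where the source stain profile comes from: estimated
#'   per patch (default, the full Macenko treatment), once per slide from a
#'   pixel subsample, or the fixed reference basis (no estimation).
#' @param stain_rescale Apply the per-stain robust-maximum concentration
#'   rescale (the Macenko default). Per-slide quantities leak slide-level
#'   information into tiles; see the methods vignette before combining
#'   `stain_mode = "slide"` with localisation claims.
#' @param input_size Backbone input side length.
#' @param mask Optional ground-truth lesion mask (matrix) for annotating
#'   per-tile lesion fractions.
#' @param slide_id Optional identifier.
#' @return List with `coords` (data frame of kept tiles: `x`, `y`,
#'   `background_fraction`, and `lesion_fraction` when a mask is given),
#'   `x` (`n_kept x (input_size^2*3)` matrix of model inputs),
#'   `otsu_threshold`, `n_grid`, `n_kept`, `n_norm_failed`.
#' @export
prepare_slide_tiles <- function(image, size = 256L, stride = 128L,
                                max_bg = 0.75,
                                reference = reference_stain_profile(),
                                stain_config = stain_norm_config(),
                                stain_mode = c("patch", "slide", "reference"),
                                stain_rescale = TRUE,
                                input_size = 32L, mask = NULL,
                                slide_id = NA_character_) {
  stain_mode <- match.arg(stain_mode)
  grid <- tile_slide(image, size = size, stride = stride, max_bg = max_bg,
                     slide_id = slide_id)
  kept <- grid$tiles[which(grid$tiles$kept), , drop = FALSE]
  n_kept <- nrow(kept)
  d <- input_size^2 * 4L
  x <- matrix(NA_real_, n_kept, d)
  n_failed <- 0L
  lesion_fraction <- rep(NA_real_, n_kept)
  slide_profile <- NULL
  if (!is.null(reference) && stain_mode == "reference") {
    # unmix every tile in the fixed reference basis: nothing estimated from
    # the slide can then leak slide-level information into its tiles
    slide_profile <- reference
  }
  if (!is.null(reference) && stain_mode == "slide" && n_kept > 0L) {
    # one stain profile per slide, from a pixel subsample of the whole
    # raster: all tiles then share a common concentration scale, which
    # preserves within-slide contrast between lesional and unremarkable
    # tissue (a per-patch percentile rescale would compress exactly the
    # tiles with the strongest signal)
    step <- max(1L, floor(sqrt(length(image) / 3 / 2e5)))
    sub <- image[seq(1L, nrow(image), step), seq(1L, ncol(image), step), ,
                 drop = FALSE]
    slide_profile <- tryCatch(
      estimate_stain_profile(matrix(sub, ncol = 3L), stain_config),
      error = function(e) NULL
    )
  }
  for (j in seq_len(n_kept)) {
    patch <- extract_tile(image, kept$x[j], kept$y[j], size)
    if (!is.null(reference)) {
      x[j, ] <- tryCatch(
        as.vector(normalized_tile_planes(patch, reference, stain_config,
                                         input_size,
                                         profile = slide_profile,
                                         rescale = stain_rescale)),
        error = function(e) {
          n_failed <<- n_failed + 1L
          as.vector(preprocess_patch(patch, input_size))
        }
      )
    } else {
      x[j, ] <- as.vector(preprocess_patch(patch, input_size))
    }
    if (!is.null(mask)) {
      lesion_fraction[j] <- mean(mask[(kept$y[j] + 1L):(kept$y[j] + size),
                                      (kept$x[j] + 1L):(kept$x[j] + size)])
    }
  }
  coords <- kept[, c("x", "y", "background_fraction")]
  rownames(coords) <- NULL
  if (!is.null(mask)) coords$lesion_fraction <- lesion_fraction
  list(coords = coords, x = x, otsu_threshold = grid$otsu_threshold,
       n_grid = nrow(grid$tiles), n_kept = n_kept, n_norm_failed = n_failed)
}

#' Case-grouped cross-validated MIL experiment
#'
#' The full study loop: every slide is tiled, stain-normalised and cached
#' once; cases are split into `k` stratified, case-disjoint folds; for each
#' fold a fresh compact CNN is trained with top-k MIL on the other folds'
#' slides and applied to every kept tile of the held-out slides; slide
#' scores are the per-head means of the tile probabilities. Decision
#' thresholds for the two heads are then selected at the
#' sensitivity = specificity balance point averaged over folds (on the
#' pooled out-of-fold scores), and per-class metrics, pooled ROC AUCs and a
#' lesion-localisation summary are reported.
#'
#' @param manifest Manifest data frame (see [read_manifest()]); `mask_uri`,
#'   when present, enables the localisation summary.
#' @param k Number of folds.
#' @param config A [train_config()]; its `seed` drives fold assignment,
#'   model initialisation and bag sampling.
#' @param input_size,channels Backbone settings (see [tiny_cnn()]).
#' @param size,stride,max_bg Tiling parameters.
#' @param lesion_overlap Mask-fraction cut splitting held-out tiles into
#'   the lesion group (fraction strictly above) and the non-lesion group
#'   (at or below); the default 0 counts any mask overlap as lesional.
#' @param progress Print per-fold progress.
#' @return List with `slide_scores` (data frame: slide, case, label, fold,
#'   per-head means, decisions), `thresholds` (`threshold_pair`),
#'   `metrics` (per-class `metrics_report`s), `auc` (pooled per-head ROC
#'   AUCs), `localisation` (per-positive-slide lesion vs non-lesion mean
#'   predictions and the success rate), `folds`, `loss_logs`.
#' @export
run_mil_experiment <- function(manifest, k = 5L, config = train_config(),
                               input_size = 32L,
                               channels = c(8L, 16L, 32L, 128L),
                               size = 256L, stride = 128L, max_bg = 0.75,
                               lesion_overlap = 0, progress = FALSE) {
  validate_manifest(manifest)
  n_slides <- nrow(manifest)

  # --- per-slide preprocessing (shared across folds) ---
  tiles <- vector("list", n_slides)
  coords <- vector("list", n_slides)
  names(tiles) <- manifest$slide_id
  names(coords) <- manifest$slide_id
  for (i in seq_len(n_slides)) {
    image <- read_image(manifest$image_uri[i])
    mask <- NULL
    if (!is.null(manifest$mask_uri) && nzchar(manifest$mask_uri[i]) &&
        file.exists(manifest$mask_uri[i])) {
      mask <- read_image(manifest$mask_uri[i])[, , 1] / 255
    }
    prep <- prepare_slide_tiles(image, size = size, stride = stride,
                                max_bg = max_bg, input_size = input_size,
                                mask = mask, slide_id = manifest$slide_id[i])
    tiles[[i]] <- prep$x
    coords[[i]] <- prep$coords
    if (progress) {
      message(sprintf("prepared %s: %d/%d tiles kept", manifest$slide_id[i],
                      prep$n_kept, prep$n_grid))
    }
  }

  set.seed(config$seed)
  folds <- make_folds(manifest, k = k)
  slide_fold <- folds$folds[manifest$case_id]

  labels <- manifest$label
  names(labels) <- manifest$slide_id

  scores <- data.frame(
    slide_id = manifest$slide_id, case_id = manifest$case_id,
    label = labels, fold = as.integer(slide_fold),
    mean_normal = NA_real_, mean_coeliac = NA_real_,
    n_tiles = vapply(tiles, nrow, 1L), stringsAsFactors = FALSE,
    row.names = NULL
  )
  tile_preds <- vector("list", n_slides)
  names(tile_preds) <- manifest$slide_id
  loss_logs <- vector("list", k)

  for (f in seq_len(k)) {
    train_idx <- which(slide_fold != f & scores$n_tiles > 0L)
    test_idx <- which(slide_fold == f)
    fold_seed <- config$seed + 7919L * f
    fold_config <- config
    fold_config$seed <- fold_seed
    # identical backbone initialisation across folds: fold models then differ
    # only through the data they saw, keeping out-of-fold scores comparable
    set.seed(config$seed)
    model <- tiny_cnn(input_size = input_size, channels = channels)
    fit <- mil_train(tiles[train_idx], labels[train_idx], model, fold_config)
    loss_logs[[f]] <- fit$loss_log
    for (i in test_idx) {
      if (scores$n_tiles[i] == 0L) next
      preds <- predict_tiles(fit$model, tiles[[i]])
      tile_preds[[i]] <- preds
      sc <- slide_score(preds, slide_id = manifest$slide_id[i])
      scores$mean_normal[i] <- sc$mean_normal
      scores$mean_coeliac[i] <- sc$mean_coeliac
    }
    if (progress) {
      message(sprintf("fold %d/%d: trained on %d slides, scored %d", f, k,
                      length(train_idx), length(test_idx)))
    }
  }

  ok <- !is.na(scores$mean_coeliac)
  is_norm <- scores$label == "normal"
  is_coel <- scores$label == "coeliac"
  t_normal <- select_threshold(scores$mean_normal[ok], is_norm[ok],
                               folds = scores$fold[ok])
  t_coeliac <- select_threshold(scores$mean_coeliac[ok], is_coel[ok],
                                folds = scores$fold[ok])
  thresholds <- threshold_pair(clamp01(t_normal), clamp01(t_coeliac))

  scores$normal_positive <- scores$mean_normal > thresholds$t_normal
  scores$coeliac_positive <- scores$mean_coeliac > thresholds$t_coeliac
  scores$discordant <- scores$normal_positive == scores$coeliac_positive

  metrics <- list(
    normal = compute_metrics(scores$normal_positive[ok], is_norm[ok],
                             scores$mean_normal[ok]),
    coeliac = compute_metrics(scores$coeliac_positive[ok], is_coel[ok],
                              scores$mean_coeliac[ok])
  )
  auc <- c(normal = metrics$normal$roc_auc, coeliac = metrics$coeliac$roc_auc)

  localisation <- NULL
  if (!is.null(manifest$mask_uri)) {
    loc_rows <- list()
    for (i in which(is_coel & ok)) {
      cc <- coords[[i]]
      if (is.null(cc$lesion_fraction) || is.null(tile_preds[[i]])) next
      # lesion tiles overlap the ground-truth mask (beyond lesion_overlap,
      # 0 by default: any overlap counts); non-lesion tiles do not
      lesion_t <- cc$lesion_fraction > lesion_overlap
      clean_t <- cc$lesion_fraction <= lesion_overlap
      # both groups need enough tiles for their means to be a measurement
      if (sum(lesion_t) < 3L || sum(clean_t) < 3L) next
      p <- tile_preds[[i]][, "coeliac"]
      loc_rows[[length(loc_rows) + 1L]] <- data.frame(
        slide_id = manifest$slide_id[i],
        mean_lesion = mean(p[lesion_t]), mean_other = mean(p[clean_t]),
        n_lesion_tiles = sum(lesion_t), n_other_tiles = sum(clean_t),
        stringsAsFactors = FALSE
      )
    }
    if (length(loc_rows)) {
      loc <- do.call(rbind, loc_rows)
      localisation <- list(
        slides = loc,
        success_rate = mean(loc$mean_lesion > loc$mean_other)
      )
    }
  }

  list(slide_scores = scores, thresholds = thresholds, metrics = metrics,
       auc = auc, localisation = localisation, folds = folds,
       loss_logs = loss_logs, tile_preds = tile_preds, coords = coords)
}

clamp01 <- function(x, eps = 1e-6) min(max(x, eps), 1 - eps)

# Fused Macenko normalisation + backbone preprocessing for one tile:
# identical maths to preprocess_patch(normalize_patch(patch)) but without
# the intermediate 8-bit RGB rendering round-trip (one OD conversion
# instead of three, and no quantisation step).
normalized_tile_planes <- function(patch, reference, stain_config,
                                   input_size, profile = NULL,
                                   rescale = FALSE) {
  od <- as_od_matrix(patch, stain_config$io_white)
  src <- if (is.null(profile)) {
    estimate_profile_from_od(od, stain_config)
  } else {
    profile
  }
  conc <- od_to_concentrations(od, src$stain_matrix)
  if (rescale) {
    # full Macenko rescale, as in normalize_patch(); off by default in the
    # pipeline: the robust concentration maximum is itself a function of
    # local disease burden, so dividing by it suppresses exactly the
    # strongest-signal tiles and degrades patch-level localisation,
    # while unmixing in the estimated basis already removes the
    # scanner's stain-vector rotation
    scale <- reference$max_concentrations / pmax(src$max_concentrations, 1e-8)
    conc <- sweep(conc, 2, scale, "*")
  }
  od_ref <- conc %*% t(reference$stain_matrix)
  build_planes(conc, sqrt(rowSums(od_ref^2)), dim(patch)[1:2],
               dim(patch)[1] %/% input_size)
}
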