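#' MIL training configuration
#'
#' The weakly supervised training recipe: bags of `bag_size` patches sampled
#' with replacement from each slide, `alpha` "least normal" patches of a
#' positive slide labelled coeliac and `beta` "most normal" patches labelled
#' normal (all other patches masked out of the loss), trained with Adam.
#' Defaults: 10 epochs, bag size 100, `alpha = 10`, `beta = 0`, learning
#' rate and weight decay both `1e-4`.
#'
#' @param epochs Number of passes over the slides.
#' @param bag_size Patches per bag.
#' @param alpha Count of least-normal patches labelled positive on a
#'   positive slide.
#' @param beta Count of most-normal patches labelled negative on a positive
#'   slide.
#' @param learning_rate,weight_decay Adam settings (other optimiser
#'   parameters stay at their conventional defaults).
#' @param seed Seed driving slide order and bag sampling.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 10L, bag_size = 100L, alpha = 10L,
                         beta = 0L, learning_rate = 1e-4,
                         weight_decay = 1e-4, seed = 1L) {
  stopifnot(alpha >= 1L, beta >= 0L, alpha + beta <= bag_size, epochs >= 0L,
            bag_size >= 1L, learning_rate > 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), bag_size = as.integer(bag_size),
                 alpha = as.integer(alpha), beta = as.integer(beta),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Sample a bag of patches from a slide
#'
#' `bag_size` independent uniform draws *with replacement* from the slide's
#' kept tiles, using R's RNG (reproducible under `set.seed()`).
#'
#' @param kept_tiles Vector of tile indices (or a single integer count,
#'   interpreted as `1:n`).
#' @param bag_size Number of draws.
#' @param slide_id Optional identifier carried on the bag.
#' @return An object of class `bag`: list with `slide_id`, `patch_refs`
#'   (length `bag_size`, duplicates allowed) and `bag_size`.
#' @export
sample_bag <- function(kept_tiles, bag_size = 100L, slide_id = NA_character_) {
  n <- if (length(kept_tiles) == 1L && is.numeric(kept_tiles)) {
    as.integer(kept_tiles)
  } else {
    length(kept_tiles)
  }
  if (n < 1L) stop("slide has no tissue tiles")
  idx <- sample.int(n, size = bag_size, replace = TRUE)
  refs <- if (length(kept_tiles) == 1L && is.numeric(kept_tiles)) {
    idx
  } else {
    kept_tiles[idx]
  }
  structure(list(slide_id = slide_id, patch_refs = refs,
                 bag_size = as.integer(bag_size)),
            class = "bag")
}

#' Assign proxy labels within a bag
#'
#' For a negative (normal) slide every patch receives the label `(1, 0)`
#' (normal, coeliac) with an active mask. For a positive slide, patches are
#' ranked by "normality" (the normal-head probability, ascending): the
#' `alpha` least-normal patches receive `(0, 1)`, the `beta` most-normal
#' receive `(1, 0)`, and every other patch is masked so it contributes no
#' gradient. Ties are broken by ascending bag index, so the assignment is
#' deterministic.
#'
#' @param predictions `bag_size x 2` matrix of per-patch probabilities
#'   (columns: normal, coeliac).
#' @param slide_label `"normal"` or `"coeliac"`.
#' @param alpha,beta Top-k counts (see [train_config()]).
#' @return An object of class `proxy_label_set`: list with `labels`
#'   (`bag_size x 2` 0/1 matrix) and `mask` (0/1 vector).
#' @export
assign_proxy_labels <- function(predictions, slide_label, alpha = 10L,
                                beta = 0L) {
  stopifnot(is.matrix(predictions), ncol(predictions) == 2L)
  b <- nrow(predictions)
  if (alpha + beta > b) stop("alpha + beta must not exceed the bag size")
  labels <- matrix(0, b, 2L, dimnames = list(NULL, c("normal", "coeliac")))
  mask <- integer(b)
  if (slide_label == "normal") {
    labels[, 1L] <- 1
    mask[] <- 1L
  } else if (slide_label == "coeliac") {
    ord <- order(predictions[, 1L]) # stable: ties by ascending bag index
    pos <- ord[seq_len(alpha)]
    labels[pos, 2L] <- 1
    mask[pos] <- 1L
    if (beta > 0L) {
      neg <- ord[seq.int(b - beta + 1L, b)]
      labels[neg, 1L] <- 1
      mask[neg] <- 1L
    }
  } else {
    stop("slide_label must be 'normal' or 'coeliac'")
  }
  structure(list(labels = labels, mask = mask), class = "proxy_label_set")
}

#' Masked binary cross-entropy over a bag
#'
#' Mean of the elementwise sigmoid binary cross-entropy over the *active*
#' rows only; masked rows are excluded from the mean, so their gradient is
#' exactly zero. Computed from logits in the numerically stable form
#' `max(z, 0) - z y + log(1 + exp(-|z|))`.
#'
#' @param logits `bag_size x 2` matrix of head logits.
#' @param proxy A [assign_proxy_labels()] result.
#' @return List with `loss` (scalar, non-negative) and `grad`
#'   (`bag_size x 2` gradient of the loss w.r.t. the logits; exactly zero on
#'   masked rows).
#' @export
masked_bce_loss <- function(logits, proxy) {
  stopifnot(is.matrix(logits), all(dim(logits) == dim(proxy$labels)))
  active <- proxy$mask == 1L
  n_active <- sum(active)
  if (n_active == 0L) stop("no active labels in the proxy label set")
  z <- logits[active, , drop = FALSE]
  y <- proxy$labels[active, , drop = FALSE]
  elem <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))
  denom <- 2 * n_active # two head entries per active patch
  grad <- matrix(0, nrow(logits), 2L)
  grad[active, ] <- (sigmoid(z) - y) / denom
  list(loss = sum(elem) / denom, grad = grad)
}

#' Train a patch classifier with top-k MIL
#'
#' One training epoch visits every slide in (seeded) random order; at each
#' visit a fresh bag is sampled with replacement from the slide's kept
#' tiles, the classifier infers on the bag, proxy labels are assigned from
#' the slide label and the patch ranking, and one Adam step is taken on the
#' masked binary cross-entropy. Slides with no kept tiles are skipped with a
#' warning.
#'
#' @param tiles Named list: one `n_tiles x D` matrix of preprocessed patch
#'   inputs per slide (see [preprocess_patch()]; rows are flattened model
#'   inputs).
#' @param labels Named character vector (`"normal"`/`"coeliac"`) aligned
#'   with `tiles`.
#' @param model A `patch_classifier` (e.g. [tiny_cnn()]).
#' @param config A [train_config()].
#' @return List with `model` (trained, same object surface) and `loss_log`,
#'   a data frame with one row per slide visit (`epoch`, `slide_id`,
#'   `loss`).
#' @export
mil_train <- function(tiles, labels, model, config = train_config()) {
  stopifnot(length(tiles) >= 1L, length(labels) == length(tiles))
  if (is.null(names(tiles))) names(tiles) <- paste0("slide_", seq_along(tiles))
  labels <- as.character(labels)
  names(labels) <- names(tiles)
  if (length(unique(labels)) < 2L) {
    stop("training data must contain both classes")
  }
  empty <- vapply(tiles, nrow, 1L) == 0L
  if (any(empty)) {
    warning("skipping slides with no tissue tiles: ",
            paste(names(tiles)[empty], collapse = ", "))
    tiles <- tiles[!empty]
    labels <- labels[!empty]
    if (length(unique(labels)) < 2L) {
      stop("training data must contain both classes")
    }
  }
  set.seed(config$seed)
  state <- adam_init(model$params())
  log_epoch <- integer(0)
  log_slide <- character(0)
  log_loss <- numeric(0)
  slide_ids <- names(tiles)
  for (ep in seq_len(config$epochs)) {
    for (sid in sample(slide_ids)) {
      bag <- sample_bag(nrow(tiles[[sid]]), config$bag_size, slide_id = sid)
      x <- tiles[[sid]][bag$patch_refs, , drop = FALSE]
      logits <- model$forward(x, cache = TRUE)
      probs <- sigmoid(logits)
      proxy <- assign_proxy_labels(probs, labels[[sid]],
                                   alpha = config$alpha, beta = config$beta)
      lb <- masked_bce_loss(logits, proxy)
      grads <- model$backward(lb$grad)
      step <- adam_step(model$params(), grads, state,
                        lr = config$learning_rate,
                        weight_decay = config$weight_decay)
      model$set_params(step$params)
      state <- step$state
      log_epoch <- c(log_epoch, ep)
      log_slide <- c(log_slide, sid)
      log_loss <- c(log_loss, lb$loss)
    }
  }
  list(model = model,
       loss_log = data.frame(epoch = log_epoch, slide_id = log_slide,
                             loss = log_loss, stringsAsFactors = FALSE))
}

#' Predict class probabilities for every kept tile of a slide
#'
#' Pure inference on all kept tiles (no sampling), in tile-index order.
#'
#' @param model A trained `patch_classifier`.
#' @param tiles `n_tiles x D` matrix of preprocessed patch inputs.
#' @param batch_size Forward-pass batch size.
#' @return `n_tiles x 2` matrix of probabilities in `(0, 1)` (columns:
#'   normal, coeliac).
#' @export
predict_tiles <- function(model, tiles, batch_size = 256L) {
  if (!is.matrix(tiles) || nrow(tiles) == 0L) {
    stop("slide has no kept tiles to predict on")
  }
  n <- nrow(tiles)
  out <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("normal", "coeliac")))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- sigmoid(model$forward(tiles[idx, , drop = FALSE]))
  }
  out
}
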