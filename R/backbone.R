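#' Compact CNN patch classifier
#'
#' The default backbone behind the patch-classifier contract: four 3x3
#' convolution blocks (ReLU, 2x2 max pooling after the first three), global
#' average pooling and a linear layer with two independent output heads
#' (normal, coeliac). Patches enter at a reduced working size (default
#' 32x32, produced by [preprocess_patch()]) so that CPU training over
#' thousands of bags completes in minutes. Weights use He initialisation
#' drawn from R's RNG, so construction is reproducible under `set.seed()`.
#'
#' The returned object satisfies the contract the MIL trainer needs: a
#' `forward()` pass over a batch, a `backward()` pass returning parameter
#' gradients, and flat get/set access to the trainable parameters. Any
#' object with the same surface (e.g. an adapter around a large pretrained
#' network) can be substituted.
#'
#' @param input_size Side length of the (downsampled) input, a multiple of 8.
#' @param channels Integer vector of output channels for the four blocks.
#' @param in_channels Number of input channels.
#' @return An object of class `patch_classifier`; see Details.
#' @details Fields:
#' \describe{
#'   \item{`forward(x, cache = FALSE)`}{`x` is an `n x (input_size^2 * 3)`
#'     matrix of flattened (column-major `H x W x C`) inputs; returns an
#'     `n x 2` matrix of logits. With `cache = TRUE` intermediate
#'     activations are retained for `backward()`.}
#'   \item{`backward(dlogits)`}{gradients of the loss w.r.t. all parameters,
#'     as a list mirroring `params()`.}
#'   \item{`params()` / `set_params(p)`}{trainable-parameter access.}
#' }
#' @export
tiny_cnn <- function(input_size = 32L, channels = c(8L, 16L, 32L, 128L),
                     in_channels = 4L) {
  stopifnot(length(channels) == 4L, input_size %% 8L == 0L)
  pool <- c(TRUE, TRUE, TRUE, FALSE)
  cins <- c(in_channels, channels[-length(channels)])
  he <- function(n_in, nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / n_in)), nr, nc)
  }
  conv_w <- lapply(seq_along(channels), function(l) {
    he(9L * cins[l], 9L * cins[l], channels[l])
  })
  conv_b <- lapply(channels, function(co) numeric(co))
  # zero-initialised head: logits start at zero and grow along the learned
  # direction only, instead of being buried under a frozen random
  # projection of the features
  fc_w <- matrix(0, channels[4L], 2L)
  fc_b <- numeric(2L)

  env <- new.env(parent = emptyenv())
  env$params <- list(conv_w = conv_w, conv_b = conv_b, fc_w = fc_w, fc_b = fc_b)
  env$pool <- pool
  env$cache <- NULL
  eps2 <- 1e-8
  nc4 <- channels[4L]

  obj <- list(
    input_size = as.integer(input_size),
    in_channels = as.integer(in_channels),
    channels = as.integer(channels),
    forward = function(x, cache = FALSE) {
      stopifnot(is.matrix(x), ncol(x) == input_size^2 * in_channels)
      xc <- array(t(x), c(input_size, input_size, in_channels * nrow(x)))
      out <- cnn_forward_cpp(xc, env$params$conv_w, env$params$conv_b,
                             env$pool, in_channels, cache)
      feats <- out$feats
      # layer-normalised embedding (per-sample mean/sd across feature
      # coordinates, no affine): removes the common activation level so
      # head updates go entirely into the discriminative pattern, and
      # keeps scores comparable across tiles, slides and fold models
      mu <- rowMeans(feats)
      cf <- feats - mu
      sdv <- sqrt(rowMeans(cf^2) + eps2)
      fhat <- cf / sdv
      logits <- fhat %*% env$params$fc_w
      logits <- sweep(logits, 2, env$params$fc_b, "+")
      if (cache) {
        env$cache <- list(cpp = out$cache, cf = cf, sdv = sdv, fhat = fhat)
      } else {
        env$cache <- NULL
      }
      logits
    },
    backward = function(dlogits) {
      if (is.null(env$cache)) {
        stop("backward() requires a preceding forward(cache = TRUE)")
      }
      cc <- env$cache
      d_fc_w <- t(cc$fhat) %*% dlogits
      d_fc_b <- colSums(dlogits)
      dfhat <- dlogits %*% t(env$params$fc_w)
      # Jacobian of the layer normalisation f -> (f - mean(f)) / sd(f)
      dcf <- dfhat / cc$sdv -
        cc$cf * (rowSums(dfhat * cc$cf) / (nc4 * cc$sdv^3))
      dfeats <- dcf - rowMeans(dcf)
      g <- cnn_backward_cpp(env$params$conv_w, env$pool, cc$cpp, dfeats)
      list(conv_w = g$conv_w, conv_b = g$conv_b, fc_w = d_fc_w, fc_b = d_fc_b)
    },
    params = function() env$params,
    set_params = function(p) {
      env$params <- p
      invisible(NULL)
    }
  )
  class(obj) <- "patch_classifier"
  obj
}

#' Preprocess a patch for the compact backbone
#'
#' Maps a stain-normalised RGB patch to the four planes the backbone
#' consumes: haematoxylin concentration, eosin concentration (both unmixed
#' in the reference stain basis), optical-density magnitude, and local
#' haematoxylin texture energy -- the per-block standard deviation of the
#' haematoxylin concentration at full resolution, which preserves nuclear
#' crowding (e.g. dense lymphocyte infiltrates) that block-mean
#' downsampling would otherwise erase. All planes are ~0 on background and
#' carry a fixed gain so stained tissue sits at order one.
#'
#' @param patch RGB array on the 0--255 scale; side length must be a
#'   multiple of `input_size`.
#' @param input_size Backbone input side length.
#' @param reference `stain_profile` whose basis is used for unmixing.
#' @return Numeric array `input_size x input_size x 4`.
#' @export
preprocess_patch <- function(patch, input_size = 32L,
                             reference = reference_stain_profile()) {
  f <- dim(patch)[1] %/% input_size
  stopifnot(dim(patch)[1] == f * input_size, dim(patch)[2] == f * input_size)
  od <- as_od_matrix(patch)
  conc <- od_to_concentrations(od, reference$stain_matrix)
  build_planes(conc, sqrt(rowSums(od^2)), dim(patch)[1:2], f)
}

# Assemble the four input planes from per-pixel concentrations and OD
# magnitude. The gain of 12 puts stained tissue at order one-to-several:
# with a slow, short training schedule the head's attainable logit swing
# scales with feature magnitude, and this gain lets the heads reach
# saturation within the ten-epoch recipe.
build_planes <- function(conc, od_mag, hw, f) {
  gain <- 12
  ch <- matrix(conc[, 1L], hw[1], hw[2])
  base <- array(c(conc[, 1L], conc[, 2L], od_mag), c(hw, 3L))
  if (f > 1L) {
    m <- block_mean_downsample(base, f)
    # texture plane: sqrt(E[x^2] - E[x]^2) of haematoxylin per block
    msq <- block_mean_downsample(array(ch^2, c(hw, 1L)), f)
    tex <- sqrt(pmax(msq[, , 1L] - m[, , 1L]^2, 0))
  } else {
    m <- base
    tex <- matrix(0, hw[1], hw[2])
  }
  gain * array(c(m, tex), c(dim(m)[1:2], 4L))
}

#' Elementwise logistic sigmoid
#' @param x Numeric.
#' @return Values in `(0, 1)`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- Adam optimiser over nested parameter lists -------------------------

# Apply a binary function elementwise over two parallel nested lists.
map_params <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(function(x, y) map_params(f, x, y), a, b, SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

#' Adam optimiser state
#'
#' @param params Nested list of parameter arrays (as returned by a
#'   `patch_classifier`'s `params()`).
#' @return An `adam_state` list (first/second moments and step counter).
#' @export
adam_init <- function(params) {
  structure(list(m = zero_like(params), v = zero_like(params), t = 0L),
            class = "adam_state")
}

#' One Adam update
#'
#' Standard Adam with L2 weight decay added to the gradient (the
#' conventional `weight_decay` behaviour of the optimiser's reference
#' implementation); `beta1 = 0.9`, `beta2 = 0.999`, `eps = 1e-8` defaults.
#'
#' @param params,grads Parallel nested lists.
#' @param state An `adam_state`.
#' @param lr Learning rate.
#' @param weight_decay L2 penalty coefficient.
#' @param beta1,beta2,eps Adam moment constants.
#' @return List with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr = 1e-4, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0) {
    grads <- map_params(function(g, p) g + weight_decay * p, grads, params)
  }
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g,
                        state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2,
                        state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- map_params(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                    state$m, state$v)
  params <- map_params(`-`, params, upd)
  list(params = params, state = state)
}

#' Save / load a trained patch classifier
#'
#' The checkpoint is a JSON file holding the flattened weights plus an
#' architecture sidecar, so checkpoints are portable text.
#'
#' @param model A `patch_classifier`.
#' @param path Checkpoint path (`.json`).
#' @param config Optional [train_config()] stored alongside the weights.
#' @return `save_model()` returns `path` invisibly; `load_model()` a
#'   `patch_classifier`.
#' @export
save_model <- function(model, path, config = NULL) {
  p <- model$params()
  payload <- list(
    arch = list(input_size = model$input_size, channels = model$channels,
                in_channels = model$in_channels),
    conv_w = lapply(p$conv_w, as.numeric),
    conv_b = lapply(p$conv_b, as.numeric),
    fc_w = as.numeric(p$fc_w),
    fc_b = as.numeric(p$fc_b),
    train_config = if (is.null(config)) NULL else unclass(config)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- tiny_cnn(input_size = x$arch$input_size,
                    channels = as.integer(x$arch$channels),
                    in_channels = x$arch$in_channels)
  p <- model$params()
  cins <- c(model$in_channels, model$channels[-4L])
  p$conv_w <- lapply(seq_len(4L), function(l) {
    matrix(as.numeric(x$conv_w[[l]]), 9L * cins[l], model$channels[l])
  })
  p$conv_b <- lapply(x$conv_b, as.numeric)
  p$fc_w <- matrix(as.numeric(x$fc_w), length(as.numeric(x$fc_w)) %/% 2L, 2L)
  p$fc_b <- as.numeric(x$fc_b)
  model$set_params(p)
  model
}
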