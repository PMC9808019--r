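test_that("bag sampling draws with replacement, reproducibly", {
  set.seed(1)
  b <- sample_bag(1L, 100L)
  expect_equal(b$patch_refs, rep(1L, 100))
  set.seed(2)
  b1 <- sample_bag(1000L, 100L)
  set.seed(2)
  b2 <- sample_bag(1000L, 100L)
  expect_identical(b1$patch_refs, b2$patch_refs)
  expect_error(sample_bag(0L, 10L), "no tissue tiles")
  # empirical frequencies within 3 sigma of the binomial expectation
  set.seed(3)
  big <- sample_bag(5L, 10000L)
  freq <- tabulate(big$patch_refs, 5) / 10000
  sigma <- sqrt(0.2 * 0.8 / 10000)
  expect_true(all(abs(freq - 0.2) < 3 * sigma))
})

test_that("proxy labels follow the top-k rule with index tie-breaks", {
  # negative slide: every patch labelled normal and active
  preds <- matrix(stats::runif(200), 100, 2)
  pl <- assign_proxy_labels(preds, "normal", alpha = 10, beta = 0)
  expect_true(all(pl$labels[, 1] == 1) && all(pl$labels[, 2] == 0))
  expect_equal(sum(pl$mask), 100)

  # positive slide: exactly alpha coeliac labels at the lowest normal scores
  set.seed(8)
  preds <- cbind(stats::runif(100), stats::runif(100))
  pl <- assign_proxy_labels(preds, "coeliac", alpha = 10, beta = 0)
  expect_equal(sum(pl$labels[, 2] == 1 & pl$mask == 1), 10)
  expect_equal(sum(pl$mask), 10)
  expect_setequal(which(pl$labels[, 2] == 1), order(preds[, 1])[1:10])

  # worked 4-patch example with a tie on the normal scores
  preds4 <- cbind(c(0.9, 0.1, 0.1, 0.8), c(0.2, 0.9, 0.8, 0.3))
  pl4 <- assign_proxy_labels(preds4, "coeliac", alpha = 2, beta = 1)
  expect_equal(which(pl4$labels[, 2] == 1), c(2L, 3L))
  expect_equal(which(pl4$labels[, 1] == 1), 1L)
  expect_equal(pl4$mask, c(1L, 1L, 1L, 0L))

  expect_error(assign_proxy_labels(preds4, "coeliac", alpha = 3, beta = 2),
               "exceed")
})

test_that("proxy labels agree with a brute-force sort oracle", {
  set.seed(9)
  for (i in 1:100) {
    b <- sample(5:40, 1)
    # coarse grid of values so ties are frequent
    preds <- cbind(sample(seq(0, 1, 0.1), b, TRUE), stats::runif(b))
    alpha <- sample.int(b - 1, 1)
    beta <- sample.int(b - alpha, 1) - 1L
    if (alpha < 1) next
    got <- assign_proxy_labels(preds, "coeliac", alpha, beta)
    want <- brute_force_proxy(preds, "coeliac", alpha, beta)
    expect_identical(unname(got$labels), want$labels)
    expect_identical(got$mask, want$mask)
  }
})

test_that("masked BCE matches hand-computed values and masks gradients", {
  logits <- matrix(0, 100, 2)
  pl <- assign_proxy_labels(matrix(0.5, 100, 2), "normal")
  lb <- masked_bce_loss(logits, pl)
  expect_equal(lb$loss, log(2), tolerance = 1e-12)

  # perfect large-magnitude logits: loss tends to zero
  big <- cbind(rep(30, 100), rep(-30, 100))
  expect_lt(masked_bce_loss(big, pl)$loss, 1e-10)

  # single active row equals the hand-computed BCE of that row
  logits3 <- matrix(c(0.3, -1.2, 2.0, 0.7, -0.4, 1.1), 3, 2)
  pl3 <- structure(list(labels = rbind(c(0, 1), c(1, 0), c(0, 0)),
                        mask = c(0L, 1L, 0L)), class = "proxy_label_set")
  lb3 <- masked_bce_loss(logits3, pl3)
  p <- 1 / (1 + exp(-logits3[2, ]))
  hand <- (-log(p[1]) - log(1 - p[2])) / 2
  expect_equal(lb3$loss, hand, tolerance = 1e-12)
  expect_equal(lb3$grad[c(1, 3), ], matrix(0, 2, 2))

  # all-masked bags are an error
  pl_none <- structure(list(labels = matrix(0, 3, 2), mask = rep(0L, 3)),
                       class = "proxy_label_set")
  expect_error(masked_bce_loss(logits3, pl_none), "no active labels")
})

test_that("perturbing a masked logit leaves the loss unchanged", {
  set.seed(10)
  logits <- matrix(stats::rnorm(200), 100, 2)
  preds <- sigmoid(logits)
  pl <- assign_proxy_labels(preds, "coeliac", alpha = 10, beta = 5)
  base <- masked_bce_loss(logits, pl)$loss
  masked_rows <- which(pl$mask == 0)
  for (r in sample(masked_rows, 10)) {
    pert <- logits
    pert[r, ] <- pert[r, ] + stats::rnorm(2, sd = 5)
    expect_identical(masked_bce_loss(pert, pl)$loss, base)
  }
  grad <- masked_bce_loss(logits, pl)$grad
  expect_true(all(grad[masked_rows, ] == 0))
})

make_toy_tiles <- function(n_slides, n_tiles = 30, d_side = 8L, shift = 0.5) {
  # half the slides carry a signal in channel 1 on a third of their tiles
  tiles <- list()
  labels <- character(n_slides)
  for (i in seq_len(n_slides)) {
    x <- matrix(stats::rnorm(n_tiles * d_side^2 * 4, sd = 0.3), n_tiles)
    lab <- if (i <= n_slides / 2) "normal" else "coeliac"
    if (lab == "coeliac") {
      hot <- seq_len(n_tiles %/% 3)
      x[hot, seq_len(d_side^2)] <- x[hot, seq_len(d_side^2)] + shift
    }
    tiles[[sprintf("s%02d", i)]] <- x
    labels[i] <- lab
  }
  names(labels) <- names(tiles)
  list(tiles = tiles, labels = labels)
}

test_that("training is a seeded no-op at zero epochs and reproducible", {
  toy <- make_toy_tiles(4)
  set.seed(12)
  model <- tiny_cnn(input_size = 8L, channels = c(4L, 4L, 8L, 8L))
  before <- model$params()
  fit0 <- mil_train(toy$tiles, toy$labels, model,
                    train_config(epochs = 0L, bag_size = 20L, alpha = 3L))
  expect_identical(fit0$model$params(), before)
  expect_equal(nrow(fit0$loss_log), 0L)

  run_once <- function() {
    set.seed(12)
    m <- tiny_cnn(input_size = 8L, channels = c(4L, 4L, 8L, 8L))
    mil_train(toy$tiles, toy$labels, m,
              train_config(epochs = 3L, bag_size = 20L, alpha = 3L,
                           seed = 99L))$loss_log
  }
  expect_identical(run_once(), run_once())
})

test_that("training refuses single-class data and skips empty slides", {
  toy <- make_toy_tiles(4)
  one_class <- toy$labels
  one_class[] <- "normal"
  set.seed(13)
  model <- tiny_cnn(input_size = 8L, channels = c(4L, 4L, 8L, 8L))
  expect_error(mil_train(toy$tiles, one_class, model, train_config()),
               "both classes")
  toy$tiles[["s01"]] <- toy$tiles[["s01"]][0, , drop = FALSE]
  expect_warning(
    mil_train(toy$tiles, toy$labels, model,
              train_config(epochs = 1L, bag_size = 10L, alpha = 2L)),
    "skipping"
  )
})

test_that("mean bag loss decreases over training on learnable toy data", {
  toy <- make_toy_tiles(8, shift = 1.0)
  set.seed(14)
  model <- tiny_cnn(input_size = 8L, channels = c(4L, 4L, 8L, 8L))
  fit <- mil_train(toy$tiles, toy$labels, model,
                   train_config(epochs = 10L, bag_size = 30L, alpha = 5L,
                                learning_rate = 3e-3, seed = 15L))
  ep <- tapply(fit$loss_log$loss, fit$loss_log$epoch, mean)
  expect_lt(ep[[10]], ep[[1]])
})

test_that("tile prediction is pure and shape-correct", {
  set.seed(16)
  model <- tiny_cnn(input_size = 8L, channels = c(4L, 4L, 8L, 8L))
  x <- matrix(stats::rnorm(5 * 8 * 8 * 4), 5)
  x[2, ] <- x[1, ] # duplicate pixels -> identical predictions
  p <- predict_tiles(model, x)
  expect_equal(dim(p), c(5L, 2L))
  expect_true(all(p > 0 & p < 1))
  expect_identical(p[1, ], p[2, ])
  expect_error(predict_tiles(model, x[0, , drop = FALSE]), "no kept tiles")
})
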