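test_that("slide scores are per-head arithmetic means", {
  p <- cbind(c(0.9, 0.8, 0.7), c(0.0, 0.1, 0.2))
  s <- slide_score(p, "s1")
  expect_equal(s$mean_coeliac, 0.1)
  expect_equal(s$mean_normal, 0.8)
  expect_equal(s$n_tiles, 3L)
  expect_equal(slide_score(cbind(0.4, 0.6))$mean_normal, 0.4)
  const <- slide_score(matrix(0.3, 10, 2))
  expect_equal(const$mean_coeliac, 0.3)
  expect_error(slide_score(matrix(numeric(0), 0, 2)), "no tile predictions")
})

test_that("slides are classified independently per head with strict thresholds", {
  thr <- threshold_pair() # 0.905 / 0.096
  d <- classify_slide(list(mean_normal = 0.95, mean_coeliac = 0.05), thr)
  expect_true(d$normal_positive)
  expect_false(d$coeliac_positive)
  expect_false(d$discordant)
  # boundary: exactly the threshold does not "exceed"
  d2 <- classify_slide(list(mean_normal = 0.905, mean_coeliac = 0.05), thr)
  expect_false(d2$normal_positive)
  expect_true(d2$discordant) # neither head fired
  d3 <- classify_slide(list(mean_normal = 0.95, mean_coeliac = 0.10), thr)
  expect_true(d3$normal_positive && d3$coeliac_positive)
  expect_true(d3$discordant)
})

test_that("ROC AUC is 1 for perfect separation and matches a hand example", {
  r <- roc_and_pr(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$roc_auc, 1.0)
  expect_equal(r$pr_auc, 1.0)
  # hand case with one inversion: pairs (2 pos x 2 neg), 3 of 4 correct
  r2 <- roc_and_pr(c(0.9, 0.3, 0.5, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$roc_auc, 0.75)
  expect_error(roc_and_pr(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("ROC AUC equals the Mann-Whitney statistic on random instances", {
  set.seed(23)
  for (i in 1:60) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, 0.05), n, TRUE) # ties likely
    labels <- stats::runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_and_pr(scores, labels)$roc_auc,
                 mann_whitney_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(29)
  scores <- stats::rnorm(80)
  labels <- stats::runif(80) < 0.4
  labels[1:2] <- c(TRUE, FALSE)
  ours <- roc_and_pr(scores, labels)$roc_auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(37)
  n <- 2000
  scores <- stats::runif(n)
  labels <- stats::runif(n) < 0.5
  auc <- roc_and_pr(scores, labels)$roc_auc
  n1 <- sum(labels)
  n0 <- n - n1
  sigma <- sqrt((n1 + n0 + 1) / (12 * n1 * n0)) # Mann-Whitney null sd
  expect_lt(abs(auc - 0.5), 3 * sigma)
})

test_that("threshold selection finds the balance point", {
  scores <- c(rep(0.9, 10), rep(0.1, 10))
  labels <- rep(c(TRUE, FALSE), each = 10)
  t <- select_threshold(scores, labels)
  expect_gt(t, 0.1)
  expect_lt(t, 0.9)
  # two overlapping Gaussians: balance point at the midpoint of the means
  set.seed(39)
  s <- c(stats::rnorm(4000, 1), stats::rnorm(4000, 0))
  l <- rep(c(TRUE, FALSE), each = 4000)
  expect_equal(select_threshold(s, l), 0.5, tolerance = 0.1)
  expect_error(select_threshold(rep(0.5, 10), rep(c(TRUE, FALSE), 5)),
               "degenerate")
  # literal |TPR - FPR| objective is available but picks a chance-level point
  t_lit <- select_threshold(s, l, objective = "literal")
  expect_true(t_lit < min(s) || t_lit > 0.995 * max(s))
})

test_that("folds are case-disjoint and stratified within one case", {
  # the documented example: 10 cases, 6 normal, 4 coeliac, 5 folds
  cases <- sprintf("c%02d", 1:10)
  m <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(slide_id = paste0("s", i), case_id = cases[i],
               label = if (i <= 6) "normal" else "coeliac", source = "x",
               image_uri = "none.png")
  }))
  set.seed(41)
  fa <- make_folds(m, k = 5)
  counts <- table(factor(fa$folds, levels = 1:5),
                  m$label[match(names(fa$folds), m$case_id)])
  expect_true(all(rowSums(counts) == 2))
  expect_true(all(counts[, "coeliac"] %in% 0:1))
  expect_true(all(counts[, "normal"] %in% 1:2))

  # a case with several slides lands in exactly one fold
  m2 <- rbind(m, data.frame(slide_id = c("s11", "s12"), case_id = "c01",
                            label = "normal", source = "x",
                            image_uri = "none.png"))
  fa2 <- make_folds(m2, k = 5)
  slide_folds <- fa2$folds[m2$case_id]
  expect_equal(length(unique(slide_folds[m2$case_id == "c01"])), 1L)

  expect_equal(unname(make_folds(m, k = 1)$folds), rep(1L, 10))
  expect_error(make_folds(m[1:4, ], k = 5), "fewer cases")
})

test_that("fold stratification tolerance holds on random manifests", {
  set.seed(43)
  for (i in 1:30) {
    m <- random_manifest(sample(8:30, 1))
    k <- sample(2:5, 1)
    if (length(unique(m$case_id)) < k) next
    fa <- make_folds(m, k)
    # case-disjoint by construction of the mapping: check via slides
    sf <- fa$folds[m$case_id]
    expect_true(all(tapply(sf, m$case_id, function(x) length(unique(x))) == 1))
    case_lab <- tapply(m$label, m$case_id, function(x) x[1])
    for (cl in unique(case_lab)) {
      per_fold <- tabulate(fa$folds[names(case_lab)[case_lab == cl]], k)
      expect_lte(max(abs(per_fold - sum(case_lab == cl) / k)), 1)
    }
  }
})

test_that("metrics match a hand-built contingency table", {
  # TP=3, FP=1, FN=1, TN=5
  dec <- c(rep(TRUE, 4), rep(FALSE, 6))
  lab <- c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5))
  r <- compute_metrics(dec, lab)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.75)
  expect_equal(r$accuracy, 0.8)
  expect_equal(c(r$tp, r$fp, r$tn, r$fn), c(3, 1, 5, 1))

  perfect <- compute_metrics(lab, lab)
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall),
               c(1, 1, 1))

  expect_warning(r0 <- compute_metrics(rep(FALSE, 4), c(TRUE, TRUE, FALSE, FALSE)),
                 "precision")
  expect_true(is.nan(r0$precision))
  expect_equal(r0$recall, 0)
})

test_that("metric identities hold on random confusion tables", {
  set.seed(47)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    dec <- stats::runif(n) < 0.5
    lab <- stats::runif(n) < 0.5
    r <- suppressWarnings(compute_metrics(dec, lab))
    expect_equal(r$tp + r$fp + r$tn + r$fn, n)
    expect_equal(r$accuracy, (r$tp + r$tn) / n)
    for (v in c(r$precision, r$recall)) {
      expect_true(is.nan(v) || (v >= 0 && v <= 1))
    }
  }
})
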