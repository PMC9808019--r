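#' Summarise patch predictions into a slide score
#'
#' The slide-level statistic is the arithmetic mean of the per-tile
#' probabilities, taken per class head.
#'
#' @param predictions `n_tiles x 2` matrix of per-tile probabilities
#'   (columns: normal, coeliac).
#' @param slide_id Optional identifier.
#' @return An object of class `slide_score`: list with `slide_id`,
#'   `mean_normal`, `mean_coeliac`, `n_tiles`.
#' @export
slide_score <- function(predictions, slide_id = NA_character_) {
  if (!is.matrix(predictions) || nrow(predictions) == 0L) {
    stop("cannot score a slide with no tile predictions")
  }
  stopifnot(ncol(predictions) == 2L)
  structure(list(slide_id = slide_id,
                 mean_normal = mean(predictions[, 1L]),
                 mean_coeliac = mean(predictions[, 2L]),
                 n_tiles = nrow(predictions)),
            class = "slide_score")
}

#' Decision thresholds for the two class heads
#'
#' Defaults are the operating points selected on the original cohort: a
#' slide is called normal when the mean normal-head prediction exceeds
#' 0.905 and coeliac-positive when the mean coeliac-head prediction exceeds
#' 0.096. The two heads are thresholded independently.
#'
#' @param t_normal,t_coeliac Thresholds in `(0, 1)`.
#' @return A `threshold_pair` list.
#' @export
threshold_pair <- function(t_normal = 0.905, t_coeliac = 0.096) {
  stopifnot(t_normal > 0, t_normal < 1, t_coeliac > 0, t_coeliac < 1)
  structure(list(t_normal = t_normal, t_coeliac = t_coeliac),
            class = "threshold_pair")
}

#' Classify a slide from its mean scores
#'
#' Each head is decided independently by a strict comparison ("exceeds"),
#' so a slide can trigger both heads or neither; such slides are flagged
#' `discordant` rather than resolved.
#'
#' @param score A [slide_score()].
#' @param thresholds A [threshold_pair()].
#' @return List with logicals `normal_positive`, `coeliac_positive` and
#'   `discordant`.
#' @export
classify_slide <- function(score, thresholds = threshold_pair()) {
  np <- score$mean_normal > thresholds$t_normal
  cp <- score$mean_coeliac > thresholds$t_coeliac
  list(normal_positive = np, coeliac_positive = cp, discordant = np == cp)
}

#' ROC and PR curves with trapezoidal AUC
#'
#' Sweeps all distinct score values as thresholds (predict positive when
#' `score >= t`), accumulating true/false positives with ties grouped, and
#' integrates both curves by the trapezoidal rule. The ROC AUC therefore
#' equals the Mann--Whitney pairwise-comparison statistic with ties counted
#' one half.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param labels Logical (or 0/1) vector: `TRUE` for the positive class.
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`), `pr`
#'   (data frame `threshold`, `recall`, `precision`), `roc_auc`, `pr_auc`.
#' @export
roc_and_pr <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  p <- sum(labels)
  n <- sum(!labels)
  if (p == 0L || n == 0L) {
    stop("both classes must be present to compute ROC/PR curves")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores
  last <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last]
  fp <- cumsum(!y)[last]
  thr <- s[last]
  tpr <- tp / p
  fpr <- fp / n
  precision <- tp / (tp + fp)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  pr <- data.frame(threshold = thr, recall = tpr, precision = precision)
  roc_auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  # PR curve: trapezoid over achievable recall, anchored at the first point
  rec <- c(0, pr$recall)
  prec <- c(pr$precision[1L], pr$precision)
  pr_auc <- sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
  list(roc = roc, pr = pr, roc_auc = roc_auc, pr_auc = pr_auc)
}

#' Select a decision threshold at the sensitivity = specificity balance point
#'
#' Chooses, among candidate thresholds (midpoints between consecutive
#' distinct scores plus outer sentinels), the one minimising
#' `|sensitivity - specificity|`, averaged over cross-validation folds when
#' fold ids are supplied. Ties break towards the lower threshold. A slide is
#' called positive when its score strictly exceeds the threshold.
#'
#' The balance-point objective is the standard reading of selecting an
#' operating point where the true-positive rate matches the true-negative
#' rate; the literal objective `|TPR - FPR|` (which favours chance-level
#' points) is available via `objective = "literal"` for comparison.
#'
#' @param scores Numeric slide scores.
#' @param labels Logical (or 0/1): `TRUE` for the positive class.
#' @param folds Optional fold ids, same length as `scores`.
#' @param objective `"balance"` (default) or `"literal"`.
#' @return The selected threshold (numeric scalar).
#' @export
select_threshold <- function(scores, labels, folds = NULL,
                             objective = c("balance", "literal")) {
  objective <- match.arg(objective)
  labels <- as.logical(labels)
  if (sum(labels) == 0L || sum(!labels) == 0L) {
    stop("both classes must be present to select a threshold")
  }
  su <- sort(unique(scores))
  if (length(su) < 2L) {
    stop("degenerate scores: all values identical, no threshold separates them")
  }
  mids <- (su[-1] + su[-length(su)]) / 2
  gap <- max(diff(su)) / 2
  cand <- c(su[1] - gap, mids, su[length(su)] + gap)
  if (is.null(folds)) folds <- rep(1L, length(scores))
  fold_ids <- unique(folds)
  obj <- sapply(cand, function(t) {
    per_fold <- vapply(fold_ids, function(f) {
      in_f <- folds == f
      y <- labels[in_f]
      pos_pred <- scores[in_f] > t
      sens <- if (any(y)) mean(pos_pred[y]) else NA_real_
      spec <- if (any(!y)) mean(!pos_pred[!y]) else NA_real_
      fpr <- if (any(!y)) mean(pos_pred[!y]) else NA_real_
      if (objective == "balance") abs(sens - spec) else abs(sens - fpr)
    }, numeric(1))
    mean(per_fold, na.rm = TRUE)
  })
  cand[which.min(obj)] # which.min takes the first (lowest) candidate on ties
}

#' Case-grouped stratified fold assignment
#'
#' Assigns whole cases (patient samples) to `k` folds so that no case is
#' split across folds and the normal/coeliac case ratio of each fold stays
#' within one case of perfect stratification. Cases are shuffled within
#' class strata (seeded via R's RNG) and dealt greedily to the currently
#' lightest fold.
#'
#' @param manifest Data frame with `case_id` and `label` columns (one row
#'   per slide; a case's slides must share a label).
#' @param k Number of folds.
#' @return An object of class `fold_assignment`: list with `folds` (named
#'   integer vector, case_id -> fold in `1..k`) and `k`.
#' @export
make_folds <- function(manifest, k = 5L) {
  stopifnot(k >= 1L)
  cases <- unique(manifest$case_id)
  if (length(cases) < k) stop("fewer cases than folds")
  case_label <- vapply(cases, function(cid) {
    labs <- unique(manifest$label[manifest$case_id == cid])
    if (length(labs) > 1L) {
      warning("case ", cid, " has mixed slide labels; using the first")
    }
    labs[1L]
  }, character(1))
  assignment <- integer(length(cases))
  names(assignment) <- cases
  fold_total <- integer(k)
  classes <- names(sort(table(case_label), decreasing = TRUE))
  for (cl in classes) {
    members <- sample(cases[case_label == cl])
    for (cid in members) {
      f <- which.min(fold_total)
      assignment[cid] <- f
      fold_total[f] <- fold_total[f] + 1L
    }
  }
  structure(list(folds = assignment, k = as.integer(k)),
            class = "fold_assignment")
}

#' Per-class classification metrics
#'
#' Confusion counts and the three headline ratios for one class head:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`. Ratios with a zero denominator are reported as `NaN` with
#' a warning, never silently as 0. If `scores` are supplied, ROC and PR
#' AUCs are included.
#'
#' @param decisions Logical vector of positive predictions for the class.
#' @param labels Logical vector of true class membership.
#' @param scores Optional numeric scores for AUCs.
#' @return An object of class `metrics_report`: list with `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `precision`, `recall` and (optionally) `roc_auc`,
#'   `pr_auc`.
#' @export
compute_metrics <- function(decisions, labels, scores = NULL) {
  decisions <- as.logical(decisions)
  labels <- as.logical(labels)
  stopifnot(length(decisions) == length(labels), length(labels) >= 1L)
  tp <- sum(decisions & labels)
  fp <- sum(decisions & !labels)
  tn <- sum(!decisions & !labels)
  fn <- sum(!decisions & labels)
  precision <- if (tp + fp == 0L) {
    warning("no positive predictions: precision is undefined (NaN)")
    NaN
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0L) {
    warning("no positive instances: recall is undefined (NaN)")
    NaN
  } else tp / (tp + fn)
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              accuracy = (tp + tn) / length(labels),
              precision = precision, recall = recall)
  if (!is.null(scores)) {
    curves <- roc_and_pr(scores, labels)
    out$roc_auc <- curves$roc_auc
    out$pr_auc <- curves$pr_auc
  }
  structure(out, class = "metrics_report")
}
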