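# Shared fixture builders. Everything is generated in code at test time.

# Brute-force Otsu: exhaustive search over all 256 thresholds, kept naive on
# purpose so it stays an independent oracle for the vectorised implementation.
brute_force_otsu <- function(hist) {
  p <- hist / sum(hist)
  lev <- 0:255
  best <- -Inf
  bt <- NA_integer_
  for (t in 0:255) {
    w0 <- sum(p[1:(t + 1)])
    w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:(t + 1)] * lev[1:(t + 1)]) / w0
    mu1 <- sum(p[(t + 2):256] * lev[(t + 2):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best + 1e-12) {
      best <- v
      bt <- t
    }
  }
  bt
}

# A flat RGB patch of one grey value.
flat_patch <- function(value, size = 64L) {
  array(value, c(size, size, 3L))
}

# Synthetic two-stain patch: od = M %*% C with a concentration cloud that
# contains near-pure pixels of each stain, so the angular extremes of the OD
# cloud sit close to the true stain vectors. The construction is the oracle.
stain_test_patch <- function(stain_matrix, n_side = 64L) {
  n <- n_side^2
  kind <- sample(3L, n, replace = TRUE, prob = c(0.3, 0.3, 0.4))
  ch <- ifelse(kind == 1L, stats::runif(n, 0.5, 1.2),
        ifelse(kind == 2L, stats::runif(n, 0, 0.02), stats::runif(n, 0.2, 0.8)))
  ce <- ifelse(kind == 2L, stats::runif(n, 0.4, 1.0),
        ifelse(kind == 1L, stats::runif(n, 0, 0.02), stats::runif(n, 0.2, 0.7)))
  od <- cbind(ch, ce) %*% t(stain_matrix)
  list(patch = array(od_to_rgb(od), c(n_side, n_side, 3L)),
       concentrations = cbind(ch, ce))
}

angle_deg <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# Random slide manifest (labels by case) for fold-assignment tests.
random_manifest <- function(n_cases, p_coeliac = 0.4, max_slides_per_case = 3L) {
  case_ids <- sprintf("c%03d", seq_len(n_cases))
  labels <- ifelse(stats::runif(n_cases) < p_coeliac, "coeliac", "normal")
  # ensure both classes appear
  if (all(labels == labels[1])) {
    labels[1] <- setdiff(c("normal", "coeliac"), labels[1])
  }
  rows <- lapply(seq_len(n_cases), function(i) {
    ns <- sample.int(max_slides_per_case, 1L)
    data.frame(slide_id = sprintf("%s_s%d", case_ids[i], seq_len(ns)),
               case_id = case_ids[i], label = labels[i], source = "x",
               image_uri = "none.png", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Brute-force proxy labelling: full sort of the normality scores, positives
# at the alpha lowest, negatives at the beta highest, ties by bag index.
brute_force_proxy <- function(predictions, slide_label, alpha, beta) {
  b <- nrow(predictions)
  labels <- matrix(0, b, 2L)
  mask <- integer(b)
  if (slide_label == "normal") {
    labels[, 1L] <- 1
    mask[] <- 1L
  } else {
    key <- order(predictions[, 1L], seq_len(b))
    pos <- key[seq_len(alpha)]
    labels[pos, 2L] <- 1
    mask[pos] <- 1L
    if (beta > 0) {
      neg <- key[(b - beta + 1L):b]
      labels[neg, 1L] <- 1
      mask[neg] <- 1L
    }
  }
  list(labels = labels, mask = mask)
}

# Mann-Whitney AUC oracle: all pairwise comparisons, ties count one half.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
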