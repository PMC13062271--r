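# Shared helpers: random valid sequences, a tiny labelled cohort, and
# independent brute-force oracles for the evaluation metrics.

rand_seqs <- function(n, min_len = 10L, max_len = 30L) {
  vapply(seq_len(n), function(i) {
    len <- min_len + sample.int(max_len - min_len + 1L, 1L) - 1L
    paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
  }, character(1))
}

small_cohort <- function(n_per_tissue = 40L, multiplier = 10, seed = 11L,
                         duplicate_rate = 0.1) {
  cfg <- synthetic_config(
    n_per_tissue = stats::setNames(rep(n_per_tissue, 9L), TISSUES),
    planted_signals = default_planted_signals(multiplier),
    duplicate_rate = duplicate_rate, seed = seed)
  generate_cohort(cfg)
}

# Brute-force metric oracles, written as explicit loops so they stay
# independent of the package implementation.

oracle_confusion <- function(y_true, y_pred) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1L
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1L
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1L
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1L
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

oracle_auc_roc <- function(y_true, y_score) {
  pos <- y_score[y_true == 1]; neg <- y_score[y_true == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

oracle_auc_pr <- function(y_true, y_score) {
  n_pos <- sum(y_true == 1)
  thresholds <- sort(unique(y_score), decreasing = TRUE)
  ap <- 0; last_recall <- 0
  for (t in thresholds) {
    pred <- as.integer(y_score >= t)
    cts <- oracle_confusion(y_true, pred)
    precision <- cts["TP"] / (cts["TP"] + cts["FP"])
    recall <- cts["TP"] / n_pos
    ap <- ap + (recall - last_recall) * precision
    last_recall <- recall
  }
  unname(ap)
}

oracle_panel <- function(y_true, y_score, threshold = 0.5) {
  y_pred <- as.integer(y_score >= threshold)
  cts <- oracle_confusion(y_true, y_pred)
  tp <- cts["TP"]; fp <- cts["FP"]; tn <- cts["TN"]; fn <- cts["FN"]
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  specificity <- if (tn + fp == 0) 0 else tn / (tn + fp)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  unname(c((recall + specificity) / 2,
           (tp + tn) / length(y_true),
           precision, recall, f1, mcc,
           oracle_auc_roc(y_true, y_score),
           oracle_auc_pr(y_true, y_score)))
}
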