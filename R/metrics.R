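# Eight-metric evaluation panel for imbalanced one-versus-rest tasks:
# balanced accuracy, accuracy, precision, recall, F1, Matthews correlation
# coefficient (primary), AUC-ROC (rank statistic) and AUC-PR (average
# precision).

#' 2x2 confusion counts
#'
#' @param y_true,y_pred Equal-length binary (0/1) vectors.
#' @return Named list with \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be binary 0/1")
  }
  list(TP = sum(y_true == 1 & y_pred == 1),
       FP = sum(y_true == 0 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FN = sum(y_true == 1 & y_pred == 0))
}

#' Matthews correlation coefficient from confusion counts
#'
#' \code{MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))}, with
#' the degenerate 0/0 case returned as 0.
#'
#' @param counts A list from [confusion()].
#' @return MCC in [-1, 1].
#' @export
mcc_from_counts <- function(counts) {
  with(counts, {
    num <- as.numeric(TP) * TN - as.numeric(FP) * FN
    den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
           sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
    if (den == 0) 0 else num / den
  })
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation, equivalent to the trapezoidal area under the
#' empirical ROC curve with midpoint tie handling.
#'
#' @param y_true Binary labels with both classes present.
#' @param y_score Numeric scores.
#' @return AUC-ROC in [0, 1].
#' @export
auc_roc <- function(y_true, y_score) {
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop("AUC-ROC undefined: y_true has a single class")
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise, non-interpolated average precision:
#' \code{AP = sum_n (R_n - R_\{n-1\}) * P_n} over threshold steps taken at the
#' distinct score values in decreasing order. The no-skill baseline equals
#' the positive-class prevalence.
#'
#' @param y_true Binary labels with at least one positive.
#' @param y_score Numeric scores.
#' @return AUC-PR in [0, 1].
#' @export
auc_pr <- function(y_true, y_score) {
  n1 <- sum(y_true == 1)
  if (n1 == 0 || n1 == length(y_true)) {
    stop("AUC-PR undefined: y_true has a single class")
  }
  o <- order(y_score, decreasing = TRUE)
  ys <- y_score[o]; yt <- y_true[o]
  tp <- cumsum(yt == 1)
  pred_pos <- seq_along(yt)
  # threshold steps at the last index of each distinct score
  steps <- which(c(diff(ys) != 0, TRUE))
  precision <- tp[steps] / pred_pos[steps]
  recall <- tp[steps] / n1
  sum(diff(c(0, recall)) * precision)
}

#' Compute the eight-metric evaluation panel
#'
#' Threshold metrics are computed from hard labels at the given threshold
#' (default 0.5); MCC uses the 0/0 -> 0 convention; F1 is 0 when precision
#' and recall are both 0; AUC-ROC is the rank statistic and AUC-PR the
#' average precision.
#'
#' @param y_true Binary labels with both classes present.
#' @param y_score Scores in [0, 1].
#' @param threshold Decision threshold; default 0.5 (label 1 iff score >=
#'   threshold).
#' @return An object of class \code{acp_eval}: list with \code{metrics}
#'   (named numeric vector of the eight panel metrics), \code{counts}
#'   ([confusion()] list) and \code{n_test}.
#' @export
compute_panel <- function(y_true, y_score, threshold = 0.5) {
  if (length(unique(y_true)) < 2L) {
    stop("evaluation requires both classes in y_true")
  }
  if (any(y_score < 0 | y_score > 1)) stop("scores must lie in [0, 1]")
  y_pred <- as.integer(y_score >= threshold)
  cts <- confusion(y_true, y_pred)
  precision <- with(cts, if (TP + FP == 0) 0 else TP / (TP + FP))
  recall <- with(cts, if (TP + FN == 0) 0 else TP / (TP + FN))
  specificity <- with(cts, if (TN + FP == 0) 0 else TN / (TN + FP))
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  metrics <- c(
    balanced_accuracy = (recall + specificity) / 2,
    accuracy = with(cts, (TP + TN) / (TP + TN + FP + FN)),
    precision = precision,
    recall = recall,
    f1 = f1,
    mcc = mcc_from_counts(cts),
    auc_roc = auc_roc(y_true, y_score),
    auc_pr = auc_pr(y_true, y_score)
  )
  structure(list(metrics = metrics, counts = cts, n_test = length(y_true)),
            class = "acp_eval")
}

#' @export
print.acp_eval <- function(x, ...) {
  cat("Evaluation panel (n =", x$n_test, "):\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' Summarize evaluation panels across tissues
#'
#' Computes per-family unweighted means and standard deviations of each
#' metric over the tissue tasks, and the per-family average rank: within
#' each tissue, families are ranked by descending MCC (ties take the mean
#' rank), and ranks are averaged per family.
#'
#' @param reports data.frame with columns \code{tissue}, \code{family} and
#'   one column per metric (at least \code{mcc}).
#' @return List with \code{means}, \code{sds} (data.frames, one row per
#'   family) and \code{avg_rank} (named numeric vector).
#' @export
summarize_across_tissues <- function(reports) {
  stopifnot(is.data.frame(reports),
            all(c("tissue", "family", "mcc") %in% names(reports)))
  metric_cols <- setdiff(names(reports), c("tissue", "family"))
  fams <- unique(reports$family)
  means <- aggregate(reports[metric_cols], by = list(family = reports$family), mean)
  sds <- aggregate(reports[metric_cols], by = list(family = reports$family), stats::sd)
  ranks <- lapply(split(reports, reports$tissue), function(df) {
    stats::setNames(rank(-df$mcc, ties.method = "average"), df$family)
  })
  avg_rank <- vapply(fams, function(f) {
    mean(vapply(ranks, function(r) {
      if (!f %in% names(r)) NA_real_ else r[[f]]
    }, numeric(1)), na.rm = TRUE)
  }, numeric(1))
  missing <- reports[FALSE, c("tissue", "family")]
  grid <- expand.grid(tissue = unique(reports$tissue), family = fams,
                      stringsAsFactors = FALSE)
  have <- paste(reports$tissue, reports$family)
  absent <- grid[!(paste(grid$tissue, grid$family) %in% have), ]
  list(means = means, sds = sds, avg_rank = avg_rank,
       missing_cells = absent)
}
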