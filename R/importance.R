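# Feature importance extraction for the tree-based families, top-k pooling
# across tissues, and descriptor-category aggregation.

#' Extract normalized feature importances from a tree-based model
#'
#' Gain-based importances for gradient boosting, impurity-based for random
#' forest, aligned to the full feature schema (features a boosted model never
#' split on get 0), renormalized to sum to 1, and sorted in descending order
#' with ties broken by schema order.
#'
#' @param model An \code{acp_model} of family \code{random_forest} or
#'   \code{xgboost}.
#' @param schema Feature schema data.frame from [feature_schema()]; defaults
#'   to the shipped schema.
#' @return An object of class \code{acp_importance}: data.frame with columns
#'   \code{feature}, \code{category}, \code{score}, \code{rank}.
#' @export
extract_importances <- function(model, schema = feature_schema()) {
  stopifnot(inherits(model, "acp_model"))
  if (!model$family %in% c("random_forest", "xgboost")) {
    stop("built-in importances are only available for tree-based families")
  }
  raw <- stats::setNames(numeric(nrow(schema)), schema$name)
  if (model$family == "random_forest") {
    imp <- model$fit$variable.importance
    raw[names(imp)] <- imp
  } else {
    imp <- xgboost::xgb.importance(model = model$fit)
    raw[imp$Feature] <- imp$Gain
  }
  if (!all(names(raw) %in% schema$name) || length(raw) != nrow(schema)) {
    stop("model features do not match the schema")
  }
  raw[raw < 0] <- 0
  total <- sum(raw)
  score <- if (total > 0) raw / total else rep(1 / length(raw), length(raw))
  ord <- order(-score, seq_along(score))  # ties: schema order
  out <- data.frame(feature = schema$name[ord],
                    category = schema$category[ord],
                    score = unname(score[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  class(out) <- c("acp_importance", "data.frame")
  out
}

#' Pool top-k important features across tissue tasks
#'
#' Concatenates each tissue's top-k feature names (with multiplicity across
#' tissues), counts descriptor-category membership in the pooled list, and
#' reports per-feature recurrence (the number of tissues in whose top-k the
#' feature appears).
#'
#' @param tables Named list of \code{acp_importance} tables, one per tissue,
#'   all over the same schema and model family.
#' @param k Top-list size per tissue (default 20).
#' @return List with \code{pooled} (data.frame \code{tissue}, \code{feature},
#'   \code{category}, \code{rank}), \code{category_counts} (named integer
#'   vector over AAC/DPC/PCP/PAAC summing to \code{k * length(tables)}),
#'   \code{recurrence} (data.frame \code{feature}, \code{n_tissues}, sorted
#'   by recurrence) and \code{pooled_count}.
#' @export
top_k_pool <- function(tables, k = 20L) {
  stopifnot(length(tables) >= 1L)
  feats <- lapply(tables, function(t) t$feature)
  ref <- sort(feats[[1L]])
  for (t in feats[-1L]) {
    if (!identical(sort(t), ref)) stop("importance tables use inconsistent schemas")
  }
  if (is.null(names(tables))) names(tables) <- paste0("task", seq_along(tables))
  pooled <- do.call(rbind, lapply(names(tables), function(ti) {
    top <- utils::head(tables[[ti]], k)
    data.frame(tissue = ti, feature = top$feature, category = top$category,
               rank = top$rank, stringsAsFactors = FALSE)
  }))
  category_counts <- vapply(c("AAC", "DPC", "PCP", "PAAC"),
                            function(cat) sum(pooled$category == cat), integer(1))
  rec <- sort(table(pooled$feature), decreasing = TRUE)
  recurrence <- data.frame(feature = names(rec), n_tissues = as.integer(rec),
                           stringsAsFactors = FALSE)
  list(pooled = pooled, category_counts = category_counts,
       recurrence = recurrence, pooled_count = nrow(pooled))
}

#' Aggregate importance mass by descriptor category
#'
#' Sums the normalized importance scores within each descriptor family
#' (AAC, DPC, PCP, PAAC). The four sums total 1.
#'
#' @param table An \code{acp_importance} table.
#' @return Named numeric vector of length 4.
#' @export
category_rollup <- function(table) {
  stopifnot(inherits(table, "acp_importance") || is.data.frame(table))
  vapply(c("AAC", "DPC", "PCP", "PAAC"), function(cat) {
    sum(table$score[table$category == cat])
  }, numeric(1))
}
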