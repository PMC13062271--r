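# End-to-end benchmarking: encode once, then for every tissue x family cell
# split group-aware, (optionally) tune on the training side, fit, and score
# the eight-metric panel on the held-out test records.

#' Benchmark classifier families over the nine one-versus-rest tissue tasks
#'
#' For each tissue and family: builds the one-versus-rest task, performs a
#' group-aware train/test split, optionally tunes hyperparameters by
#' randomized search with group-based cross-validation inside the training
#' partition (model selection on AUC-PR), fits with algorithm-level class
#' weighting, and evaluates the eight-metric panel on the held-out test set.
#'
#' @param dataset An \code{acp_dataset}.
#' @param families Character vector of model families (default
#'   \code{"xgboost"}).
#' @param tissues Tissues to benchmark; defaults to all tissues present.
#' @param test_fraction Held-out group fraction (default 0.2).
#' @param seed Integer seed (default 42).
#' @param tune Whether to run the randomized search (default FALSE: fit with
#'   the documented family defaults).
#' @param n_draws,k Search budget and CV fold count when tuning.
#' @param params Named list of fixed hyperparameters per family (overrides
#'   defaults when not tuning).
#' @param features Optional pre-computed feature matrix from
#'   [encode_dataset()] (must align to \code{dataset$records}).
#' @return List with \code{reports} (data.frame: tissue, family, the eight
#'   metrics, n_test, n_pos_test), \code{models} (nested list
#'   \code{models[[tissue]][[family]]}) and \code{splits}.
#' @export
benchmark_tissues <- function(dataset, families = "xgboost", tissues = NULL,
                              test_fraction = 0.2, seed = 42L, tune = FALSE,
                              n_draws = 20L, k = 3L, params = list(),
                              features = NULL) {
  stopifnot(inherits(dataset, "acp_dataset"))
  families <- match.arg(families, MODEL_FAMILIES, several.ok = TRUE)
  if (is.null(tissues)) {
    tissues <- intersect(TISSUES, unique(dataset$records$tissue))
  }
  if (is.null(features)) features <- encode_dataset(dataset$records)
  stopifnot(nrow(features) == dataset$n_entries)

  reports <- list(); models <- list(); splits <- list()
  for (tissue in tissues) {
    task <- build_ovr_task(dataset, tissue)
    split <- group_train_test_split(task, test_fraction, seed)
    splits[[tissue]] <- split
    xtr <- features[split$train_idx, , drop = FALSE]
    ytr <- task$labels[split$train_idx]
    xte <- features[split$test_idx, , drop = FALSE]
    yte <- task$labels[split$test_idx]
    gtr <- task$records$sequence[split$train_idx]
    models[[tissue]] <- list()
    for (family in families) {
      model <- if (tune) {
        tune_model(xtr, ytr, gtr, family, k = k, n_draws = n_draws,
                   seed = seed)$model
      } else {
        acp_train(xtr, ytr, family, params = params[[family]] %||% list(),
                  seed = seed)
      }
      models[[tissue]][[family]] <- model
      panel <- compute_panel(yte, predict(model, xte))
      reports[[paste(tissue, family)]] <- data.frame(
        tissue = tissue, family = family, t(panel$metrics),
        n_test = panel$n_test, n_pos_test = sum(yte),
        stringsAsFactors = FALSE)
    }
  }
  reports <- do.call(rbind, c(reports, list(make.row.names = FALSE)))
  list(reports = reports, models = models, splits = splits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
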