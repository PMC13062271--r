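# Five classifier families over the 473-dimensional descriptor space:
# linear SVM, random forest, penalised logistic regression, k-nearest
# neighbours, and gradient-boosted trees. Scale-sensitive families are
# standardized with moments estimated on the training rows only; tree
# families train on raw feature values. Class imbalance is handled by
# algorithm-level weighting (inverse class frequency; positive-class scaling
# for boosting), never by synthetic resampling.

#' Supported classifier families
#'
#' Character vector naming the five classifier families the package trains
#' and tunes.
#' @export
MODEL_FAMILIES <- c("svm_linear", "random_forest", "logistic_regression",
                    "knn", "xgboost")

#' Hyperparameter search space for a classifier family
#'
#' Returns the fixed search grid for each family. Incompatible
#' penalty/solver combinations for logistic regression (l1 with lbfgs) are
#' pruned when configurations are enumerated, not here, so the grid
#' serializes verbatim.
#'
#' @param family One of \code{"svm_linear"}, \code{"random_forest"},
#'   \code{"logistic_regression"}, \code{"knn"}, \code{"xgboost"}.
#' @return List with \code{family} and \code{grid} (named list of admissible
#'   values per hyperparameter).
#' @export
build_search_space <- function(family) {
  grid <- switch(family,
    svm_linear = list(
      C = c(0.001, 0.01, 0.1, 1, 10),
      kernel = "linear"
    ),
    random_forest = list(
      n_estimators = c(10, 50, 100, 200),
      max_depth = c(2, 3, 5, 7, 10),
      min_samples_leaf = c(5, 10, 20)
    ),
    logistic_regression = list(
      C = c(0.001, 0.01, 0.1, 1, 10),
      penalty = c("l1", "l2"),
      solver = c("liblinear", "lbfgs", "saga")
    ),
    knn = list(
      n_neighbors = c(3, 5, 7, 9, 11),
      weights = c("uniform", "distance"),
      metric = c("manhattan", "euclidean")
    ),
    xgboost = list(
      learning_rate = c(0.01, 0.05, 0.1, 0.3),
      max_depth = c(3, 5, 7),
      n_estimators = c(50, 100, 200),
      subsample = c(0.8, 1.0),
      colsample_bytree = c(0.8, 1.0)
    ),
    stop("unknown model family: ", family)
  )
  list(family = family, grid = grid)
}

#' Enumerate the valid configurations of a search space
#'
#' Full Cartesian product of the grid, with invalid combinations pruned
#' (logistic regression: the lbfgs solver does not support the l1 penalty).
#'
#' @param space A search space from [build_search_space()].
#' @return data.frame with one row per valid configuration.
#' @export
enumerate_configs <- function(space) {
  configs <- expand.grid(space$grid, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  if (space$family == "logistic_regression") {
    configs <- configs[!(configs$penalty == "l1" & configs$solver == "lbfgs"), ,
                       drop = FALSE]
    rownames(configs) <- NULL
  }
  configs
}

# Draw up to n_draws distinct configurations; exhaustive (enumeration order)
# when the valid grid is no larger than the budget.
sample_configs <- function(space, n_draws = 50L, seed = 42L) {
  configs <- enumerate_configs(space)
  if (nrow(configs) <= n_draws) return(configs)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  configs[sample(nrow(configs), n_draws), , drop = FALSE]
}

# Inverse-class-frequency observation weights, normalized so the mean weight
# is 1: w_i = n / (2 * n_class(y_i)).
.balanced_weights <- function(y) {
  n <- length(y)
  n1 <- sum(y == 1L); n0 <- n - n1
  ifelse(y == 1L, n / (2 * n1), n / (2 * n0))
}

.standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1  # constant columns map to 0
  list(center = center, scale = scale)
}

.standardize_apply <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

.schema_fingerprint <- function(x) {
  list(n = ncol(x), names = colnames(x))
}

.default_params <- function(family) {
  switch(family,
    svm_linear = list(C = 1, kernel = "linear"),
    random_forest = list(n_estimators = 100, max_depth = 0,
                         min_samples_leaf = 5),
    logistic_regression = list(C = 1, penalty = "l2", solver = "lbfgs"),
    knn = list(n_neighbors = 5, weights = "uniform", metric = "euclidean"),
    xgboost = list(learning_rate = 0.1, max_depth = 5, n_estimators = 100,
                   subsample = 1.0, colsample_bytree = 1.0)
  )
}

#' Fit one classifier with algorithm-level class weighting
#'
#' Trains a single model of the requested family. Scale-sensitive families
#' (linear SVM, logistic regression, KNN) are standardized with training-set
#' moments stored in the returned object; tree families (random forest,
#' gradient boosting) train on the original feature values. Balanced
#' weighting assigns each observation the inverse frequency of its class
#' (normalized to mean 1); for gradient boosting the positive class is scaled
#' by \code{scale_pos_weight}, defaulting to \code{n_neg / n_pos} and tunable
#' via \code{params}.
#'
#' @param x Numeric feature matrix with schema column names.
#' @param y Binary integer vector (0/1) with both classes present.
#' @param family Model family name, see \code{MODEL_FAMILIES}.
#' @param params Named list of hyperparameters (family grid names); missing
#'   entries fall back to documented defaults.
#' @param class_weighting \code{"balanced"} (default), \code{"pos_scale"}
#'   (gradient boosting only) or \code{"none"}.
#' @param seed Integer seed for stochastic families; default 42.
#' @return An object of class \code{acp_model}.
#' @export
acp_train <- function(x, y, family = "xgboost", params = list(),
                      class_weighting = c("balanced", "pos_scale", "none"),
                      seed = 42L) {
  family <- match.arg(family, MODEL_FAMILIES)
  class_weighting <- match.arg(class_weighting)
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) != 2L || !all(y %in% c(0L, 1L))) {
    stop("y must be binary 0/1 with both classes present")
  }
  p <- utils::modifyList(.default_params(family), params)
  weights <- if (class_weighting == "balanced") .balanced_weights(y) else rep(1, length(y))
  scaler <- NULL
  xt <- x
  if (family %in% c("svm_linear", "logistic_regression", "knn")) {
    scaler <- .standardize_fit(x)
    xt <- .standardize_apply(x, scaler)
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  fit <- switch(family,
    svm_linear = {
      cls_w <- c("0" = length(y) / (2 * sum(y == 0L)),
                 "1" = length(y) / (2 * sum(y == 1L)))
      if (class_weighting == "none") cls_w <- c("0" = 1, "1" = 1)
      e1071::svm(x = xt, y = factor(y, levels = c(0, 1)), kernel = "linear",
                 cost = p$C, class.weights = cls_w, probability = TRUE,
                 scale = FALSE)
    },
    random_forest = {
      cls_w <- c(length(y) / (2 * sum(y == 0L)), length(y) / (2 * sum(y == 1L)))
      if (class_weighting == "none") cls_w <- c(1, 1)
      ranger::ranger(x = xt, y = factor(y, levels = c(0, 1)),
                     num.trees = p$n_estimators,
                     max.depth = p$max_depth,  # 0 = unlimited
                     min.node.size = p$min_samples_leaf,
                     mtry = floor(sqrt(ncol(xt))),
                     probability = TRUE, class.weights = cls_w,
                     oob.error = TRUE, seed = seed, num.threads = 1L)
    },
    logistic_regression = {
      alpha <- if (p$penalty == "l1") 1 else 0
      if (p$penalty == "l1" && p$solver == "lbfgs") {
        stop("the lbfgs solver does not support the l1 penalty")
      }
      lambda <- 1 / (p$C * length(y))
      glmnet::glmnet(xt, y, family = "binomial", alpha = alpha,
                     lambda = lambda, weights = weights, standardize = FALSE,
                     maxit = 1e5)
    },
    knn = {
      list(x = xt, y = y, k = p$n_neighbors, vote = p$weights,
           metric = p$metric)
    },
    xgboost = {
      n1 <- sum(y == 1L); n0 <- sum(y == 0L)
      spw <- if (class_weighting == "none") 1
             else if (!is.null(p$scale_pos_weight)) p$scale_pos_weight
             else n0 / n1
      dtrain <- xgboost::xgb.DMatrix(xt, label = y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", eval_metric = "logloss",
                      tree_method = "hist", eta = p$learning_rate,
                      max_depth = p$max_depth, subsample = p$subsample,
                      colsample_bytree = p$colsample_bytree,
                      scale_pos_weight = spw, nthread = 1L, seed = seed),
        data = dtrain, nrounds = p$n_estimators, verbose = 0
      )
    }
  )
  if (family == "xgboost") p$scale_pos_weight <- spw
  structure(
    list(family = family, params = p, class_weighting = class_weighting,
         seed = seed, fit = fit, scaler = scaler,
         schema = .schema_fingerprint(x),
         n_train = length(y), n_pos = sum(y == 1L)),
    class = "acp_model"
  )
}

.check_schema <- function(object, x) {
  fp <- .schema_fingerprint(x)
  if (!identical(fp, object$schema)) {
    stop("feature schema mismatch: model was trained on a different feature layout")
  }
}

#' Predict positive-class probabilities
#'
#' @param object An \code{acp_model}.
#' @param x Feature matrix with the same schema the model was trained on.
#' @param type \code{"prob"} (default) for positive-class probabilities in
#'   [0, 1], or \code{"class"} for hard 0/1 labels at the given threshold.
#' @param threshold Decision threshold for \code{type = "class"}; default 0.5.
#' @param ... Unused.
#' @return Numeric vector of probabilities, or integer labels.
#' @export
predict.acp_model <- function(object, x, type = c("prob", "class"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(x))
  .check_schema(object, x)
  xt <- if (is.null(object$scaler)) x else .standardize_apply(x, object$scaler)
  prob <- switch(object$family,
    svm_linear = {
      pr <- stats::predict(object$fit, xt, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    random_forest = {
      stats::predict(object$fit, data = xt, num.threads = 1L)$predictions[, "1"]
    },
    logistic_regression = {
      as.numeric(stats::predict(object$fit, newx = xt, type = "response"))
    },
    knn = .knn_predict(object$fit, xt),
    xgboost = {
      stats::predict(object$fit, xgboost::xgb.DMatrix(xt))
    }
  )
  prob <- unname(pmin(1, pmax(0, as.numeric(prob))))
  if (type == "class") as.integer(prob >= threshold) else prob
}

# k-nearest-neighbour vote share of the positive class. Supports manhattan
# and euclidean metrics with uniform or inverse-distance vote weights; a
# zero-distance neighbour takes the whole vote.
.knn_predict <- function(fit, xnew) {
  vapply(seq_len(nrow(xnew)), function(i) {
    d <- if (fit$metric == "manhattan") {
      colSums(abs(t(fit$x) - xnew[i, ]))
    } else {
      sqrt(colSums((t(fit$x) - xnew[i, ])^2))
    }
    nn <- order(d)[seq_len(fit$k)]
    if (fit$vote == "uniform") {
      mean(fit$y[nn])
    } else {
      dn <- d[nn]
      if (any(dn == 0)) return(mean(fit$y[nn[dn == 0]]))
      w <- 1 / dn
      sum(w * fit$y[nn]) / sum(w)
    }
  }, numeric(1))
}

#' @export
print.acp_model <- function(x, ...) {
  cat(sprintf("<acp_model> %s (%s weighting), trained on %d records (%d positives)\n",
              x$family, x$class_weighting, x$n_train, x$n_pos))
  ps <- vapply(x$params, function(v) paste(format(v), collapse = ","), character(1))
  cat("  params:", paste(names(ps), ps, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.acp_model <- function(object, ...) {
  print(object)
  if (!is.null(object$scaler)) {
    cat("  standardization: train-set moments over", length(object$scaler$center),
        "features\n")
  }
  if (object$family == "random_forest") {
    cat(sprintf("  OOB prediction error: %.4f\n", object$fit$prediction.error))
  }
  invisible(object)
}

#' Randomized hyperparameter search with group-based cross-validation
#'
#' Samples up to \code{n_draws} distinct configurations from the family's
#' search grid (exhaustively when the grid is smaller) and scores each by the
#' mean held-out-fold area under the precision-recall curve under a
#' group-aware fold plan. Standardization and class weighting are recomputed
#' inside every training fold, so held-out rows never leak into the fold's
#' scaler moments. Ties are broken in favour of the first-sampled
#' configuration.
#'
#' @param x Feature matrix.
#' @param y Binary labels.
#' @param groups Character vector of sequence group keys, one per row of
#'   \code{x}.
#' @param family Model family.
#' @param k Fold count when \code{fold_plan} is not supplied (default 5).
#' @param n_draws Search budget (default 50).
#' @param seed Integer seed (default 42).
#' @param fold_plan Optional pre-built [group_kfold()] plan.
#' @param class_weighting Passed to [acp_train()].
#' @return List with \code{best_params}, \code{best_score}, \code{cv_table}
#'   (configurations with their mean CV AUC-PR, in sampling order) and
#'   \code{model} (refit on all rows with the winning configuration).
#' @export
tune_model <- function(x, y, groups, family = "xgboost", k = 5L,
                       n_draws = 50L, seed = 42L, fold_plan = NULL,
                       class_weighting = "balanced") {
  family <- match.arg(family, MODEL_FAMILIES)
  if (is.null(fold_plan)) fold_plan <- group_kfold(groups, k = k, seed = seed)
  configs <- sample_configs(build_search_space(family), n_draws, seed)
  scores <- numeric(nrow(configs))
  for (ci in seq_len(nrow(configs))) {
    params <- as.list(configs[ci, , drop = FALSE])
    fold_scores <- rep(NA_real_, fold_plan$k)
    for (f in seq_len(fold_plan$k)) {
      held <- fold_plan$fold_idx[[f]]
      if (length(held) == 0L) next
      ytr <- y[-held]; yte <- y[held]
      if (length(unique(ytr)) < 2L || sum(yte == 1L) == 0L ||
          sum(yte == 0L) == 0L) next
      m <- acp_train(x[-held, , drop = FALSE], ytr, family, params,
                     class_weighting = class_weighting, seed = seed)
      prob <- predict(m, x[held, , drop = FALSE])
      fold_scores[f] <- auc_pr(yte, prob)
    }
    scores[ci] <- mean(fold_scores, na.rm = TRUE)
  }
  best <- which.max(scores)  # ties: first in sampling order
  cv_table <- cbind(configs, mean_auc_pr = scores)
  rownames(cv_table) <- NULL
  best_params <- as.list(configs[best, , drop = FALSE])
  model <- acp_train(x, y, family, best_params,
                     class_weighting = class_weighting, seed = seed)
  list(best_params = best_params, best_score = scores[best],
       cv_table = cv_table, model = model)
}
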