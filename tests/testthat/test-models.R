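test_that("search grids match the documented spaces and prune invalid pairs", {
  svm <- build_search_space("svm_linear")
  expect_equal(svm$grid$C, c(0.001, 0.01, 0.1, 1, 10))
  expect_identical(svm$grid$kernel, "linear")
  knn_configs <- enumerate_configs(build_search_space("knn"))
  expect_identical(nrow(knn_configs), 20L)  # 5 x 2 x 2
  lr <- enumerate_configs(build_search_space("logistic_regression"))
  expect_false(any(lr$penalty == "l1" & lr$solver == "lbfgs"))
  expect_identical(nrow(lr), 25L)  # 30 minus 5 pruned
  xgb <- enumerate_configs(build_search_space("xgboost"))
  expect_identical(nrow(xgb), 4L * 3L * 3L * 2L * 2L)
  expect_error(build_search_space("neural_net"), "unknown model family")
})

test_that("balanced weighting is inverse class frequency with mean one", {
  y <- rep(c(1, 0), times = c(20, 80))
  w <- tissueACP:::.balanced_weights(y)
  expect_equal(mean(w), 1)
  expect_equal(unique(w[y == 1]), 100 / (2 * 20))
  expect_equal(unique(w[y == 0]), 100 / (2 * 80))
  expect_equal(unique(w[y == 1]) / unique(w[y == 0]), (1 / 0.2) / (1 / 0.8))
})

test_that("scale-sensitive training standardizes with train moments only", {
  co <- small_cohort(15, seed = 21)
  X <- encode_dataset(co$dataset$records)
  task <- build_ovr_task(co$dataset, "Skin")
  sp <- group_train_test_split(task, 0.2, seed = 2)
  xtr <- X[sp$train_idx, ]
  m <- acp_train(xtr, task$labels[sp$train_idx], "logistic_regression")
  xs <- tissueACP:::.standardize_apply(xtr, m$scaler)
  nonconst <- apply(xtr, 2, sd) > 0
  expect_equal(unname(colMeans(xs)), rep(0, ncol(xs)), tolerance = 1e-9)
  expect_equal(unname(apply(xs[, nonconst], 2, sd)),
               rep(1, sum(nonconst)), tolerance = 1e-9)
  # constant columns are centred to 0, not rescaled to NaN
  expect_true(all(is.finite(xs)))
  expect_true(all(abs(xs[, !nonconst]) < 1e-12))
  # tree families carry no scaler
  m2 <- acp_train(xtr, task$labels[sp$train_idx], "xgboost",
                  params = list(n_estimators = 10))
  expect_null(m2$scaler)
})

test_that("gradient boosting defaults its positive-class scale to n_neg/n_pos", {
  set.seed(4)
  x <- matrix(rnorm(100 * 5), 100, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- rep(c(1L, 0L), times = c(20, 80))
  m <- acp_train(x, y, "xgboost", params = list(n_estimators = 5))
  expect_equal(m$params$scale_pos_weight, 4)
  m2 <- acp_train(x, y, "xgboost",
                  params = list(n_estimators = 5, scale_pos_weight = 2))
  expect_equal(m2$params$scale_pos_weight, 2)
})

test_that("every family separates a strong compositional signal at training time", {
  # positives are heavily lysine-enriched: AAC_K alone separates the classes
  set.seed(55)
  pos_w <- setNames(rep(1, 20), AA_ALPHABET); pos_w["K"] <- 60
  pos <- vapply(1:30, function(i)
    paste(sample(AA_ALPHABET, 15, TRUE, prob = pos_w), collapse = ""), character(1))
  neg <- rand_seqs(30, 15, 15)
  X <- encode_dataset(c(pos, neg))
  y <- rep(c(1L, 0L), each = 30)
  good <- list(svm_linear = list(C = 10),
               random_forest = list(n_estimators = 100, max_depth = 10,
                                    min_samples_leaf = 5),
               logistic_regression = list(C = 10, penalty = "l2", solver = "lbfgs"),
               knn = list(n_neighbors = 3, weights = "distance", metric = "euclidean"),
               xgboost = list(learning_rate = 0.3, max_depth = 3, n_estimators = 50))
  for (fam in MODEL_FAMILIES) {
    m <- acp_train(X, y, fam, params = good[[fam]])
    panel <- compute_panel(y, predict(m, X))
    expect_equal(unname(panel$metrics["mcc"]), 1,
                 tolerance = 1e-9, label = paste(fam, "training MCC"))
  }
})

test_that("predictions are probabilities, threshold at 0.5, and are reproducible", {
  co <- small_cohort(10, seed = 31)
  X <- encode_dataset(co$dataset$records)
  task <- build_ovr_task(co$dataset, "Blood")
  sp <- group_train_test_split(task, 0.2, seed = 3)
  xtr <- X[sp$train_idx, ]; ytr <- task$labels[sp$train_idx]
  xte <- X[sp$test_idx, ]
  for (fam in c("svm_linear", "logistic_regression", "knn")) {
    p1 <- predict(acp_train(xtr, ytr, fam), xte)
    p2 <- predict(acp_train(xtr, ytr, fam), xte)
    expect_identical(p1, p2, label = paste(fam, "reproducibility"))
    expect_true(all(p1 >= 0 & p1 <= 1))
    hard <- predict(acp_train(xtr, ytr, fam), xte, type = "class")
    expect_identical(hard, as.integer(p1 >= 0.5))
  }
  # schema mismatch is refused
  m <- acp_train(xtr, ytr, "xgboost", params = list(n_estimators = 5))
  xbad <- xte[, c(2:ncol(xte), 1)]
  expect_error(predict(m, xbad), "schema mismatch")
  expect_error(acp_train(xtr, rep(1L, nrow(xtr)), "xgboost"), "both classes")
})

test_that("randomized search is exhaustive on small grids and deterministic under seed", {
  co <- small_cohort(12, seed = 41)
  X <- encode_dataset(co$dataset$records)
  task <- build_ovr_task(co$dataset, "Lung")
  groups <- task$records$sequence
  t1 <- tune_model(X, task$labels, groups, "svm_linear", k = 3, n_draws = 50,
                   seed = 5)
  expect_identical(nrow(t1$cv_table), 5L)  # all 5 C values evaluated once
  t2 <- tune_model(X, task$labels, groups, "svm_linear", k = 3, n_draws = 50,
                   seed = 5)
  expect_identical(t1$best_params, t2$best_params)
  expect_equal(t1$cv_table$mean_auc_pr, t2$cv_table$mean_auc_pr)
  # a planted strong signal beats the no-skill AUC-PR baseline
  prevalence <- mean(task$labels)
  expect_gt(t1$best_score, prevalence)
})
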