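{
  "svm_linear": {
    "C": [0.001, 0.01, 0.1, 1, 10],
    "kernel": ["linear"]
  },
  "random_forest": {
    "n_estimators": [10, 50, 100, 200],
    "max_depth": [2, 3, 5, 7, 10],
    "min_samples_leaf": [5, 10, 20]
  },
  "logistic_regression": {
    "C": [0.001, 0.01, 0.1, 1, 10],
    "penalty": ["l1", "l2"],
    "solver": ["liblinear", "lbfgs", "saga"]
  },
  "knn": {
    "n_neighbors": [3, 5, 7, 9, 11],
    "weights": ["uniform", "distance"],
    "metric": ["manhattan", "euclidean"]
  },
  "xgboost": {
    "learning_rate": [0.01, 0.05, 0.1, 0.3],
    "max_depth": [3, 5, 7],
    "n_estimators": [50, 100, 200],
    "subsample": [0.8, 1.0],
    "colsample_bytree": [0.8, 1.0]
  }
}
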