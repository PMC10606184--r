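# Independent brute-force implementations used as oracles. These deliberately
# avoid the package's own code paths: counts are tallied from raw label pairs
# or by explicit cell-by-cell loops, and F1 goes through precision/recall.

oracle_counts_from_pairs <- function(truth, pred, cl) {
  truth <- as.character(truth); pred <- as.character(pred)
  c(TP = sum(truth == cl & pred == cl),
    TN = sum(truth != cl & truth == pred),  # correctly classified other-class
    FP = sum(truth != cl & pred == cl),
    FN = sum(truth == cl & pred != cl))
}

oracle_counts_from_cm <- function(cm, ci) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
    n <- cm[i, j]
    if (i == ci && j == ci) tp <- tp + n
    else if (i == ci) fn <- fn + n
    else if (j == ci) fp <- fp + n
    else if (i == j) tn <- tn + n
  }
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

oracle_f1_harmonic <- function(tp, fp, fn) {
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  if (is.nan(p) || is.nan(r) || p + r == 0) return(0)
  2 * p * r / (p + r)
}

random_confusion_matrix <- function(K = 4, lambda = 8) {
  m <- matrix(rpois(K * K, lambda), K,
              dimnames = list(paste0("c", 1:K), paste0("c", 1:K)))
  diag(m) <- diag(m) + rpois(K, 3 * lambda)  # realistic diagonal dominance
  m
}

# independent re-computation of the panel-fitness chain for given fold splits:
# direct e1071 fit, raw-pair counting, harmonic-mean F1, mean per class, min
oracle_min_f1_fitness <- function(X, y, splits) {
  classes <- levels(y)
  f1 <- matrix(NA_real_, length(classes), length(splits),
               dimnames = list(classes, NULL))
  for (i in seq_along(splits)) {
    test <- splits[[i]]
    train <- setdiff(seq_along(y), test)
    g <- 1 / (ncol(X) * mean((X[train, ] - mean(X[train, ]))^2))
    fit <- e1071::svm(x = X[train, , drop = FALSE], y = droplevels(y[train]),
                      kernel = "linear", cost = 1, gamma = g, scale = FALSE)
    pred <- as.character(predict(fit, X[test, , drop = FALSE]))
    for (cl in classes) {
      v <- oracle_counts_from_pairs(y[test], pred, cl)
      f1[cl, i] <- oracle_f1_harmonic(v[["TP"]], v[["FP"]], v[["FN"]])
    }
  }
  min(rowMeans(f1))
}
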