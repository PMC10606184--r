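#' Multiclass confusion matrix
#'
#' @param truth,pred vectors of true and predicted labels.
#' @param classes class levels fixing row/column order (default: union of
#'   observed levels, sorted).
#' @return square integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  if (is.null(classes))
    classes <- sort(unique(c(as.character(truth), as.character(pred))))
  t <- table(factor(truth, levels = classes), factor(pred, levels = classes))
  m <- matrix(as.integer(t), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' One-vs-all outcome counts for a class
#'
#' Uses the one-vs-all convention in which, scoring class `c`, TP is the
#' count of class-`c` samples classified as `c`, FN class-`c` samples
#' classified as anything else, FP other-class samples classified as `c`,
#' and TN the sum of *correctly classified* other-class samples (the other
#' diagonal entries). Note this TN differs from the textbook binarized
#' convention ("any non-`c` sample predicted non-`c`"): a class-a sample
#' misclassified as class b (both different from `c`) counts in neither TN
#' nor any other cell for class `c`, so the four counts need not sum to the
#' test-set size. The textbook convention is available with
#' `convention = "standard"`. Worked example: with
#' `cm = rbind(c(5,0,0), c(2,3,0), c(0,0,4))` both conventions give TN = 7
#' for class 1, but for class 3 the diagonal convention gives TN = 5 + 3 = 8
#' while the standard one gives 14 - 4 - 0 - 0 = 10, because the two class-2
#' samples misclassified as class 1 still count as "predicted non-3".
#'
#' @param cm square confusion matrix (rows = true, columns = predicted).
#' @param class class name or index.
#' @param convention `"diagonal"` (default, as described) or `"standard"`.
#' @return named integer vector `c(TP, TN, FP, FN)`.
#' @export
one_vs_all_counts <- function(cm, class, convention = c("diagonal",
                                                        "standard")) {
  convention <- match.arg(convention)
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (is.character(class)) {
    class <- match(class, rownames(cm))
    if (is.na(class)) stop("class not present in confusion matrix")
  }
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- if (convention == "diagonal") sum(diag(cm)) - tp
        else sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Accuracy and F1-score from one-vs-all counts
#'
#' `ova_accuracy` is `(TP + TN) / (TP + TN + FP + FN)`; `f1_score` is
#' `TP / (TP + 0.5 (FP + FN))`, the harmonic mean of precision and recall.
#' F1 is 0 when TP = 0 with misclassifications present, and *undefined*
#' (an error) when TP = FP = FN = 0 — a class absent from both truth and
#' predictions has no meaningful score and surfacing it loudly beats a
#' silent 0 or 1.
#'
#' @param tp,tn,fp,fn non-negative counts, or a named vector from
#'   [one_vs_all_counts()] passed as `tp`.
#' @return scalar in `[0, 1]`.
#' @export
ova_accuracy <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (is.null(tn)) { v <- tp; tp <- v[["TP"]]; tn <- v[["TN"]]
                     fp <- v[["FP"]]; fn <- v[["FN"]] }
  denom <- tp + tn + fp + fn
  if (denom == 0) stop("accuracy undefined: all counts zero")
  (tp + tn) / denom
}

#' @rdname ova_accuracy
#' @export
f1_score <- function(tp, fp = NULL, fn = NULL) {
  if (is.null(fp)) { v <- tp; tp <- v[["TP"]]; fp <- v[["FP"]]
                     fn <- v[["FN"]] }
  if (tp == 0 && fp == 0 && fn == 0)
    stop("F1 undefined: class absent from truth and predictions")
  tp / (tp + 0.5 * (fp + fn))
}

#' Per-fold evaluation report
#'
#' @param truth,pred labels for one test fold.
#' @param classes class levels.
#' @param fold fold index (metadata).
#' @param convention TN convention, see [one_vs_all_counts()].
#' @return a `fold_report`: list with `fold`, `cm`, `per_class` (data.frame
#'   of TP/TN/FP/FN, one-vs-all accuracy and F1 per class) and
#'   `overall_accuracy` (trace / total).
#' @export
fold_report <- function(truth, pred, classes = NULL, fold = 1L,
                        convention = "diagonal") {
  cm <- confusion_matrix(truth, pred, classes)
  classes <- rownames(cm)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    v <- one_vs_all_counts(cm, cl, convention)
    data.frame(class = cl, TP = v[["TP"]], TN = v[["TN"]], FP = v[["FP"]],
               FN = v[["FN"]], accuracy = ova_accuracy(v),
               f1 = f1_score(v), stringsAsFactors = FALSE)
  }))
  structure(list(fold = fold, cm = cm, per_class = per_class,
                 overall_accuracy = sum(diag(cm)) / sum(cm)),
            class = "fold_report")
}

#' Cross-validation configuration
#'
#' Two splitting schemes are provided for the "70/30 split with five-fold
#' cross-validation" design: `"kfold5"` (default) is plain stratified k-fold
#' cross-validation with `n_splits` folds, so each fold's test share is
#' 1/k; `"shuffle70"` is `n_splits` repeated stratified 70/30 shuffle
#' splits. The scheme used is recorded in every report.
#'
#' @param mode `"kfold5"` or `"shuffle70"`.
#' @param n_splits number of folds / repeats.
#' @param train_fraction train share for shuffle mode.
#' @param seed seed for fold assignment and classifier fits.
#' @param convention TN convention for per-class metrics.
#' @return a `cv_config` list.
#' @export
cv_config <- function(mode = c("kfold5", "shuffle70"), n_splits = 5L,
                      train_fraction = 0.7, seed = 1L,
                      convention = "diagonal") {
  mode <- match.arg(mode)
  structure(list(mode = mode, n_splits = as.integer(n_splits),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 convention = convention),
            class = "cv_config")
}

# Stratified k-fold with balanced remainders: every class's samples are
# spread over folds with counts differing by at most one, and each class's
# remainder goes to the currently smallest folds, so total fold sizes are
# always the balanced partition of n (e.g. 678 -> 136,136,136,135,135).
stratified_kfold <- function(y, k) {
  y <- factor(y)
  sizes <- integer(k)
  folds <- replicate(k, integer(0), simplify = FALSE)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    n <- length(idx)
    per <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) {
      ord <- order(sizes, sample.int(k))  # random tie-break among equals
      per[ord[seq_len(extra)]] <- per[ord[seq_len(extra)]] + 1L
    }
    stops <- cumsum(per)
    starts <- c(1L, utils::head(stops, -1) + 1L)
    for (f in seq_len(k)) {
      if (per[f] > 0)
        folds[[f]] <- c(folds[[f]], idx[starts[f]:stops[f]])
      sizes[f] <- sizes[f] + per[f]
    }
  }
  stats::setNames(folds, paste0("Fold", seq_len(k)))
}

# stratified test-index sets for each split
make_splits <- function(y, cv) {
  with_seed(cv$seed, {
    if (cv$mode == "kfold5") {
      stratified_kfold(y, cv$n_splits)
    } else {
      train <- caret::createDataPartition(y, times = cv$n_splits,
                                          p = cv$train_fraction)
      lapply(train, function(tr) setdiff(seq_along(y), tr))
    }
  })
}

#' Cross-validated evaluation of one classifier on a fixed panel
#'
#' Splits the labeled cohort per `cv`, trains on each training portion and
#' evaluates the held-out portion, producing per-fold reports, their means,
#' and the aggregated (summed over folds) confusion matrix.
#'
#' @param gm labeled [genotype_matrix()].
#' @param panel an `snp_panel` (see [run_ga()]) or a character vector of
#'   feature keys; these columns form the classifier input.
#' @param spec a [classifier_spec()].
#' @param cv a [cv_config()].
#' @return a `cv_report`: list with `folds` (list of [fold_report()]s),
#'   `mean_accuracy` (mean overall accuracy across folds), `mean_f1` (named
#'   per-class means), `min_f1`, `aggregated_cm`, and provenance
#'   (`cv`, `spec`, `panel_size`).
#' @export
cross_validate <- function(gm, panel, spec, cv = cv_config()) {
  if (is.null(gm$labels)) stop("cohort matrix must be labeled")
  keys <- if (inherits(panel, "snp_panel")) panel$assembled else panel
  X <- subset_features(gm, keys)
  y <- factor(gm$labels)
  splits <- make_splits(y, cv)
  folds <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    test <- splits[[i]]
    train <- setdiff(seq_along(y), test)
    missing <- setdiff(levels(y), unique(as.character(y[train])))
    if (length(missing) > 0)
      stop("class absent from training split ", i, ": ",
           paste(missing, collapse = ", "))
    fit_spec <- spec
    fit_spec$seed <- spec$seed + i
    model <- fit_classifier(fit_spec, X[train, , drop = FALSE], y[train])
    pred <- predict(model, X[test, , drop = FALSE])
    folds[[i]] <- fold_report(y[test], pred, classes = levels(y), fold = i,
                              convention = cv$convention)
  }
  per_class_f1 <- sapply(folds, function(f) f$per_class$f1)
  rownames(per_class_f1) <- folds[[1]]$per_class$class
  mean_f1 <- rowMeans(per_class_f1)
  agg <- Reduce(`+`, lapply(folds, `[[`, "cm"))
  structure(list(folds = folds,
                 mean_accuracy = mean(vapply(folds, `[[`, 1,
                                             "overall_accuracy")),
                 mean_f1 = mean_f1, min_f1 = min(mean_f1),
                 aggregated_cm = agg, cv = cv, spec = spec,
                 panel_size = length(keys)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report (", x$cv$mode, ", ", length(x$folds), " splits): ",
      "mean accuracy ", round(x$mean_accuracy, 4), "\n", sep = "")
  print(round(x$mean_f1, 4))
  invisible(x)
}

#' Benchmark several classifier presets on one panel
#'
#' Runs [cross_validate()] for each preset and assembles the standard
#' benchmark table: one row per classifier with its mean overall accuracy
#' and mean per-class one-vs-all F1-scores; the best row is the one with
#' the highest minimum per-class F1.
#'
#' @inheritParams cross_validate
#' @param presets named list of [classifier_spec()]s (default: all six).
#' @return a `benchmark_report`: list with `table` (data.frame), `reports`
#'   (named list of `cv_report`s) and `best` (name of the best preset).
#' @export
benchmark_classifiers <- function(gm, panel, presets = classifier_presets(),
                                  cv = cv_config()) {
  reports <- lapply(presets, function(sp) cross_validate(gm, panel, sp, cv))
  tab <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    cbind(data.frame(classifier = nm, accuracy = r$mean_accuracy),
          as.data.frame(as.list(r$mean_f1), check.names = FALSE),
          data.frame(min_f1 = r$min_f1))
  }))
  rownames(tab) <- NULL
  structure(list(table = tab, reports = reports,
                 best = tab$classifier[which.max(tab$min_f1)]),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, 4)
  print(tab, row.names = FALSE)
  cat("best by minimum per-class F1:", x$best, "\n")
  invisible(x)
}

#' Serialize / restore a benchmark report
#'
#' JSON round-trip of the benchmark table, per-fold confusion matrices and
#' metrics, and run provenance.
#'
#' @param report a `benchmark_report`.
#' @param path JSON file path.
#' @export
write_benchmark_json <- function(report, path) {
  ser <- list(
    table = report$table,
    best = report$best,
    reports = lapply(report$reports, function(r) list(
      mode = r$cv$mode, seed = r$cv$seed, panel_size = r$panel_size,
      mean_accuracy = r$mean_accuracy, mean_f1 = as.list(r$mean_f1),
      min_f1 = r$min_f1,
      aggregated_cm = as.data.frame(r$aggregated_cm),
      folds = lapply(r$folds, function(f) list(
        fold = f$fold, cm = as.data.frame(f$cm),
        per_class = f$per_class, overall_accuracy = f$overall_accuracy)))))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_benchmark_json
#' @export
read_benchmark_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
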