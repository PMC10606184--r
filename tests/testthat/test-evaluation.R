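test_that("one-vs-all counts follow the correct-other-diagonal TN convention", {
  d <- diag(c(10, 5, 3, 2))
  dimnames(d) <- list(paste0("c", 1:4), paste0("c", 1:4))
  expect_equal(one_vs_all_counts(d, "c1"), c(TP = 10, TN = 10, FP = 0, FN = 0))

  cm2 <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(one_vs_all_counts(cm2, "a"), c(TP = 8, TN = 9, FP = 1, FN = 2))

  z <- matrix(0, 4, 4, dimnames = list(paste0("c", 1:4), paste0("c", 1:4)))
  z[2, 2] <- 7
  expect_equal(one_vs_all_counts(z, "c1"), c(TP = 0, TN = 7, FP = 0, FN = 0))

  expect_error(one_vs_all_counts(matrix(0, 2, 3), 1), "square")
})

test_that("the two TN conventions differ exactly by off-target misclassification", {
  cm <- matrix(c(5, 0, 0,
                 2, 3, 0,
                 0, 0, 4), 3, byrow = TRUE,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # class a: both conventions agree (all misclassification touches column a)
  expect_equal(one_vs_all_counts(cm, "a"),
               one_vs_all_counts(cm, "a", convention = "standard"))
  # class c: the two b->a misclassified samples count only under "standard"
  expect_equal(one_vs_all_counts(cm, "c")[["TN"]], 8)
  expect_equal(one_vs_all_counts(cm, "c", convention = "standard")[["TN"]], 10)
})

test_that("accuracy and F1 match the stated formulas and edge conventions", {
  expect_equal(ova_accuracy(5, 5, 0, 0), 1.0)
  expect_equal(f1_score(5, 0, 0), 1.0)
  expect_equal(f1_score(8, 2, 2), 0.8)     # 8 / (8 + 0.5 * 4)
  expect_equal(f1_score(0, 3, 1), 0)       # no true positives
  expect_error(f1_score(0, 0, 0), "undefined")
  expect_error(ova_accuracy(0, 0, 0, 0), "undefined")
})

test_that("metrics agree exactly with brute-force oracles on random matrices", {
  set.seed(101)
  for (r in 1:200) {
    cm <- random_confusion_matrix()
    ci <- sample(4, 1)
    v <- one_vs_all_counts(cm, ci)
    expect_equal(unname(v), unname(oracle_counts_from_cm(cm, ci)))
    if (!(v[["TP"]] == 0 && v[["FP"]] == 0 && v[["FN"]] == 0)) {
      expect_equal(f1_score(v),
                   oracle_f1_harmonic(v[["TP"]], v[["FP"]], v[["FN"]]))
    }
    expect_equal(ova_accuracy(v),
                 (v[["TP"]] + v[["TN"]]) / sum(v))
  }
})

test_that("stratified five-fold splits of 678 samples balance to 136/135", {
  y <- factor(rep(c("Poles", "Russians", "Serbs", "NonSlavs"),
                  c(127, 28, 20, 503)))
  for (seed in c(1, 42, 2024)) {
    splits <- aimpanel:::make_splits(y, cv_config(seed = seed))
    expect_equal(sort(unname(lengths(splits))), c(135L, 135L, 136L, 136L, 136L))
    expect_equal(sort(unname(unlist(splits))), seq_along(y))  # exact partition
    counts <- sapply(splits, function(s) table(y[s]))
    # per-class stratification: fold counts differ by at most one
    expect_true(all(apply(counts, 1, function(x) max(x) - min(x)) <= 1))
  }
})

test_that("per-class stratification keeps every class in every fold", {
  y <- factor(rep(c("a", "b", "c"), c(30, 10, 5)))
  splits <- aimpanel:::make_splits(y, cv_config(n_splits = 5L, seed = 3))
  counts <- sapply(splits, function(s) table(y[s]))
  expect_true(all(counts["a", ] == 6))
  expect_true(all(counts["b", ] == 2))
  expect_true(all(counts["c", ] == 1))
})

test_that("a perfectly separable panel scores 1.0 in every fold", {
  gm <- separable_gm(c(A = 12L, B = 10L, C = 10L, D = 11L))
  rep <- cross_validate(gm, colnames(gm$values),
                        classifier_presets("linear_svm")[[1]],
                        cv_config(seed = 8))
  expect_equal(rep$mean_accuracy, 1.0)
  expect_equal(unname(rep$mean_f1), rep(1.0, 4))
  for (f in rep$folds) {
    expect_equal(f$overall_accuracy, 1.0)
    expect_equal(f$per_class$f1, rep(1.0, 4))
  }
})

test_that("fold reports are internally consistent and re-derivable", {
  set.seed(15)
  gm <- make_gm(matrix(rbinom(40 * 12, 1, 0.35), 40, 12),
                labels = rep(c("a", "b", "c", "d"), 10))
  rep <- cross_validate(gm, colnames(gm$values),
                        classifier_spec("random_forest", seed = 2),
                        cv_config(seed = 4))
  total <- 0
  for (f in rep$folds) {
    n_test <- sum(f$cm)
    total <- total + n_test
    expect_equal(f$overall_accuracy, sum(diag(f$cm)) / n_test)
    for (r in seq_len(nrow(f$per_class))) {
      pc <- f$per_class[r, ]
      # diagonal-TN convention: the four counts never exceed the fold size
      expect_lte(pc$TP + pc$TN + pc$FP + pc$FN, n_test)
      std <- one_vs_all_counts(f$cm, pc$class, convention = "standard")
      expect_equal(sum(std), n_test)
      expect_equal(pc$f1, f1_score(pc$TP, pc$FP, pc$FN))
      expect_equal(pc$accuracy, ova_accuracy(pc$TP, pc$TN, pc$FP, pc$FN))
    }
  }
  # aggregated matrix is the elementwise fold sum and covers the cohort once
  expect_equal(rep$aggregated_cm, Reduce(`+`, lapply(rep$folds, `[[`, "cm")))
  expect_equal(sum(rep$aggregated_cm), nrow(gm$values))
  # means recompute from the stored per-fold reports (no hidden state)
  expect_equal(rep$mean_accuracy,
               mean(sapply(rep$folds, `[[`, "overall_accuracy")))
  expect_equal(unname(rep$mean_f1),
               unname(rowMeans(sapply(rep$folds, function(f) f$per_class$f1))))
})

test_that("metrics from fold reports match raw-pair recomputation", {
  set.seed(77)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.7, truth, sample(c("a", "b", "c"), 60,
                                                replace = TRUE))
  f <- fold_report(truth, pred, classes = c("a", "b", "c"))
  for (r in seq_len(3)) {
    v <- oracle_counts_from_pairs(truth, pred, f$per_class$class[r])
    expect_equal(unname(unlist(f$per_class[r, c("TP", "TN", "FP", "FN")])),
                 unname(v))
  }
  expect_equal(f$overall_accuracy, mean(truth == pred))
})

test_that("label-independent features give chance-level accuracy", {
  # with equal class shares, any classifier trained on permuted labels has
  # expected accuracy sum(p_c^2) = 1/K exactly, whatever its prediction rates
  set.seed(55)
  accs <- replicate(50, {
    X <- matrix(rbinom(60 * 20, 1, 0.3), 60, 20)
    gm <- make_gm(X, labels = sample(rep(c("a", "b", "c", "d"), 15)))
    cross_validate(gm, colnames(gm$values),
                   classifier_spec("random_forest",
                                   seed = sample.int(1e6, 1)),
                   cv_config(seed = sample.int(1e6, 1)))$mean_accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.25), 3 * se)
})

test_that("shuffle70 mode holds out a stratified 30% five times", {
  y <- factor(rep(c("a", "b"), c(70, 30)))
  cvc <- cv_config(mode = "shuffle70", seed = 6)
  splits <- aimpanel:::make_splits(y, cvc)
  expect_length(splits, 5L)
  for (s in splits) {
    expect_equal(length(s), 30L)
    expect_equal(as.integer(table(y[s])), c(21L, 9L))
  }
})

test_that("shrinking a class does not inflate its random-forest F1", {
  f1_big <- f1_small <- numeric(5)
  for (s in 1:5) {
    mk <- function(nA) {
      cc <- cohort_config(n_per_class = c(A = as.integer(nA), B = 60L,
                                          C = 60L, D = 60L),
                          n_background_sites = 150L, n_aims_per_class = 3L,
                          background_fst = 0.01, aim_delta = 0.3,
                          seed = 80L + s)
      cohort_matrix(simulate_cohort(cc), mode = "presence")
    }
    sp <- classifier_spec("random_forest", seed = 90L + s)
    cvc <- cv_config(seed = 95L + s)
    gac <- ga_config(pool_size_per_class = 12L, population_size = 12L,
                     generations = 6L, stagnation_patience = 3L,
                     seed = 85L + s)
    g_big <- mk(120); g_small <- mk(20)
    f1_big[s] <- cross_validate(g_big, run_ga(g_big, 3L, gac), sp,
                                cvc)$mean_f1[["A"]]
    f1_small[s] <- cross_validate(g_small, run_ga(g_small, 3L, gac), sp,
                                  cvc)$mean_f1[["A"]]
  }
  expect_lte(mean(f1_small), mean(f1_big))
})

test_that("benchmark table has one row per preset and survives serialization", {
  gm <- separable_gm()
  b <- benchmark_classifiers(gm, colnames(gm$values),
                             classifier_presets("linear_svm"),
                             cv_config(seed = 12))
  expect_equal(nrow(b$table), 1L)
  expect_equal(b$best, "linear_svm")

  b2 <- benchmark_classifiers(gm, colnames(gm$values),
                              classifier_presets(c("linear_svm",
                                                   "random_forest")),
                              cv_config(seed = 12))
  path <- tempfile(fileext = ".json")
  write_benchmark_json(b2, path)
  back <- read_benchmark_json(path)
  expect_equal(back$table$accuracy, b2$table$accuracy)
  expect_equal(back$table$min_f1, b2$table$min_f1)
  expect_equal(back$reports$linear_svm$mean_accuracy,
               b2$reports$linear_svm$mean_accuracy)
  expect_equal(unlist(back$reports$random_forest$mean_f1),
               b2$reports$random_forest$mean_f1)
})

test_that("a class absent from a training split is surfaced as an error", {
  gm1 <- separable_gm(c(A = 6L, B = 1L))
  expect_error(cross_validate(gm1, colnames(gm1$values),
                              classifier_presets("linear_svm")[[1]],
                              cv_config(n_splits = 2L, seed = 1)),
               "absent from training split")
})
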