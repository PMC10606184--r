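#' Classifier specifications and presets
#'
#' One uniform train/predict contract over the three benchmarked families:
#' support vector machines (four kernels), random forest, and gradient
#' boosted trees. The six frozen presets are:
#'
#' * `linear_svm`, `poly_svm`, `rbf_svm`, `sigmoid_svm` — SVM with `C = 1`,
#'   `gamma = "scale"` (1 / (n_features * Var(X)), the scikit-learn
#'   convention), polynomial degree 3, one-vs-one multiclass voting
#'   (via \pkg{e1071}/libsvm).
#' * `random_forest` — 100 trees, Gini impurity split rule, unlimited depth,
#'   minimum node size 1, bootstrap resampling (via \pkg{ranger}).
#' * `xgboost` — gbtree booster, `learning_rate = 0.3`, `max_depth = 6`,
#'   `lambda = 1`, `alpha = 0`, `min_child_weight = 1`, 100 boosting rounds
#'   (the round count is not part of the frozen hyperparameter set; it
#'   mirrors the common ecosystem default and is recorded in provenance),
#'   softmax multiclass objective (via \pkg{xgboost}).
#'
#' Class weighting is left at each family's unweighted default; the pipeline
#' deliberately does not rebalance classes.
#'
#' @param family one of `"svm"`, `"random_forest"`,
#'   `"gradient_boosted_trees"`.
#' @param kernel SVM kernel: `"linear"`, `"polynomial"`, `"rbf"`,
#'   `"sigmoid"`. Ignored for other families.
#' @param hyperparameters named list of overrides merged over the family
#'   defaults above.
#' @param seed integer seed used at fit time for the stochastic families.
#' @return a `classifier_spec` object.
#' @export
classifier_spec <- function(family = c("svm", "random_forest",
                                       "gradient_boosted_trees"),
                            kernel = NULL, hyperparameters = list(),
                            seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    svm = list(C = 1, gamma = "scale", degree = 3, coef0 = 0),
    random_forest = list(n_estimators = 100, criterion = "gini",
                         max_depth = NULL, min_samples_leaf = 1),
    gradient_boosted_trees = list(booster = "gbtree", learning_rate = 0.3,
                                  max_depth = 6, lambda = 1, alpha = 0,
                                  min_child_weight = 1, nrounds = 100))
  if (family == "svm") {
    if (is.null(kernel)) kernel <- "linear"
    if (!kernel %in% c("linear", "polynomial", "rbf", "sigmoid"))
      stop("unknown SVM kernel: ", kernel)
  } else kernel <- NULL
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, kernel = kernel, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @rdname classifier_spec
#' @param names optional subset of preset names to return.
#' @return `classifier_presets()` returns a named list of the six frozen
#'   `classifier_spec` presets.
#' @export
classifier_presets <- function(names = NULL, seed = 1L) {
  all <- list(
    linear_svm = classifier_spec("svm", "linear", seed = seed),
    poly_svm = classifier_spec("svm", "polynomial", seed = seed),
    rbf_svm = classifier_spec("svm", "rbf", seed = seed),
    sigmoid_svm = classifier_spec("svm", "sigmoid", seed = seed),
    random_forest = classifier_spec("random_forest", seed = seed),
    xgboost = classifier_spec("gradient_boosted_trees", seed = seed))
  if (is.null(names)) return(all)
  missing <- setdiff(names, names(all))
  if (length(missing) > 0)
    stop("unknown classifier presets: ", paste(missing, collapse = ", "))
  all[names]
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat("classifier_spec:", x$family,
      if (!is.null(x$kernel)) paste0("(", x$kernel, " kernel)"), "\n")
  invisible(x)
}

# scikit-learn "scale" gamma: 1 / (n_features * Var(all cells of X))
scale_gamma <- function(X) {
  v <- mean((X - mean(X))^2)
  if (v == 0) 1 / ncol(X) else 1 / (ncol(X) * v)
}

#' Train a classifier on a binary feature matrix
#'
#' @param spec a [classifier_spec()].
#' @param X numeric 0/1 matrix (samples x features) with column names; use
#'   [subset_features()] to extract a panel's columns.
#' @param y class labels (character or factor), one per row of `X`; at least
#'   two classes must be present.
#' @return an `aimpanel_model` carrying the fitted model, the spec, the
#'   training feature list and class levels. Fits are deterministic given
#'   `spec$seed`.
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X)
  y <- factor(y)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (nlevels(droplevels(y)) < 2)
    stop("training labels contain a single class: ", levels(droplevels(y)))
  y <- droplevels(y)
  if (length(X) > 0 && !all(X %in% c(0, 1)))
    stop("X must be a binary 0/1 matrix")
  hp <- spec$hyperparameters
  fit <- with_seed(spec$seed, switch(spec$family,
    svm = {
      gamma <- if (identical(hp$gamma, "scale")) scale_gamma(X) else hp$gamma
      kern <- c(linear = "linear", polynomial = "polynomial",
                rbf = "radial", sigmoid = "sigmoid")[[spec$kernel]]
      e1071::svm(x = X, y = y, kernel = kern, cost = hp$C, gamma = gamma,
                 degree = hp$degree, coef0 = hp$coef0, scale = FALSE)
    },
    random_forest = ranger::ranger(
      x = X, y = y, num.trees = hp$n_estimators, splitrule = hp$criterion,
      min.node.size = hp$min_samples_leaf, seed = spec$seed,
      probability = TRUE, num.threads = 1),
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(objective = "multi:softmax", num_class = nlevels(y),
                      booster = hp$booster, eta = hp$learning_rate,
                      max_depth = hp$max_depth, lambda = hp$lambda,
                      alpha = hp$alpha, min_child_weight = hp$min_child_weight,
                      nthread = 1, seed = spec$seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    }))
  structure(list(spec = spec, fit = fit, features = colnames(X),
                 classes = levels(y)),
            class = "aimpanel_model")
}

#' Predict class labels for new samples
#'
#' @param object an `aimpanel_model` from [fit_classifier()].
#' @param newdata binary matrix whose columns exactly match (names and order)
#'   the feature list the model was trained on.
#' @param ... unused.
#' @return factor of predicted labels (levels = training classes), one per
#'   row; predictions are row-wise independent.
#' @export
predict.aimpanel_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!identical(colnames(X), object$features))
    stop("prediction features do not match the model's training features")
  pred <- switch(object$spec$family,
    svm = as.character(stats::predict(object$fit, X)),
    random_forest = {
      # argmax of averaged class probabilities, first-max tie-break:
      # deterministic and row-wise independent (majority voting in ranger
      # breaks ties stochastically)
      probs <- stats::predict(object$fit, data = X,
                              num.threads = 1)$predictions
      colnames(probs)[max.col(probs, ties.method = "first")]
    },
    gradient_boosted_trees = {
      idx <- stats::predict(object$fit, xgboost::xgb.DMatrix(X))
      object$classes[as.integer(idx) + 1L]
    })
  factor(pred, levels = object$classes)
}
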