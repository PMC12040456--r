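#' The regression-family roster
#'
#' Families available to [grid_search()] and the pipeline, in roster order
#' (used for tie-breaking): k-nearest neighbours, elastic net, ordinary
#' linear regression, epsilon- and nu-support-vector regression, a single
#' decision tree, gradient boosting, random forest, AdaBoost.R2 and
#' XGBoost.
#'
#' @return Character vector of family identifiers.
#' @export
roster_families <- function() {
  c("knn", "elastic_net", "linear", "svr", "nusvr", "decision_tree",
    "gradient_boosting", "random_forest", "adaboost", "xgboost")
}

default_params <- function(family) {
  switch(family,
    knn = list(k = 5),
    elastic_net = list(alpha = 0.5, lambda = 0.01),
    linear = list(),
    svr = list(cost = 1, epsilon = 0.1),
    nusvr = list(cost = 1, nu = 0.5),
    decision_tree = list(maxdepth = 10, minsplit = 5, cp = 0.01),
    gradient_boosting = list(nrounds = 100, eta = 0.1, max_depth = 3),
    random_forest = list(num_trees = 100, max_depth = 10, min_node_size = 5),
    adaboost = list(nrounds = 50, maxdepth = 4),
    xgboost = list(nrounds = 100, eta = 0.3, max_depth = 6),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

#' Create a model specification
#'
#' @param family One of [roster_families()].
#' @param params Named list of hyperparameters overriding the family
#'   defaults. Random-forest defaults follow the tuned configuration
#'   (100 trees, max depth 10, min node size 5).
#' @return A `model_spec`.
#' @export
make_model <- function(family, params = list()) {
  defaults <- default_params(family)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(params)] <- params
  structure(list(family = family, params = defaults), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  } else "defaults"
  cat("<model_spec> ", x$family, " (", ps, ")\n", sep = "")
  invisible(x)
}

#' Fit a model specification
#'
#' Dispatches to the backing implementation of the family. All stochastic
#' families are seeded so fits are reproducible; deterministic families
#' ignore the seed.
#'
#' @param spec A `model_spec` from [make_model()].
#' @param x Numeric feature matrix.
#' @param y Numeric target vector.
#' @param seed Integer seed for stochastic families.
#' @return A `model_fit`.
#' @export
fit_model <- function(spec, x, y, seed = 0L) {
  p <- spec$params
  feature_names <- colnames(x)
  fit <- switch(spec$family,
    linear = {
      df <- as.data.frame(x)
      df$.y <- y
      stats::lm(.y ~ ., data = df)
    },
    elastic_net = glmnet::glmnet(x, y, alpha = p$alpha, lambda = p$lambda),
    knn = caret::knnreg(x, y, k = p$k),
    svr = e1071::svm(x, y, type = "eps-regression", cost = p$cost,
                     epsilon = p$epsilon, scale = FALSE),
    nusvr = e1071::svm(x, y, type = "nu-regression", cost = p$cost,
                       nu = p$nu, scale = FALSE),
    decision_tree = {
      df <- as.data.frame(x)
      df$.y <- y
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(maxdepth = p$maxdepth,
                                                  minsplit = p$minsplit,
                                                  cp = p$cp))
    },
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = y, num.trees = p$num_trees,
      max.depth = p$max_depth, min.node.size = p$min_node_size,
      importance = "impurity", seed = seed, num.threads = 1
    ),
    gradient_boosting = fit_xgb(x, y, p, seed),
    xgboost = fit_xgb(x, y, p, seed),
    adaboost = fit_adaboost_r2(x, y, nrounds = p$nrounds,
                               maxdepth = p$maxdepth),
    stop("unknown model family: ", spec$family, call. = FALSE)
  )
  structure(list(spec = spec, fit = fit, feature_names = feature_names),
            class = "model_fit")
}

fit_xgb <- function(x, y, p, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(
    params = list(eta = p$eta, max_depth = p$max_depth,
                  objective = "reg:squarederror", nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = p$nrounds, verbose = 0
  )
}

#' Predict from a fitted model
#'
#' @param fit A `model_fit` from [fit_model()].
#' @param x Feature matrix with the training columns.
#' @return Numeric vector of predictions.
#' @export
predict_model <- function(fit, x) {
  if (!identical(colnames(x), fit$feature_names)) {
    x <- x[, fit$feature_names, drop = FALSE]
  }
  family <- fit$spec$family
  if (family %in% c("linear", "decision_tree")) {
    # One-hot colour indicators sum to 1, so the linear design is
    # rank-deficient with an intercept; predictions are still estimable on
    # any valid encoding, so that specific predict.lm warning is muffled.
    withCallingHandlers(
      as.numeric(stats::predict(fit$fit, newdata = as.data.frame(x))),
      warning = function(w) {
        if (grepl("rank-deficient", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  } else if (family == "elastic_net") {
    as.numeric(stats::predict(fit$fit, newx = x,
                              s = fit$spec$params$lambda))
  } else if (family == "random_forest") {
    stats::predict(fit$fit, data = as.data.frame(x),
                   num.threads = 1)$predictions
  } else if (family %in% c("gradient_boosting", "xgboost")) {
    as.numeric(stats::predict(fit$fit, xgboost::xgb.DMatrix(x)))
  } else if (family == "adaboost") {
    predict_adaboost_r2(fit$fit, x)
  } else {
    as.numeric(stats::predict(fit$fit, x))
  }
}

#' Per-encoded-column impurity-reduction totals of a fitted ensemble
#'
#' Returns the raw per-feature impurity importances of a fitted
#' tree-based model (random forest, gradient boosting, XGBoost or a single
#' decision tree), named by encoded column. Families without an impurity
#' notion raise an error.
#'
#' @param fit A `model_fit`.
#' @return Named numeric vector over the training feature columns
#'   (absent/unused columns carry 0).
#' @export
importance_values <- function(fit) {
  family <- fit$spec$family
  out <- stats::setNames(numeric(length(fit$feature_names)),
                         fit$feature_names)
  if (family == "random_forest") {
    imp <- fit$fit$variable.importance
    out[names(imp)] <- imp
  } else if (family %in% c("gradient_boosting", "xgboost")) {
    imp <- xgboost::xgb.importance(model = fit$fit)
    if (nrow(imp) > 0) out[imp$Feature] <- imp$Gain
  } else if (family == "decision_tree") {
    imp <- fit$fit$variable.importance
    if (!is.null(imp)) out[names(imp)] <- imp
  } else {
    stop("family '", family, "' does not provide impurity importances",
         call. = FALSE)
  }
  out
}
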