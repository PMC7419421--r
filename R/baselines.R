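#' Specify a comparator classifier
#'
#' Comparators consume the same autoencoder features as the CNN and are
#' tuned by exhaustive grid search with inner stratified cross-validation
#' on the training data only, then refit on all of it with the winning
#' configuration.
#'
#' Supported methods: `"random_forest"` (randomForest) and
#' `"gradient_boosting"` (xgboost, multi-class softprob). A recurrent-net
#' comparator is part of the design space but not provided by this build;
#' requesting it raises an informative error.
#'
#' @param method comparator name.
#' @param grid named list: hyperparameter name -> vector of candidate
#'   values. Defaults are small, desk-scale grids:
#'   random forest `ntree` in 100/300 and `nodesize` in 1/5; gradient
#'   boosting `nrounds` in 50/100 and `max_depth` in 3/6.
#' @param inner_cv_folds folds of the inner tuning CV (default 3).
#' @param seed RNG seed for tuning splits and the final fit.
#' @return object of class `baseline_spec`.
#' @export
baseline_spec <- function(method = c("random_forest", "gradient_boosting",
                                     "recurrent_net"),
                          grid = NULL, inner_cv_folds = 3, seed = 1L) {
  method <- match.arg(method)
  if (method == "recurrent_net")
    stop("the recurrent-net comparator is not provided by this build; ",
         "use 'random_forest' or 'gradient_boosting'")
  allowed <- switch(method,
    random_forest = c("ntree", "mtry", "nodesize", "maxnodes"),
    gradient_boosting = c("nrounds", "max_depth", "eta", "subsample",
                          "colsample_bytree", "min_child_weight"))
  if (is.null(grid))
    grid <- switch(method,
      random_forest = list(ntree = c(100, 300), nodesize = c(1, 5)),
      gradient_boosting = list(nrounds = c(50, 100), max_depth = c(3, 6)))
  if (!length(grid) || is.null(names(grid)) || any(names(grid) == ""))
    stop("grid must be a non-empty named list")
  unknown <- setdiff(names(grid), allowed)
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", method, ": ",
         paste(unknown, collapse = ", "),
         " (allowed: ", paste(allowed, collapse = ", "), ")")
  structure(list(method = method, grid = grid,
                 inner_cv_folds = as.integer(inner_cv_folds),
                 seed = as.integer(seed)),
            class = "baseline_spec")
}

fit_baseline_once <- function(method, params, x, y_factor, seed) {
  set.seed(seed)
  if (method == "random_forest") {
    do.call(randomForest::randomForest,
            c(list(x = x, y = y_factor), params))
  } else {
    m <- nlevels(y_factor)
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y_factor) - 1L)
    nrounds <- params$nrounds %||% 50
    params$nrounds <- NULL
    xgboost::xgb.train(
      params = c(list(objective = "multi:softprob", num_class = m,
                      nthread = 1, seed = seed), params),
      data = dtrain, nrounds = nrounds, verbose = 0)
  }
}

#' Fit a tuned comparator classifier
#'
#' Exhaustive grid search over `spec$grid`, scored by accuracy under
#' inner stratified CV on the training data only, then a refit of the
#' winning configuration on all training data. The chosen configuration
#' is reported via `message()` and stored in the result.
#'
#' @param spec a [baseline_spec()].
#' @param features numeric matrix, samples x features.
#' @param labels character vector/factor, one per row.
#' @return object of class `baseline_model` exposing the same
#'   [predict_proba()] / [predict()] contract as the CNN classifier.
#' @export
fit_baseline <- function(spec, features, labels) {
  stopifnot(inherits(spec, "baseline_spec"))
  features <- as.matrix(features)
  labels <- as.character(labels)
  class_names <- sort(unique(labels))
  if (length(class_names) < 2) stop("need at least two classes")
  y_factor <- factor(labels, levels = class_names)
  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  scores <- numeric(nrow(combos))
  if (nrow(combos) > 1) {
    folds <- kfold_split(labels, spec$inner_cv_folds, stratified = TRUE,
                         seed = spec$seed)
    for (ci in seq_len(nrow(combos))) {
      params <- as.list(combos[ci, , drop = FALSE])
      acc <- vapply(folds, function(fold) {
        fit <- fit_baseline_once(spec$method, params,
                                 features[fold$train, , drop = FALSE],
                                 droplevels(y_factor[fold$train]),
                                 seed = spec$seed + ci)
        mdl <- structure(list(spec = spec, fit = fit,
                              class_names = levels(droplevels(y_factor[fold$train]))),
                         class = "baseline_model")
        mean(predict(mdl, features[fold$test, , drop = FALSE]) ==
               labels[fold$test])
      }, numeric(1))
      scores[ci] <- mean(acc)
    }
  }
  best <- as.list(combos[which.max(scores), , drop = FALSE])
  message(sprintf("fit_baseline[%s]: chose %s", spec$method,
                  paste(names(best), unlist(best), sep = "=", collapse = ", ")))
  fit <- fit_baseline_once(spec$method, best, features, y_factor,
                           seed = spec$seed)
  structure(list(spec = spec, fit = fit, class_names = class_names,
                 best_params = best, grid_scores = scores),
            class = "baseline_model")
}

#' @rdname predict_proba
#' @export
predict_proba.baseline_model <- function(object, features, ...) {
  features <- as.matrix(features)
  m <- length(object$class_names)
  if (object$spec$method == "random_forest") {
    p <- stats::predict(object$fit, features, type = "prob")
    p <- p[, object$class_names, drop = FALSE]
  } else {
    raw <- stats::predict(object$fit, xgboost::xgb.DMatrix(features))
    p <- if (is.matrix(raw)) raw else matrix(raw, ncol = m, byrow = TRUE)
    dimnames(p) <- list(rownames(features), object$class_names)
  }
  rownames(p) <- rownames(features)
  p
}

#' @rdname predict_proba
#' @export
predict.baseline_model <- function(object, features, ...) {
  p <- predict_proba(object, features)
  cls <- colnames(p)[max.col(p, ties.method = "first")]
  names(cls) <- rownames(p)
  cls
}

#' Paired comparison of classification methods
#'
#' Runs every requested method on identical cross-validation folds (and,
#' for feature-based methods, on features from the same per-fold
#' autoencoder fit), so differences reflect the classifiers rather than
#' the splits.
#'
#' @param data a labeled [cna_matrix()].
#' @param methods character vector among `"cnn"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"majority"`.
#' @param config a [pipeline_config()] providing autoencoder / CNN /
#'   baseline settings (its `classifier` field is ignored here).
#' @param k,repeats,seed,stratified as in [cross_validate()].
#' @return object of class `method_comparison`: `table` (one row per
#'   method with mean macro metrics) and `fold_metrics`.
#' @export
compare_methods <- function(data, methods = c("cnn", "random_forest",
                                              "gradient_boosting"),
                            config = pipeline_config(), k = 5, repeats = 1,
                            seed = 1L, stratified = TRUE) {
  stopifnot(inherits(data, "cna_matrix"))
  if (is.null(data$labels)) stop("compare_methods needs a labeled cohort")
  if (length(methods) < 2) stop("need at least two methods to compare")
  bad <- setdiff(methods, c("cnn", "random_forest", "gradient_boosting",
                            "majority"))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  class_names <- sort(unique(data$labels))
  fold_metrics <- NULL
  for (r in seq_len(repeats)) {
    folds <- kfold_split(data$labels, k, stratified, seed = seed + 1009L * (r - 1L))
    for (f in seq_along(folds)) {
      fold <- folds[[f]]
      fold_seed <- seed + 1009L * (r - 1L) + f
      train <- subset_cna(data, samples = fold$train)
      test <- subset_cna(data, samples = fold$test)
      scaled_tr <- scale_cna(train)
      scaled_te <- apply_scaling(test, scaled_tr$scale_divisor)
      if (config$use_autoencoder) {
        ae_args <- utils::modifyList(
          list(input_dim = ncol(train$values), encoder_widths = c(128, 32),
               code_dim = 16, seed = fold_seed),
          config$ae)
        ae <- build_autoencoder(do.call(autoencoder_spec, ae_args))
        if (config$pretrain) ae <- pretrain_layerwise(ae, scaled_tr)
        ae <- fine_tune(ae, scaled_tr)
        feat_tr <- encode(ae, scaled_tr)
        feat_te <- encode(ae, scaled_te)
      } else {
        feat_tr <- scaled_tr$values
        feat_te <- scaled_te$values
      }
      for (method in methods) {
        pred <- switch(method,
          cnn = {
            clf_args <- utils::modifyList(
              list(input_dim = ncol(feat_tr), n_classes = length(class_names),
                   seed = fold_seed),
              config$clf)
            clf <- build_classifier(do.call(classifier_spec, clf_args),
                                    class_names)
            clf <- train_classifier(clf, feat_tr, train$labels,
                                    validation_split = config$validation_split)
            predict(clf, feat_te)
          },
          majority = rep(names(which.max(table(train$labels))), nrow(feat_te)),
          {
            b_args <- utils::modifyList(list(method = method, seed = fold_seed),
                                        config$baseline)
            fit <- fit_baseline(do.call(baseline_spec, b_args),
                                feat_tr, train$labels)
            predict(fit, feat_te)
          })
        rep_ <- eval_report(test$labels, pred, class_names)
        fold_metrics <- rbind(fold_metrics, data.frame(
          method = method, repeat_ = r, fold = f, n_test = rep_$n,
          macro_precision = rep_$macro$macro_precision,
          macro_recall = rep_$macro$macro_recall,
          macro_f1 = rep_$macro$macro_f1,
          accuracy = rep_$macro$accuracy))
      }
    }
  }
  agg <- do.call(rbind, lapply(split(fold_metrics, fold_metrics$method)[unique(methods)],
    function(d) data.frame(
      method = d$method[1],
      macro_precision = mean(d$macro_precision),
      macro_recall = mean(d$macro_recall),
      macro_f1 = mean(d$macro_f1),
      accuracy = mean(d$accuracy))))
  rownames(agg) <- NULL
  structure(list(table = agg, fold_metrics = fold_metrics,
                 k = k, repeats = repeats, seed = seed),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("method_comparison: %d-fold x %d repeat(s), paired folds\n",
              x$k, x$repeats))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}
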