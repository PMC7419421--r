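#' Build a multiclass confusion matrix
#'
#' Entry (i, j) counts samples of true class i predicted as class j.
#'
#' @param truth,predicted character vectors of equal length.
#' @param class_names ordered class names; defaults to the sorted union
#'   of the observed values.
#' @return object of class `confusion_matrix`: `class_names` and an
#'   m x m integer `counts` matrix.
#' @export
confusion_matrix <- function(truth, predicted, class_names = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have the same length")
  if (length(truth) == 0) stop("empty prediction set")
  if (is.null(class_names))
    class_names <- sort(union(unique(truth), unique(predicted)))
  bad <- setdiff(union(truth, predicted), class_names)
  if (length(bad)) stop("values outside class_names: ", paste(bad, collapse = ", "))
  counts <- table(factor(truth, levels = class_names),
                  factor(predicted, levels = class_names))
  counts <- matrix(as.integer(counts), nrow = length(class_names),
                   dimnames = list(true = class_names, predicted = class_names))
  structure(list(class_names = class_names, counts = counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (rows = truth, columns = predicted):\n")
  print(x$counts)
  invisible(x)
}

#' Per-class one-vs-rest metrics
#'
#' Treats each class in turn as positive and all others as negative:
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, one-vs-rest accuracy
#' `(TP+TN)/total` and `F1 = 2PR/(P+R)`. A zero denominator yields 0 and
#' is flagged in `zero_division` (the degenerate all-wrong case gives
#' P = R = F1 = 0, the all-correct case gives all metrics 1).
#'
#' @param conf a [confusion_matrix()].
#' @return data.frame with one row per class: counts (`tp`, `fp`, `fn`,
#'   `tn`) and metrics (`precision`, `recall`, `accuracy`, `f1`,
#'   `zero_division`).
#' @export
per_class_metrics <- function(conf) {
  stopifnot(inherits(conf, "confusion_matrix"))
  cm <- conf$counts
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  accuracy <- (tp + tn) / total
  f1 <- safe_div(2 * precision * recall, precision + recall)
  data.frame(class = conf$class_names, tp = tp, fp = fp, fn = fn, tn = tn,
             precision = precision, recall = recall, accuracy = accuracy,
             f1 = f1,
             zero_division = (tp + fp == 0) | (tp + fn == 0) |
               (precision + recall == 0),
             row.names = NULL)
}

#' Macro-averaged metrics and overall accuracy
#'
#' Unweighted means of the per-class precision/recall/F1, plus two
#' accuracy readings: the headline overall multiclass accuracy
#' trace/total, and the macro mean of the per-class one-vs-rest
#' accuracies (which counts true negatives and is therefore higher).
#'
#' @param conf a [confusion_matrix()].
#' @param metrics optional precomputed [per_class_metrics()] result.
#' @return list: `macro_precision`, `macro_recall`, `macro_f1`,
#'   `accuracy` (overall), `macro_ovr_accuracy`.
#' @export
macro_average <- function(conf, metrics = per_class_metrics(conf)) {
  stopifnot(inherits(conf, "confusion_matrix"))
  list(macro_precision = mean(metrics$precision),
       macro_recall = mean(metrics$recall),
       macro_f1 = mean(metrics$f1),
       accuracy = sum(diag(conf$counts)) / sum(conf$counts),
       macro_ovr_accuracy = mean(metrics$accuracy))
}

#' Evaluate predictions against truth
#'
#' @inheritParams confusion_matrix
#' @return object of class `eval_report`: `confusion`, `per_class`
#'   (data.frame), `macro` (list), `n`.
#' @export
eval_report <- function(truth, predicted, class_names = NULL) {
  conf <- confusion_matrix(truth, predicted, class_names)
  pc <- per_class_metrics(conf)
  structure(list(confusion = conf, per_class = pc,
                 macro = macro_average(conf, pc), n = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d samples, %d classes\n", x$n,
              length(x$confusion$class_names)))
  print(x$per_class[, c("class", "precision", "recall", "accuracy", "f1")],
        digits = 4)
  m <- x$macro
  cat(sprintf("macro P %.4f | R %.4f | F1 %.4f | accuracy %.4f (macro one-vs-rest %.4f)\n",
              m$macro_precision, m$macro_recall, m$macro_f1, m$accuracy,
              m$macro_ovr_accuracy))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits a machine-readable JSON report, the confusion matrix as TSV and
#' a plain-text per-class table.
#'
#' @param report an [eval_report()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of paths written, invisibly.
#' @export
write_eval_report <- function(report, dir, prefix = "eval") {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pj <- file.path(dir, paste0(prefix, "_report.json"))
  jsonlite::write_json(list(per_class = report$per_class, macro = report$macro,
                            n = report$n), pj, auto_unbox = TRUE, digits = NA)
  pc <- file.path(dir, paste0(prefix, "_confusion.tsv"))
  utils::write.table(report$confusion$counts, pc, sep = "\t", quote = FALSE,
                     col.names = NA)
  pt <- file.path(dir, paste0(prefix, "_per_class.tsv"))
  utils::write.table(report$per_class, pt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(pj, pc, pt))
}

#' Misclassification profile of one true class
#'
#' Fractions of the source class's samples assigned to each predicted
#' class (the source row of the confusion matrix normalized to 1).
#'
#' @param conf a [confusion_matrix()].
#' @param source_class the true class to profile.
#' @return named numeric vector over predicted classes, summing to 1.
#' @export
misclassification_profile <- function(conf, source_class) {
  stopifnot(inherits(conf, "confusion_matrix"))
  if (!source_class %in% conf$class_names)
    stop("unknown class: ", source_class)
  row <- conf$counts[source_class, ]
  if (sum(row) == 0) stop("class '", source_class, "' has no evaluated samples")
  row / sum(row)
}

#' Seeded (stratified) k-fold split
#'
#' Partitions samples into k folds of near-equal size. With
#' `stratified = TRUE` (default) each class is dealt round-robin into the
#' folds after a seeded shuffle, so per-class fold sizes differ by at most
#' one; plain random splitting shuffles all samples together.
#'
#' @param labels character vector (or factor) of per-sample classes; only
#'   its length is used when `stratified = FALSE`.
#' @param k number of folds, `2 <= k <= n`.
#' @param stratified preserve class proportions per fold.
#' @param seed shuffle seed.
#' @return list of k elements, each `list(train = idx, test = idx)`; test
#'   sets partition `1..n`.
#' @export
kfold_split <- function(labels, k, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= n")
  set.seed(seed)
  assign_fold <- integer(n)
  if (stratified) {
    labels <- as.character(labels)
    small <- names(which(table(labels) < k))
    if (length(small))
      stop("class(es) smaller than k under stratification: ",
           paste(small, collapse = ", "))
    offset <- 0L
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign_fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)  # rotate start so fold sizes balance
    }
  } else {
    idx <- sample.int(n)
    assign_fold[idx] <- ((seq_len(n) - 1L) %% k) + 1L
  }
  lapply(seq_len(k), function(f)
    list(train = which(assign_fold != f), test = which(assign_fold == f)))
}

#' Configure the end-to-end pipeline used in cross-validation
#'
#' @param classifier `"cnn"` (the multi-scale network), or one of the
#'   comparators `"random_forest"`, `"gradient_boosting"`, `"majority"`
#'   (largest-training-class dummy).
#' @param use_autoencoder compress with the autoencoder before
#'   classification (TRUE, the two-stage design) or feed scaled CNA values
#'   directly.
#' @param pretrain run greedy layer-wise pretraining before fine-tuning.
#' @param ae named list of [autoencoder_spec()] overrides (e.g.
#'   `encoder_widths`, `code_dim`, `epochs`).
#' @param clf named list of [classifier_spec()] overrides.
#' @param baseline named list passed to [baseline_spec()] for comparator
#'   classifiers (e.g. `grid`).
#' @param validation_split monitored split inside [train_classifier()].
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(classifier = c("cnn", "random_forest",
                                           "gradient_boosting", "majority"),
                            use_autoencoder = TRUE, pretrain = TRUE,
                            ae = list(), clf = list(), baseline = list(),
                            validation_split = 0.1) {
  classifier <- match.arg(classifier)
  structure(list(classifier = classifier,
                 use_autoencoder = isTRUE(use_autoencoder),
                 pretrain = isTRUE(pretrain), ae = ae, clf = clf,
                 baseline = baseline, validation_split = validation_split),
            class = "pipeline_config")
}

# Fit the configured pipeline on one train split and predict one test
# split. Scaling divisor and all models are fitted on the training split
# only.
fit_predict_fold <- function(train, test, config, class_names, fold_seed) {
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
  labs_tr <- train$labels
  if (config$classifier == "cnn") {
    clf_args <- utils::modifyList(
      list(input_dim = ncol(feat_tr), n_classes = length(class_names),
           seed = fold_seed),
      config$clf)
    clf <- build_classifier(do.call(classifier_spec, clf_args), class_names)
    clf <- train_classifier(clf, feat_tr, labs_tr,
                            validation_split = config$validation_split)
    pred <- predict(clf, feat_te)
  } else if (config$classifier == "majority") {
    top <- names(which.max(table(labs_tr)))
    pred <- rep(top, nrow(feat_te))
  } else {
    b_args <- utils::modifyList(list(method = config$classifier, seed = fold_seed),
                                config$baseline)
    fit <- fit_baseline(do.call(baseline_spec, b_args), feat_tr, labs_tr)
    pred <- predict(fit, feat_te)
  }
  pred
}

#' Repeated (stratified) k-fold cross-validation of the pipeline
#'
#' For every repeat and fold, the scaling divisor, autoencoder and
#' classifier are fitted on the training fold only and evaluated on the
#' held-out fold; a leakage guard asserts that no sample appears in both.
#' Macro metrics are aggregated across all folds and repeats.
#'
#' @param data a labeled [cna_matrix()].
#' @param config a [pipeline_config()].
#' @param k folds (default 10).
#' @param repeats independent reshuffled repetitions (default 1).
#' @param seed split/models seed.
#' @param stratified stratify folds by class (default TRUE).
#' @return object of class `cv_result`: per-fold `reports` and `folds`,
#'   a `fold_metrics` data.frame, and `summary` with mean/sd (and range)
#'   of each macro metric.
#' @export
cross_validate <- function(data, config = pipeline_config(), k = 10,
                           repeats = 1, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(data, "cna_matrix"))
  if (is.null(data$labels)) stop("cross_validate needs a labeled cohort")
  class_names <- sort(unique(data$labels))
  reports <- list(); fold_sets <- list()
  fold_metrics <- NULL
  for (r in seq_len(repeats)) {
    folds <- kfold_split(data$labels, k, stratified, seed = seed + 1009L * (r - 1L))
    for (f in seq_along(folds)) {
      fold <- folds[[f]]
      if (length(intersect(fold$train, fold$test)) > 0)
        stop("leakage: train and test folds overlap")  # guard, never expected
      train <- subset_cna(data, samples = fold$train)
      test <- subset_cna(data, samples = fold$test)
      pred <- fit_predict_fold(train, test, config, class_names,
                               fold_seed = seed + 1009L * (r - 1L) + f)
      rep_ <- eval_report(test$labels, pred, class_names)
      reports[[length(reports) + 1L]] <- rep_
      fold_sets[[length(fold_sets) + 1L]] <- fold
      fold_metrics <- rbind(fold_metrics, data.frame(
        repeat_ = r, fold = f,
        macro_precision = rep_$macro$macro_precision,
        macro_recall = rep_$macro$macro_recall,
        macro_f1 = rep_$macro$macro_f1,
        accuracy = rep_$macro$accuracy,
        macro_ovr_accuracy = rep_$macro$macro_ovr_accuracy))
    }
  }
  metric_cols <- setdiff(colnames(fold_metrics), c("repeat_", "fold"))
  summary <- do.call(rbind, lapply(metric_cols, function(mc) data.frame(
    metric = mc, mean = mean(fold_metrics[[mc]]), sd = stats::sd(fold_metrics[[mc]]),
    min = min(fold_metrics[[mc]]), max = max(fold_metrics[[mc]]))))
  structure(list(reports = reports, folds = fold_sets,
                 fold_metrics = fold_metrics, summary = summary,
                 k = k, repeats = repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d-fold x %d repeat(s), %d fold reports\n",
              x$k, x$repeats, length(x$reports)))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Pooled confusion matrix across all CV folds
#' @param cv a [cross_validate()] result.
#' @return a [confusion_matrix()] summing fold confusion counts.
#' @export
pooled_confusion <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  counts <- Reduce(`+`, lapply(cv$reports, function(r) r$confusion$counts))
  structure(list(class_names = cv$reports[[1]]$confusion$class_names,
                 counts = counts), class = "confusion_matrix")
}

#' Sweep the cross-validation fold count k
#'
#' Runs [cross_validate()] once per k in `seq(k_min, k_max, step)` and
#' tabulates mean accuracy, to study how the train/test size trade-off
#' moves performance.
#'
#' @inheritParams cross_validate
#' @param k_min,k_max,step sweep range (defaults 5..30 by 1).
#' @return data.frame with columns `k`, `mean_accuracy`, `sd_accuracy`,
#'   `mean_macro_f1`.
#' @export
k_sweep <- function(data, config = pipeline_config(), k_min = 5, k_max = 30,
                    step = 1, repeats = 1, seed = 1L, stratified = TRUE) {
  ks <- seq(k_min, k_max, by = step)
  out <- lapply(ks, function(k) {
    cv <- cross_validate(data, config, k = k, repeats = repeats,
                         seed = seed, stratified = stratified)
    data.frame(k = k, mean_accuracy = mean(cv$fold_metrics$accuracy),
               sd_accuracy = stats::sd(cv$fold_metrics$accuracy),
               mean_macro_f1 = mean(cv$fold_metrics$macro_f1))
  })
  do.call(rbind, out)
}
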