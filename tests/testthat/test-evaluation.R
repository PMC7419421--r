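test_that("all-correct and all-wrong prediction sets hit the degenerate metric values", {
  truth <- rep(c("A", "B", "C"), each = 10)
  rep_ok <- eval_report(truth, truth)
  expect_true(all(rep_ok$per_class$precision == 1))
  expect_true(all(rep_ok$per_class$recall == 1))
  expect_true(all(rep_ok$per_class$accuracy == 1))
  expect_true(all(rep_ok$per_class$f1 == 1))
  expect_equal(rep_ok$macro$accuracy, 1)

  truth2 <- rep(c("A", "B"), each = 5)
  flipped <- rep(c("B", "A"), each = 5)  # TP = 0 and TN = 0 per class
  rep_bad <- eval_report(truth2, flipped)
  expect_true(all(rep_bad$per_class$precision == 0))
  expect_true(all(rep_bad$per_class$recall == 0))
  expect_true(all(rep_bad$per_class$f1 == 0))
  expect_true(all(rep_bad$per_class$accuracy == 0))
  expect_true(all(rep_bad$per_class$zero_division))
})

test_that("hand-computed three-class confusion matrix metrics", {
  # counts [[5,1,0],[2,6,0],[0,0,4]]
  truth <- c(rep("c1", 6), rep("c2", 8), rep("c3", 4))
  pred <- c(rep("c1", 5), "c2", rep("c1", 2), rep("c2", 6), rep("c3", 4))
  conf <- confusion_matrix(truth, pred)
  expect_equal(unname(conf$counts), rbind(c(5, 1, 0), c(2, 6, 0), c(0, 0, 4)))
  pc <- per_class_metrics(conf)
  p1 <- 5 / 7; r1 <- 5 / 6
  expect_equal(pc$precision[1], p1)
  expect_equal(pc$recall[1], r1)
  expect_equal(pc$f1[1], 2 * p1 * r1 / (p1 + r1))
  mac <- macro_average(conf)
  expect_equal(mac$macro_precision, mean(pc$precision))
  expect_equal(mac$accuracy, 15 / 18)
})

test_that("metrics agree with a recount-from-pairs oracle on random predictions", {
  set.seed(71)
  for (i in 1:300) {
    m <- sample(2:5, 1)
    n <- sample(10:40, 1)
    classes <- paste0("k", seq_len(m))
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    pc <- per_class_metrics(confusion_matrix(truth, pred, classes))
    for (ci in seq_len(m)) {
      c0 <- classes[ci]
      tp <- sum(truth == c0 & pred == c0)
      fp <- sum(truth != c0 & pred == c0)
      fn <- sum(truth == c0 & pred != c0)
      tn <- n - tp - fp - fn
      expect_equal(pc$precision[ci], if (tp + fp == 0) 0 else tp / (tp + fp),
                   tolerance = 1e-12)
      expect_equal(pc$recall[ci], if (tp + fn == 0) 0 else tp / (tp + fn),
                   tolerance = 1e-12)
      expect_equal(pc$accuracy[ci], (tp + tn) / n, tolerance = 1e-12)
      pr <- pc$precision[ci]; rc <- pc$recall[ci]
      expect_equal(pc$f1[ci], if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc),
                   tolerance = 1e-12)
    }
    # algebraic identity: overall accuracy = class-frequency-weighted recall
    mac <- macro_average(confusion_matrix(truth, pred, classes))
    freq <- vapply(classes, function(c0) mean(truth == c0), numeric(1))
    rec <- vapply(seq_len(m), function(ci) {
      tp <- sum(truth == classes[ci] & pred == classes[ci])
      tot <- sum(truth == classes[ci])
      if (tot == 0) 0 else tp / tot
    }, numeric(1))
    expect_equal(mac$accuracy, sum(freq * rec), tolerance = 1e-12)
  }
})

test_that("misclassification profiles normalize the source row", {
  conf <- confusion_matrix(rep(c("u", "v", "w"), c(10, 5, 5)),
                           c(rep("u", 2), rep("v", 6), rep("w", 2),
                             rep("v", 5), rep("w", 5)))
  prof <- misclassification_profile(conf, "u")
  expect_equal(sum(prof), 1)
  expect_equal(unname(prof), c(0.2, 0.6, 0.2))
  perfect <- confusion_matrix(c("u", "v"), c("u", "v"))
  expect_equal(unname(misclassification_profile(perfect, "u")["u"]), 1)
  expect_error(misclassification_profile(conf, "zzz"), "unknown")
})

test_that("k-fold splits partition samples with balanced, stratified sizes", {
  labels <- rep(c("A", "B", "C"), c(40, 30, 30))
  folds <- kfold_split(labels, 10, stratified = TRUE, seed = 4)
  tests <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(tests)), seq_along(labels))
  expect_equal(anyDuplicated(unlist(tests)), 0)
  sizes <- lengths(tests)
  expect_lte(max(sizes) - min(sizes), 1)
  for (fold in folds) {
    expect_length(intersect(fold$train, fold$test), 0)
    tab <- table(factor(labels[fold$test], levels = c("A", "B", "C")))
    expect_lte(max(abs(tab - c(4, 3, 3))), 1)
  }
  # imbalanced labels: per-fold class proportions stay within one sample
  lab2 <- rep(c("A", "B"), c(50, 10))
  for (fold in kfold_split(lab2, 5, seed = 6)) {
    tab <- table(factor(lab2[fold$test], levels = c("A", "B")))
    expect_equal(unname(tab["A"]), 10)
    expect_equal(unname(tab["B"]), 2)
  }
  expect_error(kfold_split(rep(c("A", "B"), c(20, 3)), 5), "smaller than k")
  expect_error(kfold_split(labels, 1), "k must satisfy")
})

test_that("cross_validate produces one report per fold and never leaks samples", {
  coh <- small_six_class(n_genes = 120, n_per_class = 10, seed = 23)
  cfg <- pipeline_config(classifier = "majority", use_autoencoder = FALSE)
  cv <- cross_validate(coh, cfg, k = 5, seed = 11)
  expect_length(cv$reports, 5)
  for (fold in cv$folds)
    expect_length(intersect(fold$train, fold$test), 0)
  # majority dummy scores the largest class frequency (balanced: 1/6)
  expect_equal(mean(cv$fold_metrics$accuracy), 1 / 6, tolerance = 1e-9)
  # aggregate mean of a constant metric equals that constant
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"], 1 / 6,
               tolerance = 1e-9)
  expect_error(cross_validate(cna_matrix(coh$values), cfg, k = 5), "label")
})

test_that("k_sweep tabulates one row per k with accuracies in [0, 1]", {
  coh <- small_six_class(n_genes = 120, n_per_class = 8, seed = 24)
  cfg <- pipeline_config(classifier = "majority", use_autoencoder = FALSE)
  tab <- k_sweep(coh, cfg, k_min = 5, k_max = 8, step = 1, seed = 2)
  expect_equal(tab$k, 5:8)
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))
})

test_that("evaluation reports serialize to JSON, TSV and a per-class table", {
  rep_ <- eval_report(rep(c("A", "B"), 5), rep(c("A", "B"), 5))
  dir <- withr::local_tempdir()
  paths <- write_eval_report(rep_, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[1])
  expect_equal(js$macro$accuracy, 1)
})
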