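test_that("same-padding preserves width for every odd kernel and random lengths", {
  expect_equal(same_pad_width(100, 9)$pad, 4)
  expect_equal(same_pad_width(100, 9)$output_length, 100)
  expect_equal(same_pad_width(100, 1)$pad, 0)
  expect_equal(same_pad_width(7, 5)$pad, 2)
  expect_equal(same_pad_width(7, 5)$output_length, 7)
  expect_error(same_pad_width(10, 4), "odd")
  set.seed(51)
  for (i in 1:50) {
    L <- sample(1:200, 1)
    k <- sample(c(1, 3, 5, 7, 9), 1)
    expect_equal(same_pad_width(L, k)$output_length, L)
  }
})

test_that("network topology follows the channel and width arithmetic", {
  spec <- classifier_spec(input_dim = 100, n_classes = 6, seed = 2)
  m <- build_classifier(spec, LETTERS[1:6])
  # stem: 9-wide kernel on a depth-1 input, 64 filters
  expect_equal(dim(m$params$stem$W), c(9, 64))
  # block 1: 5 branches x 64 filters + pool branch carrying input depth 64
  expect_equal(dim(m$params$blocks[[1]]$convs[[1]]$W), c(1 * 64, 64))
  C1 <- 5 * 64 + 64
  expect_equal(dim(m$params$blocks[[2]]$convs[[1]]$W), c(1 * C1, 64))
  # widths 100 -> 50 -> 25 after two halving pools
  C2 <- 5 * 64 + C1
  expect_equal(dim(m$params$dense1$W)[1], 25 * C2)
  expect_equal(dim(m$params$out$W), c(spec$dense_widths[2], 6))
  # forward pass preserves batch size and emits m probabilities
  x <- matrix(rnorm(3 * 100), 3, 100)
  p <- predict_proba(m, x)
  expect_equal(dim(p), c(3, 6))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
  # input too short for the pooling depth is refused
  expect_error(classifier_spec(input_dim = 4, n_classes = 3,
                               n_inception_blocks = 3), "halving")
})

test_that("softmax matches direct evaluation, sums to 1, and is shift-invariant", {
  expect_equal(softmax(c(3, 3, 3, 3)), rep(0.25, 4))
  expect_equal(softmax(c(0, log(2))), c(1 / 3, 2 / 3))
  set.seed(52)
  for (i in 1:200) {
    a <- rnorm(sample(2:8, 1), sd = 3)
    direct <- exp(a) / sum(exp(a))  # unshifted independent route
    expect_equal(softmax(a), direct, tolerance = 1e-12)
    expect_equal(sum(softmax(a)), 1, tolerance = 1e-12)
    expect_equal(softmax(a + 100), softmax(a), tolerance = 1e-12)
  }
  # stable for magnitudes that overflow exp()
  big <- softmax(c(1000, 1001))
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1)
})

test_that("cross-entropy matches its definition and degenerate cases", {
  onehot <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy(onehot, c(0, 1, 2), epsilon = 0), 0)
  unif <- matrix(1 / 4, 5, 4)
  expect_equal(cross_entropy(unif, rep(0, 5)), 5 * log(4))
  p <- matrix(c(0.7, 0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(cross_entropy(p, c(0, 1)), -(log(0.7) + log(0.8)))
  # invariant to sample order
  ord <- sample(2)
  expect_equal(cross_entropy(p[ord, ], c(0, 1)[ord]), cross_entropy(p, c(0, 1)))
  expect_error(cross_entropy(p, c(0, 2)), "out of range")
  expect_error(cross_entropy(matrix(c(0.5, 0.2), 1), 0), "sum to 1")
})

test_that("training learns a separable problem and the LR schedule only decreases", {
  fx <- make_features(n_per_class = 25, dim = 16, m = 3, seed = 55)
  spec <- classifier_spec(input_dim = 16, n_classes = 3, filters_per_branch = 4,
                          n_inception_blocks = 1, dense_widths = c(16, 8),
                          epochs = 10, seed = 56)
  m <- train_classifier(build_classifier(spec), fx$features, fx$labels)
  expect_equal(m$history$lr[1], 0.01)
  expect_true(all(diff(m$history$lr) <= 0))
  # evaluated without dropout, the trained model separates the classes
  expect_gte(mean(predict(m, fx$features) == fx$labels), 0.95)
  expect_identical(m$class_names, c("a", "b", "c"))
  expect_error(train_classifier(build_classifier(spec), fx$features,
                                rep("a", nrow(fx$features))), "single class")
})

test_that("inference is deterministic, argmax-consistent and permutation-equivariant", {
  fx <- make_features(n_per_class = 10, dim = 16, m = 3, seed = 57)
  spec <- classifier_spec(input_dim = 16, n_classes = 3, filters_per_branch = 4,
                          n_inception_blocks = 1, dense_widths = c(16, 8),
                          epochs = 3, seed = 58)
  m <- train_classifier(build_classifier(spec), fx$features, fx$labels)
  p1 <- predict_proba(m, fx$features)
  p2 <- predict_proba(m, fx$features)
  expect_identical(p1, p2)
  cls <- predict(m, fx$features)
  expect_identical(unname(cls), colnames(p1)[max.col(p1, ties.method = "first")])
  perm <- sample(nrow(fx$features))
  expect_identical(unname(predict(m, fx$features[perm, ])), unname(cls[perm]))
  expect_error(predict_proba(m, fx$features[, 1:5]), "expects")
})

test_that("real labels yield a lower final loss than permuted labels (learning signal)", {
  fx <- make_features(n_per_class = 20, dim = 16, m = 3, seed = 59)
  spec <- classifier_spec(input_dim = 16, n_classes = 3, filters_per_branch = 4,
                          n_inception_blocks = 1, dense_widths = c(16, 8),
                          epochs = 8, seed = 60)
  m_real <- train_classifier(build_classifier(spec), fx$features, fx$labels,
                             validation_split = 0)
  set.seed(61)
  shuffled <- sample(fx$labels)
  m_null <- train_classifier(build_classifier(spec), fx$features, shuffled,
                             validation_split = 0)
  expect_lt(tail(m_real$history$loss, 1), tail(m_null$history$loss, 1))
})

test_that("classifier models and predictions round-trip through files", {
  fx <- make_features(n_per_class = 8, dim = 16, m = 3, seed = 62)
  spec <- classifier_spec(input_dim = 16, n_classes = 3, filters_per_branch = 4,
                          n_inception_blocks = 1, dense_widths = c(16, 8),
                          epochs = 2, seed = 63)
  m <- train_classifier(build_classifier(spec), fx$features, fx$labels)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(predict_proba(back, fx$features), predict_proba(m, fx$features),
               tolerance = 1e-10)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- write_predictions(m, fx$features, tsv)
  expect_true(file.exists(tsv))
  expect_identical(colnames(df), c("sample_id", "predicted_class",
                                   "p_a", "p_b", "p_c"))
  expect_equal(unname(rowSums(df[, 3:5])), rep(1, nrow(df)), tolerance = 1e-9)
})
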