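make_scaled <- function(n_genes = 120, n_per_class = 8, seed = 3) {
  scale_cna(small_six_class(n_genes = n_genes, n_per_class = n_per_class,
                            seed = seed))
}

test_that("spec validation and layer shape arithmetic", {
  s <- autoencoder_spec(100, encoder_widths = c(32), code_dim = 8)
  m <- build_autoencoder(s)
  expect_equal(dim(m$encoder[[1]]$W), c(100, 32))
  expect_equal(dim(m$encoder[[2]]$W), c(32, 8))
  expect_equal(dim(m$decoder[[1]]$W), c(8, 32))
  expect_equal(dim(m$decoder[[2]]$W), c(32, 100))
  expect_error(autoencoder_spec(100, c(32, 64), 8), "decreasing")
  expect_error(autoencoder_spec(100, c(32), 40), "smaller than the last")
  expect_error(autoencoder_spec(10, c(8), 12), "smaller")
})

test_that("shape contract holds for arbitrary widths", {
  set.seed(41)
  for (i in 1:5) {
    d_in <- sample(20:60, 1)
    w1 <- sample(10:19, 1); w2 <- sample(5:9, 1)
    code <- sample(2:4, 1)
    m <- build_autoencoder(autoencoder_spec(d_in, c(w1, w2), code, seed = i))
    x <- matrix(runif(6 * d_in, -1, 1), 6, d_in)
    expect_equal(dim(encode(m, x)), c(6, code))
    expect_equal(dim(reconstruct(m, x)), c(6, d_in))
  }
})

test_that("reconstruction lies in (-1,1) and encode is a deterministic row-wise map", {
  sc <- make_scaled()
  m <- build_autoencoder(autoencoder_spec(120, c(32), 6, epochs = 2, seed = 9))
  y <- reconstruct(m, sc)
  expect_true(all(y > -1 & y < 1))
  f1 <- encode(m, sc)
  f2 <- encode(m, sc)
  expect_identical(f1, f2)
  # duplicated input rows give duplicated feature rows
  x <- sc$values[c(1, 1, 2), ]
  fx <- encode(m, x)
  expect_identical(unname(fx[1, ]), unname(fx[2, ]))
  expect_false(isTRUE(all.equal(unname(fx[1, ]), unname(fx[3, ]))))
  expect_error(encode(m, sc$values[, 1:50]), "expects")
})

test_that("layer-wise pretraining runs one stage per encoder layer and reduces loss", {
  sc <- make_scaled()
  spec <- autoencoder_spec(120, c(32, 16), 6, epochs = 6, seed = 10)
  m0 <- build_autoencoder(spec)
  m <- pretrain_layerwise(m0, sc)
  expect_length(m$pretrain_history, 3)  # len(widths) + 1 stages
  h1 <- m$pretrain_history[[1]]
  expect_length(h1, 6)
  expect_lt(tail(h1, 1), h1[1])
  # zero-epoch pretraining is a no-op
  expect_identical(pretrain_layerwise(m0, sc, epochs_per_stage = 0), m0)
})

test_that("fine-tuning appends history and reduces reconstruction error", {
  sc <- make_scaled()
  spec <- autoencoder_spec(120, c(32), 6, epochs = 8, seed = 12)
  m0 <- build_autoencoder(spec)
  m <- fine_tune(m0, sc)
  expect_length(m$history, 8)
  mse0 <- mean((reconstruct(m0, sc) - sc$values)^2)
  mse1 <- mean((reconstruct(m, sc) - sc$values)^2)
  expect_lt(mse1, mse0)
  expect_lt(tail(m$history, 1), m$history[1])
  # history grows by spec$epochs on each call
  m2 <- fine_tune(m, sc)
  expect_length(m2$history, 16)
  # constant all-zero data is a representable fixed point: loss -> ~0
  zeros <- matrix(0, 40, 120)
  mz <- fine_tune(build_autoencoder(spec), zeros, epochs = 12)
  expect_lt(tail(mz$history, 1), 1e-3)
})

test_that("training is reproducible run-to-run with a fixed seed", {
  sc <- make_scaled()
  spec <- autoencoder_spec(120, c(32), 6, epochs = 3, seed = 33)
  run <- function() {
    m <- build_autoencoder(spec)
    m <- pretrain_layerwise(m, sc, epochs_per_stage = 2)
    fine_tune(m, sc)
  }
  a <- run(); b <- run()
  expect_identical(a$encoder, b$encoder)
  expect_identical(a$history, b$history)
})

test_that("code-layer features retain class signal (bottleneck sanity)", {
  coh <- small_six_class(n_genes = 300, n_per_class = 12, seed = 8)
  sc <- scale_cna(coh)
  m <- build_autoencoder(autoencoder_spec(300, c(64, 24), 8, epochs = 8, seed = 14))
  m <- pretrain_layerwise(m, sc, epochs_per_stage = 4)
  m <- fine_tune(m, sc)
  f <- encode(m, sc)
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(f)), coh$labels),
                                     function(i) colMeans(f[i, , drop = FALSE])))
  d <- as.matrix(dist(rbind(centroids, f)))[-(1:6), 1:6]
  pred <- rownames(centroids)[apply(d, 1, which.min)]
  acc <- mean(pred == coh$labels)
  expect_gt(acc, 2 / 6)  # features beat chance by a wide margin
})

test_that("autoencoder models round-trip through the JSON container", {
  sc <- make_scaled()
  m <- fine_tune(build_autoencoder(autoencoder_spec(120, c(16), 4,
                                                    epochs = 2, seed = 15)), sc)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$encoder, m$encoder, tolerance = 1e-12)
  expect_equal(back$history, m$history, tolerance = 1e-12)
  expect_equal(encode(back, sc), encode(m, sc), tolerance = 1e-10)
})
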