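#' Specify the multi-scale 1D convolutional classifier
#'
#' The classification stage: code-layer features are reshaped to a
#' width-by-1 sequence and passed through a stem convolution (the largest
#' kernel first, which cuts parameters early), a stack of inception-style
#' blocks — parallel convolution branches with odd kernel widths 1, 3, 5,
#' 7, 9 plus a max-pooling branch, depth-concatenated and then
#' width-halved by pooling — a flatten, two fully connected layers with a
#' dropout layer between them, and a softmax output over the tumor
#' classes. All convolutions are stride 1 with same-padding, so each
#' branch preserves sequence width and the branches can be concatenated.
#'
#' Defaults follow the full-scale training setting: 64 filters per
#' branch, batch size 16, 12 epochs, initial learning rate 0.01 with
#' plateau-based reduction, dropout 0.4.
#'
#' @param input_dim width of the input feature vector (default 100, the
#'   autoencoder code width).
#' @param n_classes number of tumor classes (>= 2).
#' @param kernel_widths odd convolution widths of the parallel branches.
#' @param filters_per_branch filters per convolution branch.
#' @param stem_kernel_width odd width of the opening convolution.
#' @param n_inception_blocks how many concat blocks (each ends in a
#'   width-halving max pool).
#' @param dense_widths widths of the two fully connected layers.
#' @param dropout_rate dropout probability between the dense layers,
#'   active only during training.
#' @param batch_size,epochs,initial_learning_rate Adam mini-batch size,
#'   epoch count and starting step size.
#' @param lr_factor,lr_patience,min_lr plateau schedule: multiply the
#'   learning rate by `lr_factor` when the monitored loss has not improved
#'   for `lr_patience` epochs, never below `min_lr`.
#' @param seed RNG seed for initialization, batch order and dropout.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(input_dim = 100,
                            n_classes,
                            kernel_widths = c(1, 3, 5, 7, 9),
                            filters_per_branch = 64,
                            stem_kernel_width = 9,
                            n_inception_blocks = 2,
                            dense_widths = c(128, 64),
                            dropout_rate = 0.4,
                            batch_size = 16,
                            epochs = 12,
                            initial_learning_rate = 0.01,
                            lr_factor = 0.5,
                            lr_patience = 2,
                            min_lr = 1e-5,
                            seed = 1L) {
  stopifnot(input_dim >= 2, n_classes >= 2, filters_per_branch >= 1,
            n_inception_blocks >= 0, length(dense_widths) == 2,
            batch_size >= 1, epochs >= 0, initial_learning_rate > 0,
            lr_factor > 0, lr_factor < 1, lr_patience >= 1, min_lr > 0)
  if (any(kernel_widths %% 2 == 0) || any(kernel_widths < 1))
    stop("kernel widths must be odd and >= 1")
  if (stem_kernel_width %% 2 == 0) stop("stem kernel width must be odd")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  final_w <- input_dim %/% 2^n_inception_blocks
  if (final_w < 1)
    stop(sprintf("input width %d cannot survive %d halving pools (limit: >= %d)",
                 input_dim, n_inception_blocks, 2^n_inception_blocks))
  structure(list(input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 kernel_widths = as.integer(kernel_widths),
                 filters_per_branch = as.integer(filters_per_branch),
                 stem_kernel_width = as.integer(stem_kernel_width),
                 n_inception_blocks = as.integer(n_inception_blocks),
                 dense_widths = as.integer(dense_widths),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 initial_learning_rate = initial_learning_rate,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 min_lr = min_lr, seed = as.integer(seed)),
            class = "classifier_spec")
}

# Channel counts entering each stage.
clf_channel_plan <- function(spec) {
  Fb <- spec$filters_per_branch
  chans <- Fb  # after stem
  widths <- spec$input_dim
  for (i in seq_len(spec$n_inception_blocks)) {
    chans <- c(chans, length(spec$kernel_widths) * Fb + utils::tail(chans, 1))
    widths <- c(widths, utils::tail(widths, 1) %/% 2)
  }
  list(channels = chans, widths = widths)
}

#' Build an untrained multi-scale CNN classifier
#'
#' @param spec a [classifier_spec()].
#' @param class_names optional ordered class names; when omitted they are
#'   fixed at training time as the sorted unique labels.
#' @return object of class `cnn_classifier`.
#' @export
build_classifier <- function(spec, class_names = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!is.null(class_names) && length(class_names) != spec$n_classes)
    stop("class_names length must equal n_classes")
  set.seed(spec$seed)
  Fb <- spec$filters_per_branch
  plan <- clf_channel_plan(spec)
  stem <- list(W = glorot_matrix(spec$stem_kernel_width * 1, Fb), b = rep(0, Fb))
  blocks <- vector("list", spec$n_inception_blocks)
  for (i in seq_len(spec$n_inception_blocks)) {
    C_in <- plan$channels[i]
    blocks[[i]] <- list(convs = lapply(spec$kernel_widths, function(k)
      list(W = glorot_matrix(k * C_in, Fb), b = rep(0, Fb))))
  }
  flat_dim <- utils::tail(plan$widths, 1) * utils::tail(plan$channels, 1)
  dense1 <- new_dense(flat_dim, spec$dense_widths[1])
  dense2 <- new_dense(spec$dense_widths[1], spec$dense_widths[2])
  out <- new_dense(spec$dense_widths[2], spec$n_classes)
  structure(list(spec = spec, class_names = class_names,
                 params = list(stem = stem, blocks = blocks,
                               dense1 = dense1, dense2 = dense2, out = out),
                 history = NULL, trained = FALSE),
            class = "cnn_classifier")
}

#' @export
print.cnn_classifier <- function(x, ...) {
  s <- x$spec
  plan <- clf_channel_plan(s)
  cat(sprintf("cnn_classifier: input %d -> stem conv(k=%d, %d) -> %d block(s) -> flatten %d -> dense %s -> softmax(%d)\n",
              s$input_dim, s$stem_kernel_width, s$filters_per_branch,
              s$n_inception_blocks,
              utils::tail(plan$widths, 1) * utils::tail(plan$channels, 1),
              paste(s$dense_widths, collapse = "/"), s$n_classes))
  if (!is.null(x$class_names)) cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  cat("  trained:", x$trained, "\n")
  invisible(x)
}

#' Numerically stable softmax
#'
#' `P_k = exp(a_k) / sum_i exp(a_i)`, computed after subtracting the row
#' maximum so it is shift-invariant and stable for large magnitudes.
#'
#' @param logits numeric vector, or matrix with one row per sample.
#' @return probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(logits) {
  if (is.vector(logits)) return(drop(softmax(matrix(logits, 1))))
  stopifnot(all(is.finite(logits)))
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Multiclass cross-entropy of predicted probabilities
#'
#' `loss = -sum_i log P[i, y_i]` with integer-coded true labels (0-based,
#' i.e. in `[0, m)`), the summed form of categorical cross-entropy with
#' one-hot targets. Probabilities are clamped below at `epsilon` so exact
#' zeros do not produce infinite loss.
#'
#' @param probabilities n x m matrix; rows must sum to 1.
#' @param true_labels integer vector of length n with values in 0..m-1.
#' @param epsilon clamp for log(0) (default 1e-12).
#' @return nonnegative scalar loss (the sum over samples).
#' @export
cross_entropy <- function(probabilities, true_labels, epsilon = 1e-12) {
  p <- as.matrix(probabilities)
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  y <- as.integer(true_labels)
  if (length(y) != nrow(p)) stop("one label per probability row required")
  if (any(y < 0 | y >= ncol(p)))
    stop("labels out of range [0, ", ncol(p), ")")
  picked <- p[cbind(seq_len(nrow(p)), y + 1L)]
  -sum(log(pmax(picked, epsilon)))
}

clf_forward <- function(model, x, dropout_rng = FALSE) {
  spec <- model$spec
  n <- nrow(x)
  a <- array(x, c(n, spec$input_dim, 1))
  cache <- list(in_shape = dim(a))
  st <- conv1d_forward(a, model$params$stem$W, model$params$stem$b)
  cache$stem <- list(x2 = st$x2, pre = st$out, in_shape = dim(a))
  a <- relu(st$out)
  cache$blocks <- vector("list", spec$n_inception_blocks)
  for (i in seq_len(spec$n_inception_blocks)) {
    bc <- list(in_shape = dim(a))
    C_in <- dim(a)[3]
    L <- dim(a)[2]
    Fb <- spec$filters_per_branch
    nb <- length(spec$kernel_widths)
    concat <- array(0, c(n, L, nb * Fb + C_in))
    bc$convs <- vector("list", nb)
    for (j in seq_len(nb)) {
      cv <- conv1d_forward(a, model$params$blocks[[i]]$convs[[j]]$W,
                           model$params$blocks[[i]]$convs[[j]]$b)
      bc$convs[[j]] <- list(x2 = cv$x2, pre = cv$out)
      concat[, , (j - 1) * Fb + seq_len(Fb)] <- relu(cv$out)
    }
    mp <- maxpool_same_forward(a)
    bc$pool_arg <- mp$arg
    concat[, , nb * Fb + seq_len(C_in)] <- mp$out
    hp <- maxpool_halve_forward(concat)
    bc$halve <- list(take_even = hp$take_even, in_len = hp$in_len,
                     concat_dim = dim(concat))
    cache$blocks[[i]] <- bc
    a <- hp$out
  }
  cache$flat_shape <- dim(a)
  flat <- a
  dim(flat) <- c(n, prod(dim(a)[2:3]))
  cache$flat <- flat
  pre1 <- dense_forward(model$params$dense1, flat)
  act1 <- relu(pre1)
  cache$pre1 <- pre1
  if (dropout_rng && spec$dropout_rate > 0) {
    mask <- matrix(stats::runif(length(act1)) >= spec$dropout_rate,
                   nrow(act1), ncol(act1)) / (1 - spec$dropout_rate)
    act1 <- act1 * mask
    cache$drop_mask <- mask
  }
  cache$act1 <- act1
  pre2 <- dense_forward(model$params$dense2, act1)
  act2 <- relu(pre2)
  cache$pre2 <- pre2
  cache$act2 <- act2
  logits <- dense_forward(model$params$out, act2)
  probs <- softmax(logits)
  list(probs = probs, cache = cache)
}

clf_backward <- function(model, fw, y_idx) {
  spec <- model$spec
  cache <- fw$cache
  p <- fw$probs
  n <- nrow(p)
  dlogits <- p
  dlogits[cbind(seq_len(n), y_idx)] <- dlogits[cbind(seq_len(n), y_idx)] - 1
  dlogits <- dlogits / n
  g <- list()
  g$out <- list(W = crossprod(cache$act2, dlogits), b = colSums(dlogits))
  d <- tcrossprod(dlogits, model$params$out$W) * relu_grad(cache$pre2)
  g$dense2 <- list(W = crossprod(cache$act1, d), b = colSums(d))
  d <- tcrossprod(d, model$params$dense2$W)
  if (!is.null(cache$drop_mask)) d <- d * cache$drop_mask
  d <- d * relu_grad(cache$pre1)
  g$dense1 <- list(W = crossprod(cache$flat, d), b = colSums(d))
  d <- tcrossprod(d, model$params$dense1$W)
  dim(d) <- cache$flat_shape
  g$blocks <- vector("list", spec$n_inception_blocks)
  for (i in rev(seq_len(spec$n_inception_blocks))) {
    bc <- cache$blocks[[i]]
    d_concat <- maxpool_halve_backward(d, bc$halve)
    Fb <- spec$filters_per_branch
    nb <- length(spec$kernel_widths)
    C_in <- bc$in_shape[3]
    dx <- array(0, bc$in_shape)
    g$blocks[[i]] <- list(convs = vector("list", nb))
    for (j in seq_len(nb)) {
      dbr <- d_concat[, , (j - 1) * Fb + seq_len(Fb), drop = FALSE]
      dbr <- dbr * relu_grad(bc$convs[[j]]$pre)
      bk <- conv1d_backward(dbr, bc$convs[[j]]$x2,
                            model$params$blocks[[i]]$convs[[j]]$W, bc$in_shape)
      g$blocks[[i]]$convs[[j]] <- list(W = bk$dW, b = bk$db)
      dx <- dx + bk$dx
    }
    dpool <- d_concat[, , nb * Fb + seq_len(C_in), drop = FALSE]
    dx <- dx + maxpool_same_backward(dpool, bc$pool_arg, bc$in_shape)
    d <- dx
  }
  d <- d * relu_grad(cache$stem$pre)
  bk <- conv1d_backward(d, cache$stem$x2, model$params$stem$W, cache$stem$in_shape)
  g$stem <- list(W = bk$dW, b = bk$db)
  g[c("stem", "blocks", "dense1", "dense2", "out")]
}

encode_labels <- function(labels, class_names) {
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), class_names)
  if (length(unknown))
    stop("labels not among the model's classes: ", paste(unknown, collapse = ", "))
  match(labels, class_names)
}

#' Train the CNN classifier
#'
#' Minimizes sparse categorical cross-entropy with Adam for `spec$epochs`
#' epochs. The learning rate starts at `spec$initial_learning_rate` and is
#' multiplied by `spec$lr_factor` whenever the monitored loss (a held-out
#' validation split by default, the training loss if
#' `validation_split = 0` and no validation set is given) fails to improve
#' for `spec$lr_patience` consecutive epochs, never dropping below
#' `spec$min_lr`. Dropout is active only here, never at inference.
#' Integer label coding follows the sorted order of the class names and is
#' stored in the model.
#'
#' @param model a [build_classifier()] result.
#' @param features numeric matrix, n x `spec$input_dim` (code-layer
#'   features).
#' @param labels character vector/factor of length n.
#' @param validation_split fraction of samples held out to monitor the
#'   plateau schedule (default 0.1; ignored when `validation` is given).
#' @param validation optional list(features, labels) monitored instead.
#' @return the trained model; `history` is a data.frame with per-epoch
#'   `loss`, `accuracy`, `monitored_loss` and `lr`.
#' @export
train_classifier <- function(model, features, labels, validation_split = 0.1,
                             validation = NULL) {
  stopifnot(inherits(model, "cnn_classifier"))
  spec <- model$spec
  features <- as.matrix(features)
  if (ncol(features) != spec$input_dim)
    stop(sprintf("features have %d columns but the model expects %d",
                 ncol(features), spec$input_dim))
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) stop("one label per feature row required")
  if (length(unique(labels)) < 2)
    stop("training set contains a single class; need at least two")
  if (is.null(model$class_names)) model$class_names <- sort(unique(labels))
  if (length(model$class_names) != spec$n_classes)
    stop(sprintf("%d distinct classes but spec$n_classes = %d",
                 length(model$class_names), spec$n_classes))
  y <- encode_labels(labels, model$class_names)

  set.seed(spec$seed + 10L)
  n <- nrow(features)
  if (!is.null(validation)) {
    xval <- as.matrix(validation$features)
    yval <- encode_labels(as.character(validation$labels), model$class_names)
    xtr <- features; ytr <- y
  } else if (validation_split > 0 && floor(n * validation_split) >= 1) {
    hold <- sample.int(n, max(1L, floor(n * validation_split)))
    xval <- features[hold, , drop = FALSE]; yval <- y[hold]
    xtr <- features[-hold, , drop = FALSE]; ytr <- y[-hold]
  } else {
    xval <- NULL; yval <- NULL
    xtr <- features; ytr <- y
  }

  state <- adam_init(model$params)
  lr <- spec$initial_learning_rate
  best <- Inf; wait <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     accuracy = numeric(0), monitored_loss = numeric(0),
                     lr = numeric(0))
  for (ep in seq_len(spec$epochs)) {
    batch_losses <- numeric(0); correct <- 0L
    for (idx in epoch_batches(nrow(xtr), spec$batch_size)) {
      xb <- xtr[idx, , drop = FALSE]
      yb <- ytr[idx]
      fw <- clf_forward(model, xb, dropout_rng = TRUE)
      loss <- check_finite_loss(
        cross_entropy(fw$probs, yb - 1L) / length(yb))
      batch_losses <- c(batch_losses, loss)
      correct <- correct + sum(max.col(fw$probs, ties.method = "first") == yb)
      grads <- clf_backward(model, fw, yb)
      st <- adam_step(model$params, grads, state, lr)
      model$params <- st$params
      state <- st$state
    }
    mon <- if (!is.null(xval)) {
      fv <- clf_forward(model, xval, dropout_rng = FALSE)
      cross_entropy(fv$probs, yval - 1L) / length(yval)
    } else mean(batch_losses)
    hist <- rbind(hist, data.frame(epoch = ep, loss = mean(batch_losses),
                                   accuracy = correct / nrow(xtr),
                                   monitored_loss = mon, lr = lr))
    if (mon < best - 1e-4) { best <- mon; wait <- 0L }
    else {
      wait <- wait + 1L
      if (wait >= spec$lr_patience) {
        lr <- max(lr * spec$lr_factor, spec$min_lr)
        wait <- 0L
      }
    }
  }
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Predicted class probabilities / labels
#'
#' Deterministic inference (dropout off). `predict()` returns the class of
#' highest probability; exact ties break to the lowest class index.
#'
#' @param object a trained `cnn_classifier` (or fitted baseline).
#' @param features numeric matrix, one row per sample.
#' @param ... unused.
#' @return `predict_proba`: n x m matrix of probabilities, columns named
#'   by class; `predict`: character vector of class names.
#' @export
predict_proba <- function(object, features, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.cnn_classifier <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$spec$input_dim)
    stop(sprintf("features have %d columns but the model expects %d",
                 ncol(features), object$spec$input_dim))
  p <- clf_forward(object, features, dropout_rng = FALSE)$probs
  colnames(p) <- object$class_names %||% sprintf("class%d", seq_len(ncol(p)))
  rownames(p) <- rownames(features)
  p
}

#' @rdname predict_proba
#' @export
predict.cnn_classifier <- function(object, features, ...) {
  p <- predict_proba(object, features)
  cls <- colnames(p)[max.col(p, ties.method = "first")]
  names(cls) <- rownames(p)
  cls
}

#' Write predictions as a TSV
#'
#' Columns: `sample_id`, `predicted_class`, then one probability column
#' per class.
#'
#' @param object a fitted classifier with a [predict_proba()] method.
#' @param features feature matrix with sample row names.
#' @param path output path.
#' @return the prediction data.frame, invisibly.
#' @export
write_predictions <- function(object, features, path) {
  p <- predict_proba(object, features)
  cls <- colnames(p)[max.col(p, ties.method = "first")]
  df <- data.frame(sample_id = rownames(p) %||% seq_len(nrow(p)),
                   predicted_class = cls, p, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("p_", colnames(p))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
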