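#' Specify a stacked symmetric autoencoder
#'
#' The feature-extraction stage: a symmetric encoder/decoder network whose
#' narrow code layer yields the compressed per-sample features used by the
#' downstream classifier. Hidden layers use the rectifier
#' `f(x) = max(0, x)`; the final reconstruction layer uses tanh so its
#' output matches the scaled input range (-1, 1). Training minimizes mean
#' squared reconstruction error with Adam.
#'
#' Defaults follow the full-scale design (hidden widths 4096, 1024, 256
#' around a 100-unit code; learning rate 0.01, batch size 64, 16 epochs);
#' tests and desk-scale runs override them with smaller widths.
#'
#' @param input_dim number of genes in the scaled input.
#' @param encoder_widths strictly decreasing hidden widths of the encoder;
#'   the decoder mirrors them.
#' @param code_dim width of the central code layer (the extracted
#'   feature dimension).
#' @param learning_rate,batch_size,epochs Adam step size, mini-batch size
#'   and number of end-to-end training epochs.
#' @param tied_decoder if TRUE the decoder reuses transposed encoder
#'   weights instead of learning independent ones (off by default; the
#'   reverse mapping is introduced with its own parameters).
#' @param seed RNG seed controlling initialization and batch order.
#' @return object of class `autoencoder_spec`.
#' @export
autoencoder_spec <- function(input_dim,
                             encoder_widths = c(4096, 1024, 256),
                             code_dim = 100,
                             learning_rate = 0.01,
                             batch_size = 64,
                             epochs = 16,
                             tied_decoder = FALSE,
                             seed = 1L) {
  stopifnot(input_dim >= 2, code_dim >= 1, learning_rate > 0,
            batch_size >= 1, epochs >= 0)
  encoder_widths <- as.integer(encoder_widths)
  if (length(encoder_widths) == 0) stop("need at least one encoder width")
  if (any(diff(encoder_widths) >= 0))
    stop("encoder widths must be strictly decreasing toward the code")
  if (code_dim >= utils::tail(encoder_widths, 1))
    stop("code_dim must be smaller than the last encoder width")
  if (code_dim >= input_dim)
    stop("code_dim must be smaller than input_dim")
  structure(list(input_dim = as.integer(input_dim),
                 encoder_widths = encoder_widths,
                 code_dim = as.integer(code_dim),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 tied_decoder = isTRUE(tied_decoder),
                 seed = as.integer(seed)),
            class = "autoencoder_spec")
}

ae_dims <- function(spec) c(spec$input_dim, spec$encoder_widths, spec$code_dim)

#' Build an untrained stacked autoencoder
#'
#' Allocates encoder layers input -> widths -> code and the mirrored
#' decoder code -> rev(widths) -> input, Glorot-uniform initialized from
#' `spec$seed`.
#'
#' @param spec an [autoencoder_spec()].
#' @return object of class `autoencoder_model` with `spec`, `encoder` and
#'   `decoder` layer lists, `history` (per-epoch fine-tuning MSE) and
#'   `pretrain_history` (per-stage loss traces).
#' @export
build_autoencoder <- function(spec) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  set.seed(spec$seed)
  dims <- ae_dims(spec)
  k <- length(dims) - 1
  encoder <- lapply(seq_len(k), function(i) new_dense(dims[i], dims[i + 1]))
  rdims <- rev(dims)
  decoder <- lapply(seq_len(k), function(i) new_dense(rdims[i], rdims[i + 1]))
  structure(list(spec = spec, encoder = encoder, decoder = decoder,
                 history = numeric(0), pretrain_history = list()),
            class = "autoencoder_model")
}

#' @export
print.autoencoder_model <- function(x, ...) {
  dims <- ae_dims(x$spec)
  cat("autoencoder_model:", paste(c(dims, rev(dims)[-1]), collapse = " -> "), "\n")
  cat(sprintf("  fine-tune epochs recorded: %d; pretrain stages: %d\n",
              length(x$history), length(x$pretrain_history)))
  invisible(x)
}

as_value_matrix <- function(data) {
  if (inherits(data, "scaled_matrix")) data$values
  else if (is.matrix(data)) data
  else stop("expected a scaled_matrix or a numeric matrix")
}

check_ae_input <- function(model, x) {
  if (ncol(x) != model$spec$input_dim)
    stop(sprintf("input has %d columns but the model expects %d",
                 ncol(x), model$spec$input_dim))
}

ae_decoder_effective <- function(model) {
  if (!model$spec$tied_decoder) return(model$decoder)
  k <- length(model$encoder)
  lapply(seq_len(k), function(i) {
    enc <- model$encoder[[k - i + 1]]
    list(W = t(enc$W), b = model$decoder[[i]]$b)
  })
}

ae_forward <- function(model, x, keep_cache = FALSE) {
  enc_pre <- list(); enc_act <- list(x)
  a <- x
  for (i in seq_along(model$encoder)) {
    pre <- dense_forward(model$encoder[[i]], a)
    a <- relu(pre)
    if (keep_cache) { enc_pre[[i]] <- pre; enc_act[[i + 1]] <- a }
  }
  code <- a
  dec <- ae_decoder_effective(model)
  dec_pre <- list(); dec_act <- list(code)
  k <- length(dec)
  for (i in seq_len(k)) {
    pre <- dense_forward(dec[[i]], a)
    a <- if (i == k) tanh(pre) else relu(pre)
    if (keep_cache) { dec_pre[[i]] <- pre; dec_act[[i + 1]] <- a }
  }
  out <- list(code = code, output = a)
  if (keep_cache)
    out <- c(out, list(enc_pre = enc_pre, enc_act = enc_act,
                       dec_pre = dec_pre, dec_act = dec_act))
  out
}

# One Adam-trained pass over (x -> target) for an arbitrary stack of dense
# layers (relu hidden, configurable final activation), used by both the
# shallow pretraining stages and end-to-end fine-tuning.
train_dense_stack <- function(layers, final_act, x, target, epochs, batch_size,
                              lr, tied_from = NULL) {
  params <- layers
  state <- adam_init(params)
  losses <- numeric(0)
  n <- nrow(x)
  k <- length(layers)
  for (ep in seq_len(epochs)) {
    batch_losses <- numeric(0)
    for (idx in epoch_batches(n, batch_size)) {
      xb <- x[idx, , drop = FALSE]
      tb <- target[idx, , drop = FALSE]
      pre <- vector("list", k); act <- vector("list", k + 1)
      act[[1]] <- xb
      for (i in seq_len(k)) {
        pre[[i]] <- dense_forward(params[[i]], act[[i]])
        act[[i + 1]] <- if (i == k) {
          if (final_act == "tanh") tanh(pre[[i]])
          else if (final_act == "relu") relu(pre[[i]]) else pre[[i]]
        } else relu(pre[[i]])
      }
      y <- act[[k + 1]]
      loss <- check_finite_loss(mean((y - tb)^2))
      batch_losses <- c(batch_losses, loss)
      d <- 2 * (y - tb) / length(tb)
      grads <- vector("list", k)
      for (i in rev(seq_len(k))) {
        dpre <- if (i == k) {
          if (final_act == "tanh") d * (1 - y^2)
          else if (final_act == "relu") d * relu_grad(pre[[i]]) else d
        } else d * relu_grad(pre[[i]])
        grads[[i]] <- list(W = crossprod(act[[i]], dpre), b = colSums(dpre))
        if (i > 1) d <- tcrossprod(dpre, params[[i]]$W)
      }
      st <- adam_step(params, grads, state, lr)
      params <- st$params
      state <- st$state
    }
    losses <- c(losses, mean(batch_losses))
  }
  list(layers = params, losses = losses)
}

#' Greedy layer-wise pretraining
#'
#' Trains a sequence of shallow one-hidden-layer autoencoders: stage j
#' learns encoder layer j together with a mirrored decoder layer to
#' reconstruct the previous stage's code, then passes its rectified code
#' forward as the next stage's input. Learned weights are copied into the
#' deep model (encoder layer j and the matching decoder layer), after
#' which [fine_tune()] optimizes the whole stack end to end. Stage 1
#' reconstructs the scaled input, so its decoder uses tanh; deeper stages
#' reconstruct nonnegative rectified codes and use a rectified output.
#'
#' With `epochs_per_stage = 0` the model is returned unchanged.
#'
#' @param model an [build_autoencoder()] result.
#' @param data a `scaled_matrix` (or numeric matrix) with
#'   `spec$input_dim` columns.
#' @param epochs_per_stage training epochs per shallow stage; defaults to
#'   `spec$epochs`.
#' @return the model with pretrained weights and per-stage loss traces in
#'   `pretrain_history`.
#' @export
pretrain_layerwise <- function(model, data, epochs_per_stage = model$spec$epochs) {
  stopifnot(inherits(model, "autoencoder_model"), epochs_per_stage >= 0)
  x <- as_value_matrix(data)
  check_ae_input(model, x)
  if (epochs_per_stage == 0) return(model)
  if (model$spec$tied_decoder)
    stop("layer-wise pretraining requires an untied decoder")
  set.seed(model$spec$seed + 1L)
  dims <- ae_dims(model$spec)
  k <- length(dims) - 1
  z <- x
  for (j in seq_len(k)) {
    dec_init <- new_dense(dims[j + 1], dims[j])
    stage <- train_dense_stack(
      layers = list(model$encoder[[j]], dec_init),
      final_act = if (j == 1) "tanh" else "relu",
      x = z, target = z,
      epochs = epochs_per_stage,
      batch_size = model$spec$batch_size,
      lr = model$spec$learning_rate)
    model$encoder[[j]] <- stage$layers[[1]]
    model$decoder[[k - j + 1]] <- stage$layers[[2]]
    model$pretrain_history[[j]] <- stage$losses
    z <- relu(dense_forward(model$encoder[[j]], z))
  }
  names(model$pretrain_history) <- sprintf("stage%d", seq_len(k))
  model
}

#' Fine-tune the full autoencoder end to end
#'
#' Minimizes mean squared reconstruction error over the whole
#' encoder/decoder stack with Adam for `spec$epochs` epochs (override via
#' `epochs`), appending per-epoch losses to `model$history`.
#'
#' @inheritParams pretrain_layerwise
#' @param epochs number of epochs; defaults to `spec$epochs`.
#' @return the trained model.
#' @export
fine_tune <- function(model, data, epochs = model$spec$epochs) {
  stopifnot(inherits(model, "autoencoder_model"), epochs >= 0)
  x <- as_value_matrix(data)
  check_ae_input(model, x)
  if (epochs == 0) return(model)
  if (model$spec$tied_decoder)
    return(fine_tune_tied(model, x, epochs))
  set.seed(model$spec$seed + 2L + length(model$history))
  k <- length(model$encoder)
  layers <- c(model$encoder, model$decoder)
  res <- train_dense_stack(layers, "tanh", x, x, epochs,
                           model$spec$batch_size, model$spec$learning_rate)
  model$encoder <- res$layers[seq_len(k)]
  model$decoder <- res$layers[k + seq_len(k)]
  model$history <- c(model$history, res$losses)
  model
}

# Tied-decoder fine-tuning: decoder weights are transposed encoder
# weights; gradients from both passes accumulate on the shared matrices.
fine_tune_tied <- function(model, x, epochs) {
  set.seed(model$spec$seed + 2L + length(model$history))
  k <- length(model$encoder)
  params <- list(enc = model$encoder,
                 dec_b = lapply(model$decoder, `[[`, "b"))
  state <- adam_init(params)
  n <- nrow(x)
  for (ep in seq_len(epochs)) {
    batch_losses <- numeric(0)
    for (idx in epoch_batches(n, model$spec$batch_size)) {
      xb <- x[idx, , drop = FALSE]
      model$encoder <- params$enc
      for (i in seq_len(k)) model$decoder[[i]]$b <- params$dec_b[[i]]
      fw <- ae_forward(model, xb, keep_cache = TRUE)
      y <- fw$output
      loss <- check_finite_loss(mean((y - xb)^2))
      batch_losses <- c(batch_losses, loss)
      d <- 2 * (y - xb) / length(xb)
      gW <- lapply(params$enc, function(l) l$W * 0)
      g_enc_b <- lapply(params$enc, function(l) l$b * 0)
      g_dec_b <- lapply(params$dec_b, function(b) b * 0)
      dec <- ae_decoder_effective(model)
      for (i in rev(seq_len(k))) {
        dpre <- if (i == k) d * (1 - y^2) else d * relu_grad(fw$dec_pre[[i]])
        # decoder layer i uses t(W) of encoder layer k-i+1
        j <- k - i + 1
        gW[[j]] <- gW[[j]] + t(crossprod(fw$dec_act[[i]], dpre))
        g_dec_b[[i]] <- g_dec_b[[i]] + colSums(dpre)
        d <- tcrossprod(dpre, dec[[i]]$W)
      }
      for (i in rev(seq_len(k))) {
        dpre <- d * relu_grad(fw$enc_pre[[i]])
        gW[[i]] <- gW[[i]] + crossprod(fw$enc_act[[i]], dpre)
        g_enc_b[[i]] <- g_enc_b[[i]] + colSums(dpre)
        if (i > 1) d <- tcrossprod(dpre, params$enc[[i]]$W)
      }
      grads <- list(enc = Map(function(w, b) list(W = w, b = b), gW, g_enc_b),
                    dec_b = g_dec_b)
      st <- adam_step(params, grads, state, model$spec$learning_rate)
      params <- st$params
      state <- st$state
    }
    model$history <- c(model$history, mean(batch_losses))
  }
  model$encoder <- params$enc
  for (i in seq_len(k)) model$decoder[[i]]$b <- params$dec_b[[i]]
  model
}

#' Extract code-layer features
#'
#' Deterministic forward pass through the encoder only; the code-layer
#' activations are the per-sample features handed to the classifier.
#'
#' @inheritParams pretrain_layerwise
#' @return numeric feature matrix, n_samples x code_dim, with the input's
#'   row names preserved.
#' @export
encode <- function(model, data) {
  stopifnot(inherits(model, "autoencoder_model"))
  x <- as_value_matrix(data)
  check_ae_input(model, x)
  code <- ae_forward(model, x)$code
  rownames(code) <- rownames(x)
  colnames(code) <- sprintf("f%03d", seq_len(ncol(code)))
  code
}

#' Reconstruct inputs through the full autoencoder
#'
#' @inheritParams pretrain_layerwise
#' @return real matrix of the input's shape, entries in (-1, 1).
#' @export
reconstruct <- function(model, data) {
  stopifnot(inherits(model, "autoencoder_model"))
  x <- as_value_matrix(data)
  check_ae_input(model, x)
  y <- ae_forward(model, x)$output
  dimnames(y) <- dimnames(x)
  y
}
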