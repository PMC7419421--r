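# Plain-text (JSON) model containers. Arrays are stored column-major with
# their dimensions, so a saved model reloads bit-identically on any
# platform; the spec, class names and training history travel with the
# weights.

pack_array <- function(a) {
  if (is.null(a)) return(NULL)
  list(dim = dim(a) %||% length(a), data = as.vector(a))
}

unpack_array <- function(p) {
  if (is.null(p)) return(NULL)
  d <- unlist(p$dim)
  v <- unlist(p$data)
  if (length(d) > 1) array(v, d) else v
}

pack_layers <- function(layers)
  lapply(layers, function(l) list(W = pack_array(l$W), b = pack_array(l$b)))

unpack_layers <- function(layers)
  lapply(layers, function(l) list(W = unpack_array(l$W), b = unpack_array(l$b)))

#' Save or load a trained model as JSON text
#'
#' A self-describing container holding the model type, its spec, class
#' names (classifier), all weight arrays and the training history.
#' Works for both [build_autoencoder()] and [build_classifier()] models.
#'
#' @param model an `autoencoder_model` or `cnn_classifier`.
#' @param path output (`save_model`) / input (`load_model`) path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "autoencoder_model")) {
    obj <- list(type = "autoencoder",
                spec = unclass(model$spec),
                encoder = pack_layers(model$encoder),
                decoder = pack_layers(model$decoder),
                history = model$history,
                pretrain_history = model$pretrain_history)
  } else if (inherits(model, "cnn_classifier")) {
    obj <- list(type = "cnn_classifier",
                spec = unclass(model$spec),
                class_names = model$class_names,
                params = list(
                  stem = list(W = pack_array(model$params$stem$W),
                              b = pack_array(model$params$stem$b)),
                  blocks = lapply(model$params$blocks, function(bl)
                    list(convs = pack_layers(bl$convs))),
                  dense1 = list(W = pack_array(model$params$dense1$W),
                                b = pack_array(model$params$dense1$b)),
                  dense2 = list(W = pack_array(model$params$dense2$W),
                                b = pack_array(model$params$dense2$b)),
                  out = list(W = pack_array(model$params$out$W),
                             b = pack_array(model$params$out$b))),
                history = if (is.null(model$history)) NULL else
                  as.list(model$history),
                trained = model$trained)
  } else stop("unsupported model type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (obj$type == "autoencoder") {
    spec <- obj$spec
    spec_obj <- autoencoder_spec(spec$input_dim, unlist(spec$encoder_widths),
                                 spec$code_dim, spec$learning_rate,
                                 spec$batch_size, spec$epochs,
                                 isTRUE(spec$tied_decoder), spec$seed)
    structure(list(spec = spec_obj,
                   encoder = unpack_layers(obj$encoder),
                   decoder = unpack_layers(obj$decoder),
                   history = as.numeric(unlist(obj$history)),
                   pretrain_history = lapply(obj$pretrain_history,
                                             function(h) as.numeric(unlist(h)))),
              class = "autoencoder_model")
  } else if (obj$type == "cnn_classifier") {
    s <- obj$spec
    spec_obj <- classifier_spec(
      input_dim = s$input_dim, n_classes = s$n_classes,
      kernel_widths = unlist(s$kernel_widths),
      filters_per_branch = s$filters_per_branch,
      stem_kernel_width = s$stem_kernel_width,
      n_inception_blocks = s$n_inception_blocks,
      dense_widths = unlist(s$dense_widths),
      dropout_rate = s$dropout_rate, batch_size = s$batch_size,
      epochs = s$epochs, initial_learning_rate = s$initial_learning_rate,
      lr_factor = s$lr_factor, lr_patience = s$lr_patience,
      min_lr = s$min_lr, seed = s$seed)
    params <- list(
      stem = list(W = unpack_array(obj$params$stem$W),
                  b = unpack_array(obj$params$stem$b)),
      blocks = lapply(obj$params$blocks, function(bl)
        list(convs = unpack_layers(bl$convs))),
      dense1 = list(W = unpack_array(obj$params$dense1$W),
                    b = unpack_array(obj$params$dense1$b)),
      dense2 = list(W = unpack_array(obj$params$dense2$W),
                    b = unpack_array(obj$params$dense2$b)),
      out = list(W = unpack_array(obj$params$out$W),
                 b = unpack_array(obj$params$out$b)))
    hist <- if (is.null(obj$history)) NULL else
      as.data.frame(lapply(obj$history, unlist))
    structure(list(spec = spec_obj,
                   class_names = unlist(obj$class_names),
                   params = params, history = hist,
                   trained = isTRUE(obj$trained)),
              class = "cnn_classifier")
  } else stop("unknown model container type: ", obj$type)
}
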