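# Shared numerical machinery for the two networks: seeded Glorot-uniform
# initialization, rectifier/tanh activations, the Adam update, and
# mini-batch index streams. All routines are plain matrix code so training
# is deterministic given a seed on one BLAS configuration.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

relu_grad <- function(pre) (pre > 0) * 1

# Glorot/fan-based uniform init: U(-l, l), l = sqrt(6 / (fan_in + fan_out)).
glorot_matrix <- function(fan_in, fan_out) {
  l <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -l, l), fan_in, fan_out)
}

new_dense <- function(fan_in, fan_out) {
  list(W = glorot_matrix(fan_in, fan_out), b = rep(0, fan_out))
}

dense_forward <- function(layer, x) {
  sweep(x %*% layer$W, 2, layer$b, `+`)
}

# Adam state mirrors the structure of a parameter list (nested lists of
# numeric arrays).
adam_init <- function(params) {
  zeros <- function(p) if (is.list(p)) lapply(p, zeros) else array(0, dim = dim(p) %||% length(p))
  list(m = zeros(params), v = zeros(params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    p_new <- p - lr * mh / (sqrt(vh) + eps)
    # keep parameters free of dimnames/1-d dims picked up from gradients
    if (is.matrix(p)) dimnames(p_new) <- NULL else p_new <- as.vector(p_new)
    list(p = p_new, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

# Shuffled mini-batch index list for one epoch.
epoch_batches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}

check_finite_loss <- function(loss) {
  if (!is.finite(loss))
    stop("non-finite training loss; try a lower learning rate")
  loss
}
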