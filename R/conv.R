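# 1D convolution / pooling primitives over activations stored as
# [n_samples, length, channels] arrays. Convolution is implemented as an
# im2col patch matrix times a (kernel_width * in_channels, filters) weight
# matrix, so both the forward pass and the gradients are single BLAS calls
# per offset.

#' Same-padding arithmetic for odd-width 1D kernels
#'
#' Zero-padding of floor(k/2) elements on each end keeps the sequence
#' width unchanged under a stride-1 convolution with an odd kernel of
#' width k: output width = L + 2*floor(k/2) - k + 1 = L.
#'
#' @param sequence_length input width L (>= 1).
#' @param kernel_width odd kernel width k.
#' @param stride convolution stride (only 1 is used by the network).
#' @return list with `pad` (per-end zero count), `padded_length` and
#'   `output_length`.
#' @export
same_pad_width <- function(sequence_length, kernel_width, stride = 1) {
  stopifnot(sequence_length >= 1, kernel_width >= 1, stride >= 1)
  if (kernel_width %% 2 == 0)
    stop("kernel width must be odd for symmetric same-padding")
  pad <- kernel_width %/% 2
  padded <- sequence_length + 2 * pad
  out <- (padded - kernel_width) %/% stride + 1
  list(pad = pad, padded_length = padded, output_length = out)
}

pad_axis <- function(a, pad, fill = 0) {
  if (pad == 0) return(a)
  d <- dim(a)
  out <- array(fill, c(d[1], d[2] + 2 * pad, d[3]))
  out[, pad + seq_len(d[2]), ] <- a
  out
}

# Patch matrix (n*L, k*C) from a padded activation array.
im2col <- function(ap, k, L) {
  d <- dim(ap)
  n <- d[1]; C <- d[3]
  x2 <- matrix(0, n * L, k * C)
  for (o in seq_len(k)) {
    s <- ap[, o:(o + L - 1), , drop = FALSE]
    dim(s) <- c(n * L, C)
    x2[, (o - 1) * C + seq_len(C)] <- s
  }
  x2
}

conv1d_forward <- function(a, W, b) {
  d <- dim(a)
  n <- d[1]; L <- d[2]; C <- d[3]
  k <- nrow(W) / C
  pad <- (k - 1) / 2
  x2 <- im2col(pad_axis(a, pad), k, L)
  y2 <- sweep(x2 %*% W, 2, b, `+`)
  y <- y2
  dim(y) <- c(n, L, ncol(W))
  list(out = y, x2 = x2)
}

conv1d_backward <- function(dy, cache_x2, W, in_shape) {
  n <- in_shape[1]; L <- in_shape[2]; C <- in_shape[3]
  k <- nrow(W) / C
  pad <- (k - 1) / 2
  Fo <- ncol(W)
  dy2 <- dy
  dim(dy2) <- c(n * L, Fo)
  dW <- crossprod(cache_x2, dy2)
  db <- colSums(dy2)
  dx2 <- tcrossprod(dy2, W)
  dap <- array(0, c(n, L + 2 * pad, C))
  for (o in seq_len(k)) {
    blk <- dx2[, (o - 1) * C + seq_len(C), drop = FALSE]
    dim(blk) <- c(n, L, C)
    dap[, o:(o + L - 1), ] <- dap[, o:(o + L - 1), , drop = FALSE] + blk
  }
  dx <- dap[, pad + seq_len(L), , drop = FALSE]
  list(dW = dW, db = db, dx = dx)
}

# Width-3 stride-1 same-padded max pooling (the pooling branch of an
# inception block). Padding uses -Inf so edges pool over real values only.
maxpool_same_forward <- function(a, k = 3) {
  d <- dim(a)
  L <- d[2]
  pad <- (k - 1) / 2
  ap <- pad_axis(a, pad, fill = -Inf)
  y <- ap[, 1:L, , drop = FALSE]
  arg <- array(1L, d)
  for (o in 2:k) {
    s <- ap[, o:(o + L - 1), , drop = FALSE]
    m <- s > y
    y[m] <- s[m]
    arg[m] <- o
  }
  list(out = y, arg = arg)
}

maxpool_same_backward <- function(dy, arg, in_shape, k = 3) {
  L <- in_shape[2]
  pad <- (k - 1) / 2
  dap <- array(0, c(in_shape[1], L + 2 * pad, in_shape[3]))
  for (o in seq_len(k)) {
    m <- arg == o
    blk <- array(0, in_shape)
    blk[m] <- dy[m]
    dap[, o:(o + L - 1), ] <- dap[, o:(o + L - 1), , drop = FALSE] + blk
  }
  dap[, pad + seq_len(L), , drop = FALSE]
}

# Width-2 stride-2 max pooling; an odd trailing element is dropped.
maxpool_halve_forward <- function(a) {
  d <- dim(a)
  L2 <- d[2] %/% 2
  if (L2 < 1) stop("sequence too short to halve-pool")
  odd <- a[, 2 * seq_len(L2) - 1, , drop = FALSE]
  even <- a[, 2 * seq_len(L2), , drop = FALSE]
  m <- even > odd
  y <- odd
  y[m] <- even[m]
  list(out = y, take_even = m, in_len = d[2])
}

maxpool_halve_backward <- function(dy, cache) {
  d <- dim(dy)
  L2 <- d[2]
  dx <- array(0, c(d[1], cache$in_len, d[3]))
  dodd <- dy; dodd[cache$take_even] <- 0
  deven <- dy; deven[!cache$take_even] <- 0
  dx[, 2 * seq_len(L2) - 1, ] <- dodd
  dx[, 2 * seq_len(L2), ] <- deven
  dx
}
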