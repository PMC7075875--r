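# Minimal CNN engine used by the adversarial corrector.
#
# Tensors are dense arrays [H, W, C, B] (height, width, channels, batch).
# Convolutions are evaluated as im2col + BLAS matrix products; gradients
# are derived by hand for every primitive.  Convolution weights are
# arrays [k, k, Cin, Cout]; transposed-convolution weights [k, k, Cout,
# Cin].  All kernels are odd with "same" padding (k - 1) / 2.

# ---- convolution layers --------------------------------------------------
# im2col / col2im and the channel-major reshapes live in src/convops.cpp.

conv_out_size <- function(n, k, stride, pad) {
  (n + 2L * pad - k) %/% stride + 1L
}

conv_forward <- function(x, W, b, stride = 1L) {
  d <- dim(x)
  k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  pad <- (k - 1L) %/% 2L
  oH <- conv_out_size(d[1], k, stride, pad)
  oW <- conv_out_size(d[2], k, stride, pad)
  col <- im2col_cpp(x, d[1], d[2], d[3], d[4], k, stride, pad, oH, oW)
  out <- crossprod(matrix(W, k * k * Cin, Cout), col) + b
  y <- chan_last_cpp(out, oH, oW, Cout, d[4])
  list(y = y, cache = list(col = col, oH = oH, oW = oW, xdim = d,
                           stride = stride))
}

conv_backward <- function(dy, W, cache) {
  k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  pad <- (k - 1L) %/% 2L
  d <- cache$xdim
  dyM <- chan_first_cpp(dy, cache$oH, cache$oW, Cout, d[4])
  dW <- array(tcrossprod(cache$col, dyM), dim(W))
  db <- rowSums(dyM)
  dcol <- matrix(W, k * k * Cin, Cout) %*% dyM
  dx <- col2im_cpp(dcol, d[1], d[2], d[3], d[4], k, cache$stride, pad,
                   cache$oH, cache$oW)
  list(dx = dx, dW = dW, db = db)
}

tconv_forward <- function(x, W, b, stride = 2L) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  k <- dim(W)[1]; Cout <- dim(W)[3]
  pad <- (k - 1L) %/% 2L
  oH <- stride * H; oW <- stride * Wd
  xM <- chan_first_cpp(x, H, Wd, Cin, B)
  dcol <- matrix(W, k * k * Cout, Cin) %*% xM
  y <- col2im_cpp(dcol, oH, oW, Cout, B, k, stride, pad, H, Wd)
  y <- y + rep(b, each = oH * oW)
  list(y = y, cache = list(xM = xM, xdim = d, stride = stride))
}

tconv_backward <- function(dy, W, cache) {
  k <- dim(W)[1]; Cout <- dim(W)[3]; Cin <- dim(W)[4]
  pad <- (k - 1L) %/% 2L
  d <- cache$xdim
  dyd <- dim(dy)
  col <- im2col_cpp(dy, dyd[1], dyd[2], dyd[3], dyd[4], k, cache$stride,
                    pad, d[1], d[2])
  dxM <- crossprod(matrix(W, k * k * Cout, Cin), col)
  dx <- chan_last_cpp(dxM, d[1], d[2], Cin, d[4])
  dW <- array(tcrossprod(col, cache$xM), dim(W))
  db <- rowSums(chan_first_cpp(dy, dyd[1], dyd[2], Cout, dyd[4]))
  list(dx = dx, dW = dW, db = db)
}

# ---- activations ---------------------------------------------------------

LRELU_SLOPE <- 0.2

lrelu_forward <- function(x) {
  pos <- x > 0
  list(y = x * (LRELU_SLOPE + (1 - LRELU_SLOPE) * pos), pos = pos)
}

lrelu_backward <- function(dy, pos) {
  dy * (LRELU_SLOPE + (1 - LRELU_SLOPE) * pos)
}

sigmoid_forward <- function(x) stats::plogis(x)

# ---- optimizers ----------------------------------------------------------

zeros_like_params <- function(params) {
  lapply(params, function(p)
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim(p)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_init <- function(params) {
  list(m = zeros_like_params(params), v = zeros_like_params(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

rmsprop_init <- function(params) {
  list(v = zeros_like_params(params))
}

rmsprop_step <- function(params, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$v[[nm]] <- rho * state$v[[nm]] + (1 - rho) * g * g
    params[[nm]] <- params[[nm]] - lr * g / (sqrt(state$v[[nm]]) + eps)
  }
  list(params = params, state = state)
}

# ---- parameter initialization -------------------------------------------

he_weights <- function(k, cin, cout, scale = 1) {
  array(stats::rnorm(k * k * cin * cout, sd = scale * sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

count_params <- function(params) {
  sum(vapply(params, length, numeric(1)))
}
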