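# Residual U-Net generator and encoder-shaped discriminator.
#
# Encoder block b (features n): 5 convolutions, feature counts
# (n, n, n/2, n, n); stride 2 on the first layer (learned downsampling),
# stride 1 elsewhere; leaky-rectifier activations; residual connection
# from the first layer's activation to the last layer's activation.
# Decoder blocks mirror the encoder: 4 stride-1 convolutions with the
# same (m, m, m/2, m) feature pattern and an in-block residual across
# them, then a stride-2 transposed convolution as the last layer
# (learned upsampling).  Symmetric skip connections concatenate each
# encoder block's output onto the matching decoder block's input.  The
# generator ends in a 1-channel convolution with a sigmoid, so outputs
# live in [0, 1] like their inputs.  The discriminator reuses the encoder
# stack and adds a global-average-pool -> affine -> sigmoid head.

#' U-Net architecture settings
#'
#' @param n_blocks Encoder/decoder depth; `input_size` must be divisible
#'   by `2^n_blocks`.
#' @param base_features Feature count of the first block; doubles per
#'   block; must be even (the middle layer of each block uses half).
#' @param input_size Image side length the network operates on.
#' @param kernel_size Odd convolution kernel size.
#' @return A `unet_config` list.
#' @export
unet_config <- function(n_blocks = 4L, base_features = 64L,
                        input_size = 128L, kernel_size = 3L) {
  abort_if(n_blocks < 1, "`n_blocks` must be >= 1")
  abort_if(base_features < 2 || base_features %% 2 != 0,
           "`base_features` must be an even integer >= 2")
  abort_if(kernel_size %% 2 != 1, "`kernel_size` must be odd")
  abort_if(input_size %% 2^n_blocks != 0,
           "`input_size` must be divisible by 2^n_blocks")
  structure(list(n_blocks = as.integer(n_blocks),
                 base_features = as.integer(base_features),
                 input_size = as.integer(input_size),
                 kernel_size = as.integer(kernel_size)),
            class = "unet_config")
}

block_features <- function(cfg, b) cfg$base_features * 2L^(b - 1L)

# Encoder (and discriminator trunk) parameters: enc{b}.c{1..5}.{W,b}.
init_encoder_params <- function(cfg, in_channels = 1L) {
  k <- cfg$kernel_size
  p <- list()
  cin <- in_channels
  for (b in seq_len(cfg$n_blocks)) {
    n <- block_features(cfg, b)
    widths <- c(n, n, n %/% 2L, n, n)
    ins <- c(cin, n, n, n %/% 2L, n)
    for (l in 1:5) {
      p[[sprintf("enc%d.c%d.W", b, l)]] <- he_weights(k, ins[l], widths[l])
      p[[sprintf("enc%d.c%d.b", b, l)]] <- numeric(widths[l])
    }
    cin <- n
  }
  p
}

init_generator_params <- function(cfg, seed = 0L) {
  with_seed(seed, {
    k <- cfg$kernel_size
    B <- cfg$n_blocks
    p <- init_encoder_params(cfg, 1L)
    for (j in seq_len(B)) {
      m <- block_features(cfg, B - j + 1L)
      din <- if (j == 1L) block_features(cfg, B) else 2L * m
      mout <- if (j < B) block_features(cfg, B - j) else cfg$base_features
      ins <- c(din, m, m, m %/% 2L)
      widths <- c(m, m, m %/% 2L, m)
      for (l in 1:4) {
        p[[sprintf("dec%d.c%d.W", j, l)]] <- he_weights(k, ins[l], widths[l])
        p[[sprintf("dec%d.c%d.b", j, l)]] <- numeric(widths[l])
      }
      p[[sprintf("dec%d.t5.W", j)]] <- he_weights(k, mout, m)  # [k,k,Cout,Cin]
      p[[sprintf("dec%d.t5.b", j)]] <- numeric(mout)
    }
    # small output head so the initial prediction sits near mid-gray
    p[["out.W"]] <- he_weights(k, cfg$base_features, 1L, scale = 1e-2)
    p[["out.b"]] <- numeric(1L)
    p
  })
}

init_discriminator_params <- function(cfg, seed = 0L) {
  with_seed(seed, {
    p <- init_encoder_params(cfg, 1L)
    nB <- block_features(cfg, cfg$n_blocks)
    p[["head.w"]] <- matrix(stats::rnorm(nB, sd = sqrt(1 / nB)), nB, 1)
    p[["head.b"]] <- numeric(1L)
    p
  })
}

# ---- encoder stack -------------------------------------------------------

encoder_forward <- function(params, cfg, x, keep = FALSE) {
  h <- x
  skips <- vector("list", cfg$n_blocks)
  caches <- if (keep) vector("list", cfg$n_blocks) else NULL
  for (b in seq_len(cfg$n_blocks)) {
    cache_b <- if (keep) vector("list", 5L) else NULL
    acts <- vector("list", 5L)
    inp <- h
    for (l in 1:5) {
      cf <- conv_forward(inp, params[[sprintf("enc%d.c%d.W", b, l)]],
                         params[[sprintf("enc%d.c%d.b", b, l)]],
                         stride = if (l == 1L) 2L else 1L)
      act <- lrelu_forward(cf$y)
      if (keep) cache_b[[l]] <- list(conv = cf$cache, pos = act$pos)
      acts[[l]] <- act$y
      inp <- act$y
    }
    h <- acts[[5]] + acts[[1]]  # in-block residual, first -> last layer
    if (keep) caches[[b]] <- cache_b
    skips[[b]] <- h
  }
  list(h = h, skips = skips, caches = caches)
}

# dh: gradient w.r.t. the final encoder output; dskips: optional list of
# gradients w.r.t. each block output (from skip connections).
encoder_backward <- function(params, cfg, caches, dh, dskips = NULL) {
  grads <- list()
  for (b in rev(seq_len(cfg$n_blocks))) {
    if (!is.null(dskips) && !is.null(dskips[[b]])) dh <- dh + dskips[[b]]
    da1_res <- dh  # residual branch
    d <- dh
    for (l in 5:2) {
      cb <- caches[[b]][[l]]
      d <- lrelu_backward(d, cb$pos)
      bk <- conv_backward(d, params[[sprintf("enc%d.c%d.W", b, l)]], cb$conv)
      grads[[sprintf("enc%d.c%d.W", b, l)]] <- bk$dW
      grads[[sprintf("enc%d.c%d.b", b, l)]] <- bk$db
      d <- bk$dx
    }
    d <- d + da1_res
    cb <- caches[[b]][[1]]
    d <- lrelu_backward(d, cb$pos)
    bk <- conv_backward(d, params[[sprintf("enc%d.c1.W", b)]], cb$conv)
    grads[[sprintf("enc%d.c1.W", b)]] <- bk$dW
    grads[[sprintf("enc%d.c1.b", b)]] <- bk$db
    dh <- bk$dx
  }
  list(grads = grads, dx = dh)
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- generator -----------------------------------------------------------

gen_forward <- function(params, cfg, x, keep = FALSE) {
  enc <- encoder_forward(params, cfg, x, keep = keep)
  B <- cfg$n_blocks
  h <- enc$h
  dcaches <- if (keep) vector("list", B) else NULL
  for (j in seq_len(B)) {
    inp <- if (j == 1L) h else concat_channels(h, enc$skips[[B - j + 1L]])
    cache_j <- if (keep) vector("list", 5L) else NULL
    acts <- vector("list", 4L)
    cur <- inp
    for (l in 1:4) {
      cf <- conv_forward(cur, params[[sprintf("dec%d.c%d.W", j, l)]],
                         params[[sprintf("dec%d.c%d.b", j, l)]], stride = 1L)
      act <- lrelu_forward(cf$y)
      if (keep) cache_j[[l]] <- list(conv = cf$cache, pos = act$pos)
      acts[[l]] <- act$y
      cur <- act$y
    }
    r <- acts[[4]] + acts[[1]]  # in-block residual across the conv stack
    tf <- tconv_forward(r, params[[sprintf("dec%d.t5.W", j)]],
                        params[[sprintf("dec%d.t5.b", j)]], stride = 2L)
    act <- lrelu_forward(tf$y)
    if (keep) {
      cache_j[[5]] <- list(conv = tf$cache, pos = act$pos)
      dcaches[[j]] <- cache_j
    }
    h <- act$y
  }
  of <- conv_forward(h, params[["out.W"]], params[["out.b"]], stride = 1L)
  y <- sigmoid_forward(of$y)
  list(y = y,
       cache = if (keep) list(enc = enc, dcaches = dcaches,
                              out_conv = of$cache, y = y) else NULL)
}

gen_backward <- function(params, cfg, cache, dy) {
  B <- cfg$n_blocks
  grads <- list()
  y <- cache$y
  d <- dy * y * (1 - y)  # through the output sigmoid
  bk <- conv_backward(d, params[["out.W"]], cache$out_conv)
  grads[["out.W"]] <- bk$dW
  grads[["out.b"]] <- bk$db
  dh <- bk$dx
  dskips <- vector("list", B)
  for (j in rev(seq_len(B))) {
    cj <- cache$dcaches[[j]]
    d <- lrelu_backward(dh, cj[[5]]$pos)
    bk <- tconv_backward(d, params[[sprintf("dec%d.t5.W", j)]], cj[[5]]$conv)
    grads[[sprintf("dec%d.t5.W", j)]] <- bk$dW
    grads[[sprintf("dec%d.t5.b", j)]] <- bk$db
    dr <- bk$dx
    da1_res <- dr
    d <- dr
    for (l in 4:2) {
      cb <- cj[[l]]
      d <- lrelu_backward(d, cb$pos)
      bk <- conv_backward(d, params[[sprintf("dec%d.c%d.W", j, l)]], cb$conv)
      grads[[sprintf("dec%d.c%d.W", j, l)]] <- bk$dW
      grads[[sprintf("dec%d.c%d.b", j, l)]] <- bk$db
      d <- bk$dx
    }
    d <- d + da1_res
    cb <- cj[[1]]
    d <- lrelu_backward(d, cb$pos)
    bk <- conv_backward(d, params[[sprintf("dec%d.c1.W", j)]], cb$conv)
    grads[[sprintf("dec%d.c1.W", j)]] <- bk$dW
    grads[[sprintf("dec%d.c1.b", j)]] <- bk$db
    dinp <- bk$dx
    if (j == 1L) {
      dh <- dinp  # gradient w.r.t. the encoder output
    } else {
      m <- block_features(cfg, B - j + 1L)
      dh <- dinp[, , seq_len(m), , drop = FALSE]
      dskips[[B - j + 1L]] <- dinp[, , m + seq_len(m), , drop = FALSE]
    }
  }
  ebk <- encoder_backward(params, cfg, cache$enc$caches, dh, dskips)
  list(grads = c(grads, ebk$grads), dx = ebk$dx)
}

# ---- discriminator -------------------------------------------------------

disc_forward <- function(params, cfg, x, keep = FALSE) {
  enc <- encoder_forward(params, cfg, x, keep = keep)
  d <- dim(enc$h)
  v <- matrix(colMeans(matrix(enc$h, d[1] * d[2])), d[3], d[4])
  logit <- as.vector(crossprod(params[["head.w"]], v)) + params[["head.b"]]
  p <- sigmoid_forward(logit)
  list(p = p, cache = if (keep) list(enc = enc, v = v, p = p,
                                     hdim = d) else NULL)
}

# dp: gradient of the loss w.r.t. the probabilities (length B).
disc_backward <- function(params, cfg, cache, dp) {
  p <- cache$p
  dlogit <- dp * p * (1 - p)
  grads <- list(
    "head.w" = cache$v %*% matrix(dlogit, ncol = 1),
    "head.b" = sum(dlogit))
  dv <- params[["head.w"]] %*% matrix(dlogit, nrow = 1)  # [C, B]
  d <- cache$hdim
  dh <- array(rep(as.vector(dv), each = d[1] * d[2]) / (d[1] * d[2]), d)
  ebk <- encoder_backward(params, cfg, cache$enc$caches, dh)
  list(grads = c(grads, ebk$grads), dx = ebk$dx)
}

#' Build the residual U-Net generator
#'
#' @param config A [unet_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `generator_network`: list with `params` and `config`.
#' @export
build_generator <- function(config, seed = 0L) {
  abort_if(!inherits(config, "unet_config"), "`config` must be a unet_config")
  structure(list(params = init_generator_params(config, seed),
                 config = config),
            class = "generator_network")
}

#' Build the encoder-shaped discriminator
#'
#' Identical to the generator's encoder stack, followed by a global
#' average pool, one affine unit and a sigmoid, so the scalar output is
#' interpretable as the probability that the input is a real (clean)
#' image.
#'
#' @inheritParams build_generator
#' @return A `discriminator_network`: list with `params` and `config`.
#' @export
build_discriminator <- function(config, seed = 0L) {
  abort_if(!inherits(config, "unet_config"), "`config` must be a unet_config")
  structure(list(params = init_discriminator_params(config, seed),
                 config = config),
            class = "discriminator_network")
}

#' Total number of trainable parameters of a network
#'
#' @param network A `generator_network`, `discriminator_network`, or
#'   `trained_corrector`.
#' @return Integer-valued parameter count.
#' @export
count_parameters <- function(network) {
  abort_if(is.null(network$params), "object has no parameters")
  count_params(network$params)
}

#' Run a network forward on a batch of images
#'
#' @param network A `generator_network` or `discriminator_network`.
#' @param x Image matrix, list of matrices, or `[H, W, 1, B]` array.
#' @return Generator: array of the input shape. Discriminator: numeric
#'   vector of per-image probabilities in `(0, 1)`.
#' @export
network_forward <- function(network, x) {
  xb <- as_image_batch(x, network$config$input_size)
  if (inherits(network, "generator_network")) {
    gen_forward(network$params, network$config, xb)$y
  } else {
    disc_forward(network$params, network$config, xb)$p
  }
}

# Coerce a matrix / list of matrices / 4D array to [H, W, 1, B].
as_image_batch <- function(x, expect_size = NULL) {
  if (is.list(x)) {
    x <- array(unlist(x, use.names = FALSE),
               c(dim(x[[1]]), 1L, length(x)))
  } else if (is.matrix(x)) {
    x <- array(x, c(dim(x), 1L, 1L))
  }
  abort_if(length(dim(x)) != 4, "expected a matrix, list, or 4D array")
  if (!is.null(expect_size))
    abort_if(dim(x)[1] != expect_size || dim(x)[2] != expect_size,
             sprintf("input size %d x %d does not match the network size %d",
                     dim(x)[1], dim(x)[2], expect_size))
  x
}
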