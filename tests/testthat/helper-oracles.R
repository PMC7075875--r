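# Independent brute-force oracles used to pin down expected values.

# SSIM by explicit per-window loops (valid windows only), independent of
# the package's shift-accumulation implementation.
brute_ssim <- function(r, x, window_size = 11L, k1 = 0.01, k2 = 0.03,
                       data_range = 1, gaussian = TRUE, sigma = 1.5) {
  if (gaussian) {
    ax <- seq_len(window_size) - (window_size + 1) / 2
    w <- exp(-outer(ax^2, ax^2, `+`) / (2 * sigma^2))
    w <- w / sum(w)
  } else {
    w <- matrix(1 / window_size^2, window_size, window_size)
  }
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  n_r <- nrow(r) - window_size + 1
  n_c <- ncol(r) - window_size + 1
  vals <- matrix(0, n_r, n_c)
  for (i in seq_len(n_r)) for (j in seq_len(n_c)) {
    wr <- r[i + seq_len(window_size) - 1, j + seq_len(window_size) - 1]
    wx <- x[i + seq_len(window_size) - 1, j + seq_len(window_size) - 1]
    mu_r <- sum(w * wr); mu_x <- sum(w * wx)
    var_r <- sum(w * wr^2) - mu_r^2
    var_x <- sum(w * wx^2) - mu_x^2
    cov <- sum(w * wr * wx) - mu_r * mu_x
    vals[i, j] <- ((2 * mu_r * mu_x + c1) * (2 * cov + c2)) /
      ((mu_r^2 + mu_x^2 + c1) * (var_r + var_x + c2))
  }
  mean(vals)
}

# Dense encoding matrix E (n_c * N^2 rows, N^2 columns) assembled column
# by column from unit images.
dense_encoding_matrix <- function(coils, mask) {
  N <- nrow(mask)
  nc <- dim(coils)[3]
  E <- matrix(0i, nc * N * N, N * N)
  for (j in seq_len(N * N)) {
    ej <- matrix(0, N, N)
    ej[j] <- 1
    E[, j] <- as.vector(encode(ej, coils, mask))
  }
  E
}

# Exact 90-degree counter-clockwise rotation of a square matrix with an
# odd side, as an integer index permutation about the center pixel.
rot90_oracle <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (r in seq_len(n)) for (c in seq_len(n)) {
    out[r, c] <- m[n + 1 - c, r]
  }
  out
}

rand_image <- function(n, seed) {
  set.seed(seed)
  matrix(stats::runif(n * n), n, n)
}

rand_complex_array <- function(dims, seed) {
  set.seed(seed)
  array(complex(real = stats::rnorm(prod(dims)),
                imaginary = stats::rnorm(prod(dims))), dims)
}
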