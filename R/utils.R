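#' @keywords internal
#' @useDynLib mrimoco, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

# Small shared helpers: argument checks, seeded evaluation, centered FFTs.

abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
}

is_square_matrix <- function(x) {
  is.matrix(x) && nrow(x) == ncol(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded package internals do
#' not disturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG stream untouched.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' Stable 31-bit string hash (polynomial rolling hash in double precision)
#' so every cell of an experiment grid gets an independent, platform-stable
#' seed from one master seed.
#'
#' @param master_seed Integer master seed.
#' @param ... Character/numeric labels identifying the consumer.
#' @return Integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, ...) {
  label <- paste(c(as.character(master_seed), vapply(list(...), function(x)
    paste(format(x, digits = 15, scientific = FALSE, trim = TRUE),
          collapse = ","), character(1))), collapse = "|")
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# ---- centered orthonormal 2D Fourier transforms --------------------------

fftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq.int(d[1] %/% 2 + 1L, d[1]), seq_len(d[1] %/% 2)),
    c(seq.int(d[2] %/% 2 + 1L, d[2]), seq_len(d[2] %/% 2)), drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  x[c(seq.int(d[1] - d[1] %/% 2 + 1L, d[1]), seq_len(d[1] - d[1] %/% 2)),
    c(seq.int(d[2] - d[2] %/% 2 + 1L, d[2]), seq_len(d[2] - d[2] %/% 2)),
    drop = FALSE]
}

#' Centered orthonormal 2D DFT
#'
#' DC is at the matrix center before and after the transform and the
#' scaling is unitary (`1/sqrt(N^2)` each way), so the inverse equals the
#' adjoint and encoding operators built on it are adjoint-consistent to
#' machine precision.
#'
#' @param x Numeric or complex matrix.
#' @return Complex matrix of the same shape.
#' @export
fft2c <- function(x) {
  abort_if(!is.matrix(x), "fft2c() expects a matrix")
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' Centered orthonormal 2D inverse DFT
#' @rdname fft2c
#' @export
ifft2c <- function(x) {
  abort_if(!is.matrix(x), "ifft2c() expects a matrix")
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

# Complex Euclidean inner product <a, b> = sum(conj(a) * b).
cdot <- function(a, b) sum(Conj(a) * b)
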