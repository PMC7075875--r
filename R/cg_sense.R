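# CG-SENSE reconstruction: solve the SENSE normal equations
# (E^H E) x = E^H y by (preconditioned) conjugate gradient, applying the
# encoding operator implicitly instead of forming or inverting it.

#' Conjugate-gradient reconstruction settings
#'
#' @param max_iterations Iteration budget (>= 1).
#' @param tolerance Relative-residual stopping threshold (> 0).
#' @param preconditioning Apply the Jacobi-style intensity correction
#'   `1 / sum_c |s_c|^2` (a no-op for sum-of-squares-normalized maps, kept
#'   for unnormalized sensitivities).
#' @return A `cg_config` list.
#' @export
cg_config <- function(max_iterations = 50L, tolerance = 1e-6,
                      preconditioning = TRUE) {
  abort_if(!is.numeric(max_iterations) || max_iterations < 1,
           "`max_iterations` must be >= 1")
  abort_if(!is.numeric(tolerance) || tolerance <= 0,
           "`tolerance` must be > 0")
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 preconditioning = isTRUE(preconditioning)),
            class = "cg_config")
}

#' Apply the SENSE normal operator E^H E
#'
#' Composition of the encoding operator and its adjoint for a given
#' sampling mask; Hermitian and positive semi-definite.
#'
#' @param x Complex (or numeric) square matrix.
#' @param coils `coil_sensitivities`.
#' @param mask 0/1 matrix of sampled k-space points.
#' @return Complex matrix `E^H E x`.
#' @export
apply_normal_operator <- function(x, coils, mask) {
  encode_adjoint(encode(x, coils, mask), coils)
}

#' Reconstruct an image from multi-coil k-space with CG-SENSE
#'
#' Solves `(E^H E) x = E^H y` by conjugate gradient on the normal
#' equations, starting from the adjoint image `x0 = E^H y` and optionally
#' preconditioned by the inverse coil-intensity profile.  The pseudo
#' inverse is never formed; the encoding operator is applied implicitly
#' via FFTs.
#'
#' @param kspace An `mri_kspace` (mask taken from its scheme) or a complex
#'   `N x N x n_coils` array (supply `mask`).
#' @param coils `coil_sensitivities`.
#' @param config `cg_config`.
#' @param mask Optional 0/1 sampling mask when `kspace` is a bare array;
#'   defaults to full sampling.
#' @return A `cg_result`: list with `image` (magnitude rescaled to
#'   `[0, 1]`), `complex_solution`, `scale` (the magnitude peak divided
#'   out), `residual_history` (relative residual per iteration, starting
#'   at the initial guess) and `iterations_used`.
#' @export
cg_sense_reconstruct <- function(kspace, coils, config = cg_config(),
                                 mask = NULL) {
  if (inherits(kspace, "mri_kspace")) {
    if (is.null(mask)) mask <- scheme_union_mask(kspace$scheme)
    kspace <- kspace$samples
  }
  d <- dim(kspace)
  abort_if(is.null(d) || length(d) != 3 || d[1] != d[2],
           "`kspace` must be an N x N x n_coils array")
  if (is.null(mask)) mask <- matrix(1, d[1], d[2])
  abort_if(!any(mask != 0), "sampling mask is all zero")
  abort_if(!all(is.finite(Re(kspace))) || !all(is.finite(Im(kspace))),
           "k-space contains non-finite values")
  mask <- (mask != 0) * 1

  sos <- apply(abs(unclass(coils))^2, c(1, 2), sum)
  minv <- if (config$preconditioning) 1 / pmax(sos, 1e-12) else 1

  b <- encode_adjoint(kspace * rep(mask, times = d[3]), coils)
  bnorm <- sqrt(Re(cdot(b, b)))
  if (bnorm == 0) {
    return(structure(list(image = matrix(0, d[1], d[2]),
                          complex_solution = b, scale = 0,
                          residual_history = 0, iterations_used = 0L),
                     class = "cg_result"))
  }

  x <- b  # warm start from the adjoint image
  r <- b - apply_normal_operator(x, coils, mask)
  z <- minv * r
  p <- z
  rz <- Re(cdot(r, z))
  history <- sqrt(Re(cdot(r, r))) / bnorm
  iters <- 0L
  for (it in seq_len(config$max_iterations)) {
    if (history[length(history)] <= config$tolerance) break
    Ap <- apply_normal_operator(p, coils, mask)
    pAp <- Re(cdot(p, Ap))
    if (pAp <= 0) break  # numerically singular direction
    alpha <- rz / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    history <- c(history, sqrt(Re(cdot(r, r))) / bnorm)
    iters <- it
    z <- minv * r
    rz_new <- Re(cdot(r, z))
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }

  mag <- abs(x)
  peak <- max(mag)
  structure(list(image = if (peak > 0) mag / peak else mag,
                 complex_solution = x, scale = peak,
                 residual_history = history, iterations_used = iters),
            class = "cg_result")
}

#' @export
print.cg_result <- function(x, ...) {
  cat(sprintf(
    "<cg_result> %d x %d image, %d CG iterations, final rel. residual %.3g\n",
    nrow(x$image), ncol(x$image), x$iterations_used,
    x$residual_history[length(x$residual_history)]))
  invisible(x)
}
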