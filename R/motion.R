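# Per-shot rigid motion model and multi-coil Fourier encoding.
#
# The forward corruption model: for every shot s the object is rigidly
# moved (rotation theta_s about the image center, then in-plane translation
# (t_x, t_y)), Fourier-encoded through the coil sensitivities, and only the
# k-space points of that shot's sampling mask are kept; summing the shot
# segments yields the motion-corrupted multi-coil k-space.  Shot 1 always
# carries zero motion and defines the reference position.

MOTION_SCHEDULES <- c("constant_increment", "random_uniform", "custom")

#' Build a per-shot rigid motion trajectory
#'
#' Schedules:
#' \describe{
#'   \item{constant_increment}{a linear ramp from 0 to `max_rotation`
#'     (and to `max_translation` in both axes) across the shots, so
#'     consecutive shots differ by a constant relative rotation.}
#'   \item{random_uniform}{angles i.i.d. Uniform(-max_rotation,
#'     max_rotation) and translations Uniform(-max_translation,
#'     max_translation) per axis, deterministic in `seed`; shot 1 is
#'     forced to zero.}
#'   \item{custom}{caller-supplied `angles`, `tx`, `ty`.}
#' }
#'
#' @param schedule_name One of `"constant_increment"`, `"random_uniform"`,
#'   `"custom"`.
#' @param n_shots Number of shots `S`.
#' @param max_rotation Maximum rotation (degrees, >= 0).
#' @param max_translation Maximum translation (pixels, >= 0).
#' @param seed Integer seed (random schedule).
#' @param angles,tx,ty Per-shot parameters for the custom schedule.
#' @return A `motion_trajectory`: list with per-shot `angles` (degrees),
#'   `tx`, `ty` (pixels) and the schedule metadata.
#' @examples
#' make_motion("constant_increment", n_shots = 2, max_rotation = 5)$angles
#' @export
make_motion <- function(schedule_name = "constant_increment", n_shots,
                        max_rotation, max_translation = 0, seed = 0L,
                        angles = NULL, tx = NULL, ty = NULL) {
  abort_if(!(schedule_name %in% MOTION_SCHEDULES),
           sprintf("unknown schedule; must be one of: %s",
                   paste(MOTION_SCHEDULES, collapse = ", ")))
  abort_if(!is.numeric(n_shots) || n_shots < 1, "`n_shots` must be >= 1")
  abort_if(!is.numeric(max_rotation) || max_rotation < 0,
           "`max_rotation` must be >= 0")
  abort_if(max_translation < 0, "`max_translation` must be >= 0")
  S <- as.integer(n_shots)

  if (schedule_name == "constant_increment") {
    ramp <- if (S == 1) 0 else (seq_len(S) - 1) / (S - 1)
    angles <- ramp * max_rotation
    tx <- ramp * max_translation
    ty <- ramp * max_translation
  } else if (schedule_name == "random_uniform") {
    draws <- with_seed(seed, matrix(stats::runif(3 * S, -1, 1), S, 3))
    angles <- draws[, 1] * max_rotation
    tx <- draws[, 2] * max_translation
    ty <- draws[, 3] * max_translation
    angles[1] <- 0; tx[1] <- 0; ty[1] <- 0  # reference shot
  } else {
    abort_if(is.null(angles), "custom schedule requires `angles`")
    if (is.null(tx)) tx <- rep(0, S)
    if (is.null(ty)) ty <- rep(0, S)
    abort_if(length(angles) != S || length(tx) != S || length(ty) != S,
             "custom parameters must have one entry per shot")
  }

  structure(list(angles = as.numeric(angles), tx = as.numeric(tx),
                 ty = as.numeric(ty), schedule_name = schedule_name,
                 max_rotation = max_rotation,
                 max_translation = max_translation, n_shots = S,
                 seed = as.integer(seed)),
            class = "motion_trajectory")
}

#' Apply an in-plane rigid transform to an image
#'
#' Rotates by `theta` degrees (counter-clockwise in the displayed image)
#' about the image center, then translates by `(tx, ty)` pixels (`tx`
#' along columns, `ty` along rows).  Resampling is bilinear with zero fill
#' outside the frame.  The identity transform returns the input exactly.
#'
#' @param image Square numeric matrix.
#' @param theta Rotation angle in degrees.
#' @param tx,ty Translation in pixels.
#' @return Transformed matrix of the same shape.
#' @export
apply_rigid_transform <- function(image, theta, tx = 0, ty = 0) {
  abort_if(!is_square_matrix(image), "`image` must be a square matrix")
  if (theta == 0 && tx == 0 && ty == 0) return(image)
  n <- nrow(image)
  ctr <- (n + 1) / 2
  th <- theta * pi / 180
  ca <- cos(th); sa <- sin(th)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr - tx
  rows <- matrix(seq_len(n), n, n) - ctr - ty
  # inverse mapping: rotate output coordinates by -theta
  src_c <- ca * cols + sa * rows + ctr
  src_r <- -sa * cols + ca * rows + ctr
  r0 <- floor(src_r); c0 <- floor(src_c)
  wr <- src_r - r0; wc <- src_c - c0
  out <- numeric(n * n)
  gather <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
    v <- numeric(n * n)
    v[ok] <- image[cbind(ri[ok], ci[ok])]
    v
  }
  r0v <- as.vector(r0); c0v <- as.vector(c0)
  wrv <- as.vector(wr); wcv <- as.vector(wc)
  out <- (1 - wrv) * (1 - wcv) * gather(r0v, c0v) +
    wrv * (1 - wcv) * gather(r0v + 1, c0v) +
    (1 - wrv) * wcv * gather(r0v, c0v + 1) +
    wrv * wcv * gather(r0v + 1, c0v + 1)
  matrix(out, n, n)
}

#' Simulate smooth sum-of-squares-normalized coil sensitivity maps
#'
#' Places `n_coils` Gaussian-profile receive coils on a circle around the
#' field of view, each with a gentle linear phase ramp toward its coil
#' center, and normalizes so the sum of squared magnitudes is exactly 1 at
#' every pixel.  A single coil yields the all-ones real map.
#'
#' @param n_coils Number of coils (>= 1).
#' @param grid_size Image side length `N`.
#' @return A `coil_sensitivities`: complex array of shape
#'   `N x N x n_coils`.
#' @export
simulate_coil_maps <- function(n_coils, grid_size) {
  abort_if(!is.numeric(n_coils) || n_coils < 1, "`n_coils` must be >= 1")
  n_coils <- as.integer(n_coils)
  N <- as.integer(grid_size)
  maps <- array(0i, c(N, N, n_coils))
  if (n_coils == 1) {
    maps[, , 1] <- 1 + 0i
  } else {
    ax <- seq_len(N) - (N + 1) / 2
    xg <- matrix(ax, N, N, byrow = TRUE)
    yg <- matrix(ax, N, N)
    sigma <- 0.55 * N
    for (c in seq_len(n_coils)) {
      phi <- 2 * pi * (c - 1) / n_coils
      cx <- 0.6 * N * cos(phi)
      cy <- 0.6 * N * sin(phi)
      mag <- exp(-((xg - cx)^2 + (yg - cy)^2) / (2 * sigma^2))
      phase <- 0.15 * 2 * pi * (xg * cos(phi) + yg * sin(phi)) / N
      maps[, , c] <- mag * exp(1i * phase)
    }
    sos <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
    for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / sos
  }
  structure(maps, class = "coil_sensitivities", n_coils = n_coils)
}

coil_count <- function(coils) dim(coils)[3]

#' Multi-coil Fourier encoding operator
#'
#' For each coil: multiply the image by the coil sensitivity, take the
#' centered orthonormal 2D DFT, and zero out unsampled k-space points.
#'
#' @param image Square numeric or complex matrix (the object `x`).
#' @param coils `coil_sensitivities` of matching size.
#' @param mask 0/1 matrix of sampled k-space points (default: all).
#' @return Complex array `N x N x n_coils` of k-space samples; zero
#'   outside `mask`.
#' @export
encode <- function(image, coils, mask = NULL) {
  N <- nrow(image)
  abort_if(!is_square_matrix(image), "`image` must be a square matrix")
  abort_if(dim(coils)[1] != N || dim(coils)[2] != N,
           "coil maps do not match the image size")
  if (is.null(mask)) mask <- matrix(1, N, N)
  abort_if(!all(dim(mask) == c(N, N)), "`mask` does not match the image")
  nc <- coil_count(coils)
  y <- array(0i, c(N, N, nc))
  for (c in seq_len(nc)) y[, , c] <- fft2c(coils[, , c] * image) * mask
  y
}

#' Adjoint of the multi-coil encoding operator
#'
#' Per coil: inverse centered DFT of the (zero-filled) k-space, multiplied
#' by the conjugate sensitivity, summed over coils.
#'
#' @param kspace Complex array `N x N x n_coils` (zero at unsampled
#'   points), or an `mri_kspace` object.
#' @param coils `coil_sensitivities` of matching size.
#' @return Complex `N x N` matrix (image-domain).
#' @export
encode_adjoint <- function(kspace, coils) {
  if (inherits(kspace, "mri_kspace")) kspace <- kspace$samples
  d <- dim(kspace)
  abort_if(length(d) != 3 || d[1] != d[2],
           "`kspace` must be an N x N x n_coils array")
  abort_if(d[1] != dim(coils)[1] || d[3] != coil_count(coils),
           "coil maps do not match the k-space array")
  x <- matrix(0i, d[1], d[2])
  for (c in seq_len(d[3])) x <- x + Conj(coils[, , c]) * ifft2c(kspace[, , c])
  x
}

#' Simulate motion-corrupted multishot multi-coil k-space
#'
#' For each shot `s` the image is rigidly transformed by that shot's
#' motion parameters, encoded through the coils, and restricted to the
#' shot's sampling mask; the shot segments are summed into the full
#' corrupted k-space.  With zero motion the result equals the clean
#' encoding exactly, because the per-shot masks partition k-space.
#'
#' @param image Square numeric matrix in `[0, 1]`.
#' @param motion `motion_trajectory` with `n_shots` matching `scheme`.
#' @param scheme `sampling_scheme`.
#' @param coils `coil_sensitivities`.
#' @return An `mri_kspace`: list with `samples` (complex
#'   `N x N x n_coils`), `scheme`, and the applied `motion`.
#' @export
forward_corrupt <- function(image, motion, scheme, coils) {
  abort_if(!inherits(motion, "motion_trajectory"),
           "`motion` must be a motion_trajectory")
  abort_if(!inherits(scheme, "sampling_scheme"),
           "`scheme` must be a sampling_scheme")
  abort_if(motion$n_shots != scheme$n_shots,
           "motion and scheme disagree on the number of shots")
  N <- nrow(image)
  abort_if(scheme$grid_size != N, "scheme grid does not match the image")
  nc <- coil_count(coils)
  y <- array(0i, c(N, N, nc))
  for (s in seq_len(motion$n_shots)) {
    xs <- apply_rigid_transform(image, motion$angles[s], motion$tx[s],
                                motion$ty[s])
    y <- y + encode(xs, coils, scheme$masks[[s]])
  }
  structure(list(samples = y, scheme = scheme, motion = motion),
            class = "mri_kspace")
}
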