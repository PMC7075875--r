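# Synthetic brain-like phantoms and slice preprocessing.
#
# The phantoms stand in for magnitude brain slices: a skull-like elliptical
# ring enclosing piecewise-smooth, soft-edged elliptical structures.  They
# are deliberately rotation-asymmetric so rigid motion always changes the
# image.

# Soft-edged ellipse membership: 1 inside, 0 outside, smooth ramp of the
# requested width (in units of the normalized ellipse radius) at the edge.
soft_ellipse <- function(xg, yg, cx, cy, a, b, phi, edge = 0.08) {
  ca <- cos(phi); sa <- sin(phi)
  xr <- (xg - cx) * ca + (yg - cy) * sa
  yr <- -(xg - cx) * sa + (yg - cy) * ca
  r <- sqrt((xr / a)^2 + (yr / b)^2)
  t <- pmin(pmax((1 + edge - r) / (2 * edge), 0), 1)
  t * t * (3 - 2 * t)  # smoothstep
}

#' Generate a synthetic brain-like phantom slice
#'
#' Builds a piecewise-smooth magnitude image from overlapping soft-edged
#' ellipses inside a bright skull-like ring, normalized to `[0, 1]`.  The
#' ring is elliptical (not circular) and the interior structures are
#' randomly placed, so the image is asymmetric under rotation -- a rotated
#' copy is never identical to the original.
#'
#' @param size Image side length `N` (pixels), at least 16.
#' @param seed Integer seed; the phantom is deterministic in it.
#' @param n_ellipses Number of random interior ellipses (>= 1).
#' @return `size x size` numeric matrix with values in `[0, 1]` and max 1.
#' @examples
#' p <- generate_phantom(64, seed = 1, n_ellipses = 6)
#' range(p)
#' @export
generate_phantom <- function(size = 128L, seed = 0L, n_ellipses = 8L) {
  abort_if(!is.numeric(size) || length(size) != 1 || size < 16,
           "`size` must be a single integer >= 16")
  abort_if(!is.numeric(n_ellipses) || n_ellipses < 1,
           "`n_ellipses` must be >= 1")
  size <- as.integer(size)
  ax <- seq_len(size) - (size + 1) / 2
  xg <- matrix(ax, size, size, byrow = TRUE)   # column coordinate
  yg <- matrix(ax, size, size)                 # row coordinate

  with_seed(seed, {
    R <- size / 2
    # skull ring: outer minus inner ellipse, axes unequal on purpose
    outer_e <- soft_ellipse(xg, yg, 0, 0, 0.92 * R, 0.78 * R, 0, 0.03)
    inner_e <- soft_ellipse(xg, yg, 0, 0, 0.82 * R, 0.68 * R, 0, 0.04)
    img <- 0.95 * (outer_e - inner_e) + 0.30 * inner_e
    for (i in seq_len(n_ellipses)) {
      cx <- stats::runif(1, -0.45, 0.45) * R
      cy <- stats::runif(1, -0.40, 0.40) * R
      a <- stats::runif(1, 0.06, 0.35) * R
      b <- stats::runif(1, 0.06, 0.35) * R
      phi <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, -0.45, 0.55)
      img <- img + amp * inner_e *
        soft_ellipse(xg, yg, cx, cy, a, b, phi, stats::runif(1, 0.05, 0.2))
    }
    img <- pmax(img, 0)
    img / max(img)  # ring guarantees max > 0
  })
}

# Bilinear resampling of a matrix to a new square size, pixel-center
# aligned so that equal sizes reproduce the input exactly.
resize_bilinear <- function(m, out_size) {
  n_r <- nrow(m); n_c <- ncol(m)
  if (n_r == out_size && n_c == out_size) return(m)
  src <- function(n_in) {
    s <- (seq_len(out_size) - 0.5) * (n_in / out_size) + 0.5
    pmin(pmax(s, 1), n_in)
  }
  sr <- src(n_r); sc <- src(n_c)
  r0 <- pmin(floor(sr), n_r - 1); c0 <- pmin(floor(sc), n_c - 1)
  wr <- sr - r0; wc <- sc - c0
  m00 <- m[r0, c0, drop = FALSE]; m10 <- m[r0 + 1, c0, drop = FALSE]
  m01 <- m[r0, c0 + 1, drop = FALSE]; m11 <- m[r0 + 1, c0 + 1, drop = FALSE]
  WR <- matrix(wr, out_size, out_size); WC <- matrix(wc, out_size, out_size,
                                                    byrow = TRUE)
  (1 - WR) * (1 - WC) * m00 + WR * (1 - WC) * m10 +
    (1 - WR) * WC * m01 + WR * WC * m11
}

#' Preprocess a raw slice: center crop, resize, normalize, blank check
#'
#' Mirrors the standard preparation of magnitude slices before simulation:
#' the slice is center-cropped to its smaller square, bilinearly resampled
#' to `target_size x target_size`, and rescaled to `[0, 1]` by its maximum.
#' A slice whose maximum intensity is 0 before normalization is flagged
#' blank (such slices are discarded from datasets).
#'
#' @param slice Numeric 2D matrix.
#' @param target_size Output side length; the cropped square must be at
#'   least this large.
#' @return List with `image` (`target_size` square matrix in `[0, 1]`) and
#'   `blank` (logical).
#' @export
preprocess_slice <- function(slice, target_size = 128L) {
  abort_if(!is.matrix(slice) || !is.numeric(slice),
           "`slice` must be a numeric 2D matrix")
  n <- min(dim(slice))
  abort_if(n < target_size,
           "slice is smaller than `target_size` after center crop")
  blank <- max(slice) == 0 && min(slice) == 0
  r0 <- (nrow(slice) - n) %/% 2
  c0 <- (ncol(slice) - n) %/% 2
  sq <- slice[r0 + seq_len(n), c0 + seq_len(n), drop = FALSE]
  out <- resize_bilinear(sq, as.integer(target_size))
  mx <- max(abs(out))
  if (mx > 0) out <- out / mx
  list(image = out, blank = blank)
}

#' Load axial slices from a NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List of 2D matrices, one per slice along the third axis, in
#'   stored order.
#' @export
load_volume <- function(path) {
  abort_if(!is.character(path) || length(path) != 1,
           "`path` must be a single file path")
  abort_if(!file.exists(path),
           sprintf("cannot read NIfTI volume: '%s' does not exist", path))
  vol <- RNifti::readNifti(path)
  arr <- as.array(vol)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1L)
  abort_if(length(dim(arr)) < 3, "volume must have at least 2 dimensions")
  lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
}

#' Split scans into train/validation/test sets at the scan level
#'
#' All slices of one scan belong to exactly one split; the split is a
#' random partition, deterministic in `seed`, with sizes assigned by
#' largest-remainder rounding of `fractions`.
#'
#' @param scans List (or vector) of scans.
#' @param fractions Numeric triple summing to 1 (train, validation, test).
#' @param seed Integer seed.
#' @return List with `train`, `validation`, `test` (same type as `scans`)
#'   and `split_seed`.
#' @export
split_scans <- function(scans, fractions, seed = 0L) {
  abort_if(length(fractions) != 3 || !is.numeric(fractions),
           "`fractions` must be a numeric triple")
  abort_if(abs(sum(fractions) - 1) > 1e-9, "`fractions` must sum to 1")
  abort_if(any(fractions < 0), "`fractions` must be non-negative")
  n <- length(scans)
  raw <- fractions * n
  counts <- floor(raw + 1e-9)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  perm <- with_seed(seed, sample.int(n))
  idx <- split(perm, rep.int(1:3, counts))
  pick <- function(k) scans[sort(idx[[as.character(k)]])]
  out <- list(train = if (counts[1] > 0) pick(1) else scans[integer(0)],
              validation = if (counts[2] > 0) pick(2) else scans[integer(0)],
              test = if (counts[3] > 0) pick(3) else scans[integer(0)],
              split_seed = as.integer(seed))
  out
}
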