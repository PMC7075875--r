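# Per-shot k-space sampling schemes (encoding trajectories).
#
# A scheme assigns every point of the N x N k-space grid to exactly one of
# S shots: the per-shot binary masks are pairwise disjoint and sum to full
# coverage.  Rows index the phase-encode direction, columns the
# frequency-encode direction.

SCHEME_NAMES <- c("cartesian_sequential", "cartesian_parallel_1d",
                  "cartesian_parallel_2d", "random")

# Largest divisor of s that is <= sqrt(s); factors s = a * b with a <= b.
factor_near_square <- function(s) {
  a <- max(Filter(function(d) s %% d == 0, seq_len(floor(sqrt(s)))))
  c(a, s %/% a)
}

#' Build a per-shot k-space sampling scheme
#'
#' Supported trajectories:
#' \describe{
#'   \item{cartesian_sequential}{shot `s` owns a contiguous block of
#'     phase-encode rows (remainder rows go to the earliest shots).}
#'   \item{cartesian_parallel_1d}{shot `s` owns every `S`-th row, offset
#'     `s - 1` (row interleaving).}
#'   \item{cartesian_parallel_2d}{`S` is factored as `a x b` with
#'     `a <= b` (a square lattice when `S` is a perfect square); shot
#'     `(p, q)` owns points with row index `= p (mod a)` and column index
#'     `= q (mod b)`.}
#'   \item{random}{grid points are randomly permuted and dealt to shots in
#'     near-equal contiguous chunks, deterministic in `seed`.}
#' }
#'
#' @param scheme_name One of `"cartesian_sequential"`,
#'   `"cartesian_parallel_1d"`, `"cartesian_parallel_2d"`, `"random"`.
#' @param n_shots Number of shots `S` (>= 1).
#' @param grid_size k-space grid side `N`.
#' @param seed Integer seed (used by the random scheme only).
#' @return A `sampling_scheme`: list with `masks` (list of `S` 0/1
#'   matrices), `scheme_name`, `n_shots`, `grid_size`, `seed`.
#' @examples
#' sc <- make_scheme("cartesian_parallel_1d", n_shots = 4, grid_size = 8)
#' scheme_coverage_report(sc)
#' @export
make_scheme <- function(scheme_name, n_shots, grid_size, seed = 0L) {
  abort_if(!is.character(scheme_name) || !(scheme_name %in% SCHEME_NAMES),
           sprintf("unknown scheme name; must be one of: %s",
                   paste(SCHEME_NAMES, collapse = ", ")))
  abort_if(!is.numeric(n_shots) || n_shots < 1, "`n_shots` must be >= 1")
  n_shots <- as.integer(n_shots)
  grid_size <- as.integer(grid_size)
  abort_if(n_shots > grid_size^2,
           "`n_shots` exceeds the number of k-space points")
  N <- grid_size
  S <- n_shots
  masks <- vector("list", S)
  zero <- matrix(0, N, N)

  if (scheme_name == "cartesian_sequential") {
    abort_if(S > N, "sequential scheme needs n_shots <= grid_size rows")
    sizes <- rep(N %/% S, S)
    rem <- N %% S
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    stop_row <- cumsum(sizes)
    start_row <- c(1L, stop_row[-S] + 1L)
    for (s in seq_len(S)) {
      m <- zero
      m[start_row[s]:stop_row[s], ] <- 1
      masks[[s]] <- m
    }
  } else if (scheme_name == "cartesian_parallel_1d") {
    abort_if(S > N, "1D parallel scheme needs n_shots <= grid_size rows")
    for (s in seq_len(S)) {
      m <- zero
      m[seq.int(s, N, by = S), ] <- 1
      masks[[s]] <- m
    }
  } else if (scheme_name == "cartesian_parallel_2d") {
    ab <- factor_near_square(S)
    a <- ab[1]; b <- ab[2]
    abort_if(a > N || b > N,
             "2D parallel scheme factors exceed the grid size")
    for (s in seq_len(S)) {
      p <- (s - 1L) %% a
      q <- (s - 1L) %/% a
      m <- zero
      m[seq.int(p + 1L, N, by = a), seq.int(q + 1L, N, by = b)] <- 1
      masks[[s]] <- m
    }
  } else { # random
    perm <- with_seed(seed, sample.int(N * N))
    sizes <- rep((N * N) %/% S, S)
    rem <- (N * N) %% S
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    stops <- cumsum(sizes)
    starts <- c(1L, stops[-S] + 1L)
    for (s in seq_len(S)) {
      m <- zero
      m[perm[starts[s]:stops[s]]] <- 1
      masks[[s]] <- m
    }
  }

  structure(list(masks = masks, scheme_name = scheme_name,
                 n_shots = S, grid_size = N, seed = as.integer(seed)),
            class = "sampling_scheme")
}

#' Per-shot sample counts of a sampling scheme
#'
#' @param scheme A `sampling_scheme`.
#' @return `data.frame` with columns `shot` and `n_samples`; the counts
#'   sum to `grid_size^2`.
#' @export
scheme_coverage_report <- function(scheme) {
  abort_if(!inherits(scheme, "sampling_scheme"),
           "`scheme` must be a sampling_scheme")
  data.frame(shot = seq_len(scheme$n_shots),
             n_samples = vapply(scheme$masks, sum, numeric(1)))
}

# Union of all per-shot masks (all-ones for a partition).
scheme_union_mask <- function(scheme) {
  Reduce(`+`, scheme$masks)
}

#' Export a scheme as a PNG shot-label map
#'
#' Writes a grayscale PNG in which each k-space point's intensity encodes
#' the shot that samples it (shot 1 black, shot S white), for visual
#' inspection of trajectories.
#'
#' @param scheme A `sampling_scheme`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_scheme_png <- function(scheme, path) {
  labels <- matrix(0, scheme$grid_size, scheme$grid_size)
  for (s in seq_len(scheme$n_shots)) labels <- labels + s * scheme$masks[[s]]
  img <- if (scheme$n_shots > 1) (labels - 1) / (scheme$n_shots - 1)
         else labels
  png::writePNG(img, path)
  invisible(path)
}

#' @export
print.sampling_scheme <- function(x, ...) {
  cat(sprintf("<sampling_scheme> %s: S = %d shots on a %d x %d grid\n",
              x$scheme_name, x$n_shots, x$grid_size, x$grid_size))
  invisible(x)
}
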