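# Image-quality metrics against a reference image: peak signal-to-noise
# ratio (PSNR, dB), structural similarity (SSIM) and artifact power (AP).

check_pair <- function(reference, test) {
  abort_if(!is.matrix(reference) || !is.matrix(test),
           "images must be matrices")
  abort_if(!all(dim(reference) == dim(test)),
           "reference and test images differ in shape")
}

#' Peak signal-to-noise ratio
#'
#' `20 * log10(max(r) / sqrt(MSE))` with `MSE` the pixel-mean squared
#' difference and `max(r)` the reference peak.  Identical images (MSE = 0)
#' return `Inf`.
#'
#' @param reference Reference image matrix (not all zero).
#' @param test Test image matrix of the same shape.
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, test) {
  check_pair(reference, test)
  abort_if(all(reference == 0), "reference image is all zero")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  20 * log10(max(reference) / sqrt(mse))
}

gaussian_window <- function(size, sigma) {
  ax <- seq_len(size) - (size + 1) / 2
  w <- exp(-outer(ax^2, ax^2, `+`) / (2 * sigma^2))
  w / sum(w)
}

# Weighted local sums over all fully-interior (valid) windows, computed by
# accumulating the size^2 shifted copies of the image.
local_weighted_mean <- function(img, w) {
  k <- nrow(w)
  n_r <- nrow(img) - k + 1
  n_c <- ncol(img) - k + 1
  acc <- matrix(0, n_r, n_c)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (w[a, b] == 0) next
    acc <- acc + w[a, b] * img[a + seq_len(n_r) - 1, b + seq_len(n_c) - 1]
  }
  acc
}

#' Structural similarity index
#'
#' Windowed means, variances and covariance are combined as
#' `((2 mu_r mu_x + c1)(2 sigma_rx + c2)) /
#'  ((mu_r^2 + mu_x^2 + c1)(sigma_r^2 + sigma_x^2 + c2))`
#' with `c1 = (k1 L)^2`, `c2 = (k2 L)^2`, and the mean over all valid
#' windows is returned.  Defaults follow the reference SSIM formulation:
#' 11 x 11 Gaussian window (sigma 1.5), `k1 = 0.01`, `k2 = 0.03`, unit
#' data range.
#'
#' @param reference,test Image matrices of equal shape.
#' @param window_size Odd window side length, at most the image size.
#' @param k1,k2 Stabilizer constants.
#' @param data_range Dynamic range `L` of the images.
#' @param window `"gaussian"` (sigma 1.5) or `"uniform"` weighting.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(reference, test, window_size = 11L, k1 = 0.01, k2 = 0.03,
                 data_range = 1.0, window = c("gaussian", "uniform")) {
  check_pair(reference, test)
  window <- match.arg(window)
  abort_if(window_size %% 2 != 1, "`window_size` must be odd")
  abort_if(window_size > min(dim(reference)),
           "`window_size` exceeds the image size")
  w <- if (window == "gaussian") gaussian_window(window_size, 1.5)
       else matrix(1 / window_size^2, window_size, window_size)
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  mu_r <- local_weighted_mean(reference, w)
  mu_x <- local_weighted_mean(test, w)
  e_rr <- local_weighted_mean(reference * reference, w)
  e_xx <- local_weighted_mean(test * test, w)
  e_rx <- local_weighted_mean(reference * test, w)
  var_r <- e_rr - mu_r^2
  var_x <- e_xx - mu_x^2
  cov_rx <- e_rx - mu_r * mu_x
  s <- ((2 * mu_r * mu_x + c1) * (2 * cov_rx + c2)) /
    ((mu_r^2 + mu_x^2 + c1) * (var_r + var_x + c2))
  mean(s)
}

#' Artifact power
#'
#' `sum((|r| - |x|)^2) / sum(|r|^2)`: the squared magnitude mismatch
#' normalized by the reference energy.  Zero for an artifact-free image;
#' larger values mean stronger artifacts.
#'
#' @param reference Reference image matrix (not all zero).
#' @param test Test image matrix of the same shape.
#' @return Non-negative artifact power.
#' @export
artifact_power <- function(reference, test) {
  check_pair(reference, test)
  abort_if(all(reference == 0), "reference image is all zero")
  sum((abs(reference) - abs(test))^2) / sum(abs(reference)^2)
}

sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)

#' Evaluate PSNR/SSIM/AP over a set of image pairs
#'
#' @param references,tests Equal-length lists of image matrices.
#' @param ... Passed on to [ssim()].
#' @return A `metrics_report`: list with `per_image` (one row per pair)
#'   and `summary` (mean and sample standard deviation per metric).
#' @export
evaluate_set <- function(references, tests, ...) {
  abort_if(length(references) != length(tests),
           "`references` and `tests` differ in length")
  abort_if(length(references) == 0, "empty image set")
  per <- data.frame(
    image = seq_along(references),
    psnr = mapply(psnr, references, tests),
    ssim = mapply(function(r, x) ssim(r, x, ...), references, tests),
    artifact_power = mapply(artifact_power, references, tests))
  summ <- data.frame(
    metric = c("psnr", "ssim", "artifact_power"),
    mean = c(mean(per$psnr), mean(per$ssim), mean(per$artifact_power)),
    sd = c(sd0(per$psnr), sd0(per$ssim), sd0(per$artifact_power)))
  structure(list(per_image = per, summary = summ), class = "metrics_report")
}

#' Write a metrics report to CSV and/or JSON
#'
#' @param report A `metrics_report`.
#' @param csv_path,json_path Output paths (`NULL` to skip either).
#' @return The report, invisibly.
#' @export
write_metrics_report <- function(report, csv_path = NULL, json_path = NULL) {
  abort_if(!inherits(report, "metrics_report"),
           "`report` must be a metrics_report")
  if (!is.null(csv_path))
    utils::write.csv(report$per_image, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(per_image = report$per_image,
                              summary = report$summary),
                         json_path, digits = NA, auto_unbox = TRUE)
  invisible(report)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d image pair(s)\n", nrow(x$per_image)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-15s %8.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}
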