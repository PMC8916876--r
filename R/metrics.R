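# Image quality indexes: RMSE and PSNR compare pixel values directly; SSIM
# compares local luminance, contrast and structure over Gaussian-weighted
# sliding windows, which tracks perceived quality better than pixel error.

.as_img <- function(x) {
  if (inherits(x, "lrmd_phantom")) x$image else x
}

.check_pair <- function(x, z) {
  if (!is.matrix(x) || !is.matrix(z) || !all(dim(x) == dim(z))) {
    stop("images must be matrices of the same shape", call. = FALSE)
  }
}

#' Root mean square error between two images
#'
#' @param x Reference image (matrix or `lrmd_phantom`).
#' @param z Test image.
#' @return `sqrt(mean((x - z)^2))`, in intensity units.
#' @examples
#' rmse(matrix(0, 1, 2), matrix(c(3, 4), 1, 2))  # sqrt(12.5)
#' @export
rmse <- function(x, z) {
  x <- .as_img(x); z <- .as_img(z)
  .check_pair(x, z)
  sqrt(mean((x - z)^2))
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(data_range^2 / MSE)`. Identical images give `Inf` (reported as
#' a sentinel, not an error). The default `data_range` is 255 for images that
#' look 8-bit (maximum > 1) and the per-image maximum of the reference
#' otherwise; pass it explicitly for anything that matters.
#'
#' @inheritParams rmse
#' @param data_range Intensity range `I_max` (> 0).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0, 2, 2), matrix(1, 2, 2), data_range = 255)  # 48.13 dB
#' @export
psnr <- function(x, z, data_range = NULL) {
  x <- .as_img(x); z <- .as_img(z)
  .check_pair(x, z)
  if (is.null(data_range)) data_range <- if (max(x) > 1) 255 else max(x)
  if (data_range <= 0) stop("`data_range` must be > 0", call. = FALSE)
  mse <- mean((x - z)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# band matrix applying a 1-D kernel in 'valid' mode: out = B %*% signal
.conv_band <- function(extent, kernel) {
  k <- length(kernel)
  out_len <- extent - k + 1
  B <- matrix(0, out_len, extent)
  for (i in seq_len(out_len)) B[i, i:(i + k - 1)] <- kernel
  B
}

#' Structural similarity index (mean SSIM)
#'
#' Gaussian-weighted sliding-window SSIM with the standard constants:
#' 11x11 window, Gaussian SD 1.5, `C1 = (0.01 * data_range)^2`,
#' `C2 = (0.03 * data_range)^2`. Local weighted means, variances and
#' covariance feed the usual luminance-contrast-structure product, and the
#' map is averaged over all valid window positions. The result is at most 1,
#' with equality exactly when the images agree on every window.
#'
#' @inheritParams psnr
#' @param window Window side length (odd, default 11).
#' @param sigma Gaussian window SD (default 1.5).
#' @return Mean SSIM, dimensionless in (-1, 1].
#' @export
ssim <- function(x, z, data_range = NULL, window = 11, sigma = 1.5) {
  x <- .as_img(x); z <- .as_img(z)
  .check_pair(x, z)
  if (min(dim(x)) < window) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  if (is.null(data_range)) data_range <- if (max(x) > 1) 255 else max(x)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2

  r <- (window - 1) / 2
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  Br <- .conv_band(nrow(x), k1)
  Bc <- t(.conv_band(ncol(x), k1))
  filt <- function(m) Br %*% m %*% Bc

  mu_x <- filt(x); mu_z <- filt(z)
  var_x <- filt(x * x) - mu_x^2
  var_z <- filt(z * z) - mu_z^2
  cov_xz <- filt(x * z) - mu_x * mu_z

  num <- (2 * mu_x * mu_z + C1) * (2 * cov_xz + C2)
  den <- (mu_x^2 + mu_z^2 + C1) * (var_x + var_z + C2)
  mean(num / den)
}

#' Quality report for a denoised image against a reference
#'
#' @inheritParams psnr
#' @return A one-row tibble with `rmse`, `psnr`, `ssim` and the `data_range`
#'   the dB/similarity scores used.
#' @examples
#' ph <- make_phantom(64, 2, 0, seed = 1)
#' noisy <- add_noise(ph, noise_spec("gaussian", 5, seed = 1))
#' quality_report(ph$image, noisy, data_range = 255)
#' @export
quality_report <- function(x, z, data_range = NULL) {
  x <- .as_img(x); z <- .as_img(z)
  .check_pair(x, z)
  if (is.null(data_range)) data_range <- if (max(x) > 1) 255 else max(x)
  tibble::tibble(rmse = rmse(x, z),
                 psnr = psnr(x, z, data_range),
                 ssim = ssim(x, z, data_range),
                 data_range = data_range)
}
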