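# Difference-of-Gaussians filtering. Kernels are sampled Gaussians truncated
# at 4*sigma and renormalized to unit sum, so constant images are preserved
# exactly by each blur and map to exactly zero under the difference. Boundary
# handling is symmetric reflection.

#' Sampled Gaussian kernel
#'
#' 1-D Gaussian of standard deviation `sigma` px, truncated at `4 * sigma`
#' and normalized to unit sum. `sigma = 0` returns the identity kernel.
#'
#' @param sigma standard deviation in pixels, `>= 0`.
#' @return Numeric vector of odd length `2 * ceiling(4 * sigma) + 1`.
#' @export
gaussian_kernel <- function(sigma) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(1)
  r <- ceiling(4 * sigma)
  x <- -r:r
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Reflect-pad a matrix by p rows/cols on each side (symmetric: edge repeated,
# as in abc -> cba|abc|cba). Requires p <= dim.
reflect_pad <- function(m, p) {
  if (p == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (p > nr || p > nc) stop("raster smaller than kernel support", call. = FALSE)
  ri <- c(p:1, 1:nr, nr:(nr - p + 1))
  ci <- c(p:1, 1:nc, nc:(nc - p + 1))
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a symmetric 1-D kernel along both axes,
# symmetric-reflection boundary. The kernel is symmetric so convolution and
# correlation coincide.
conv_sep <- function(m, kernel) {
  L <- length(kernel)
  if (L == 1) return(m * kernel)
  p <- (L - 1) / 2
  nr <- nrow(m); nc <- ncol(m)
  pm <- reflect_pad(m, p)
  # along columns (vertical)
  out <- matrix(0, nr, ncol(pm))
  for (k in seq_len(L)) out <- out + kernel[k] * pm[k:(k + nr - 1), , drop = FALSE]
  # along rows (horizontal)
  res <- matrix(0, nr, nc)
  for (k in seq_len(L)) res <- res + kernel[k] * out[, k:(k + nc - 1), drop = FALSE]
  res
}

#' Gaussian blur of an intensity raster
#'
#' Separable convolution with a truncated (4 sigma), unit-sum sampled
#' Gaussian; boundaries handled by symmetric reflection.
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels (`0` returns `m` unchanged).
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma) {
  conv_sep(m, gaussian_kernel(sigma))
}

#' Difference-of-Gaussians parameters
#'
#' The defaults (0.5 and 8 px) select small high-contrast structures such as
#' first-row nailfold capillaries while suppressing illumination gradients.
#'
#' @param sigma_low narrow Gaussian standard deviation in px.
#' @param sigma_high wide Gaussian standard deviation in px.
#' @return A list of class `dog_params`.
#' @export
dog_params <- function(sigma_low = 0.5, sigma_high = 8) {
  if (!(sigma_low > 0 && sigma_high > sigma_low)) {
    stop("need 0 < sigma_low < sigma_high", call. = FALSE)
  }
  structure(list(sigma_low = sigma_low, sigma_high = sigma_high),
            class = "dog_params")
}

#' Difference-of-Gaussians band-pass filter
#'
#' Computes `G(sigma_low) * I - G(sigma_high) * I` (narrow minus wide, a
#' high-pass response) with unit-sum truncated kernels and reflective
#' boundaries. Constant images map to exactly zero; the output is signed.
#'
#' @param image a [calibrated_image()] or a plain numeric matrix.
#' @param params a [dog_params()].
#' @return A signed numeric matrix of the input shape.
#' @export
dog_filter <- function(image, params = dog_params()) {
  m <- if (inherits(image, "calibrated_image")) image$pixels else image
  stopifnot(is.matrix(m), inherits(params, "dog_params"))
  r_high <- ceiling(4 * params$sigma_high)
  if (nrow(m) <= r_high || ncol(m) <= r_high) {
    stop(sprintf("raster (%dx%d) smaller than the %d-px kernel support",
                 nrow(m), ncol(m), r_high), call. = FALSE)
  }
  gaussian_blur(m, params$sigma_low) - gaussian_blur(m, params$sigma_high)
}
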