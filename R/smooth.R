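#' Convert Gaussian FWHM to standard deviation
#'
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, the standard relation between a
#' Gaussian's full width at half maximum and its SD.
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return Sigma in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with a kernel of the given full width at
#' half maximum in millimetres. The per-axis sigma in voxels is
#' `fwhm_to_sigma(fwhm_mm) / spacing_mm`. Borders are zero-padded, matching
#' the behaviour of smoothing a skull-stripped image whose background is
#' exactly zero.
#'
#' @param vol A [wmh_volume].
#' @param fwhm_mm Positive kernel FWHM in mm.
#' @return Smoothed [wmh_volume] on the same grid.
#' @export
smooth_gaussian <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "wmh_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("fwhm_mm must be a positive scalar", call. = FALSE)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / spacing_mm(vol)
  arr <- vol$data
  for (axis in 1:3) {
    k <- gaussian_kernel(sigma_vox[axis])
    if (length(k) > 1L)
      arr <- array(.convolve_axis_cpp(as.double(arr), dim(arr), k, axis - 1L),
                   dim = dim(arr))
  }
  out <- vol
  out$data <- arr
  out
}

# Discrete Gaussian kernel, radius 4 sigma, normalised to unit sum.
gaussian_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}
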