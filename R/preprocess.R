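# FWHM of a Gaussian = 2*sqrt(2*ln 2) * sigma
FWHM_TO_SIGMA <- 2 * sqrt(2 * log(2))

# Sampled 1D Gaussian (derivative) kernels, truncated at 4 sigma.
# order 0 is normalized to unit sum; derivative kernels share that
# normalization, and the second-derivative kernel is corrected to exact zero
# DC response so that constant images map to an exactly zero Hessian.
gaussian_kernel <- function(sigma_vox, order = 0) {
  stopifnot(sigma_vox > 0, order %in% 0:2)
  r <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  s <- sum(g)
  if (order == 0) return(g / s)
  if (order == 1) return((-x / sigma_vox^2) * g / s)
  k2 <- ((x^2 - sigma_vox^2) / sigma_vox^4) * g / s
  k2 - sum(k2) * (g / s)
}

conv_axis <- function(vol, kernel, axis) {
  cpp_conv_axis(vol, dim(vol), kernel, as.integer(axis))
}

#' Gaussian PSF model from measured FWHM values
#'
#' Holds the full width at half maximum of the microscope point spread
#' function along each axis, in micrometres. The package assumes a Gaussian
#' PSF, so FWHM and standard deviation are related by
#' `FWHM = 2 * sqrt(2 * ln 2) * sigma` (about 2.3548 sigma). Defaults are
#' FWHM values typical of a two-photon system with 0.8 NA optics.
#'
#' @param fwhm_x,fwhm_y,fwhm_z FWHM in micrometres, all > 0.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(fwhm_x = 0.692, fwhm_y = 0.692, fwhm_z = 2.612) {
  stopifnot(fwhm_x > 0, fwhm_y > 0, fwhm_z > 0)
  structure(list(fwhm_x = fwhm_x, fwhm_y = fwhm_y, fwhm_z = fwhm_z),
            class = "psf_model")
}

#' In-plane blur sigmas that equalize lateral and axial resolution
#'
#' The axial PSF of scanning fluorescence microscopes is wider than the
#' lateral one; left uncorrected, this biases Hessian-based orientation
#' estimates toward the imaging plane. Convolving each XY plane with a 2D
#' Gaussian whose variance is the difference between the axial and lateral
#' PSF variances (`sigma_x^2 = sigma_PSFz^2 - sigma_PSFx^2`, likewise for y)
#' degrades the lateral resolution to match the axial one.
#'
#' @param psf a [psf_model()]; requires `fwhm_z >= fwhm_x` and
#'   `fwhm_z >= fwhm_y`, else the compensating variance would be negative.
#' @return Named numeric vector `c(sigma_x, sigma_y)` in micrometres (zero
#'   for an isotropic PSF).
#' @examples
#' anisotropy_sigmas(psf_model(0.692, 0.692, 2.612))
#' @export
anisotropy_sigmas <- function(psf) {
  stopifnot(inherits(psf, "psf_model"))
  sz <- psf$fwhm_z / FWHM_TO_SIGMA
  sx <- psf$fwhm_x / FWHM_TO_SIGMA
  sy <- psf$fwhm_y / FWHM_TO_SIGMA
  if (sz < sx || sz < sy)
    stop("axial FWHM must be >= lateral FWHM (negative compensation variance)")
  c(sigma_x = sqrt(sz^2 - sx^2), sigma_y = sqrt(sz^2 - sy^2))
}

#' Blur each XY plane with a 2D Gaussian
#'
#' Applies the PSF anisotropy compensation: every XY plane is convolved with
#' a separable 2D Gaussian of the given sigmas (micrometres, converted to
#' voxel units through the volume's voxel size); z is untouched. Zero sigmas
#' are an identity.
#'
#' @param vol a [volume_image()].
#' @param sigmas_um length-2 numeric, in-plane sigmas (um), >= 0; typically
#'   from [anisotropy_sigmas()].
#' @return The blurred [volume_image()].
#' @export
lateral_blur <- function(vol, sigmas_um) {
  stopifnot(is_volume_image(vol), length(sigmas_um) == 2, all(sigmas_um >= 0))
  out <- vol$data
  if (sigmas_um[1] > 0)
    out <- conv_axis(out, gaussian_kernel(sigmas_um[1] / vol$voxel_size_um[1]), 0)
  if (sigmas_um[2] > 0)
    out <- conv_axis(out, gaussian_kernel(sigmas_um[2] / vol$voxel_size_um[2]), 1)
  volume_image(out, vol$voxel_size_um, vol$channel)
}

#' Resample a volume to isotropic voxels (downsampling only)
#'
#' Rescales the lateral (XY) grid by `native / target` with linear
#' interpolation so that the output voxel size is `target` um along every
#' axis. Only downsampling is supported: `target` must be at least the
#' largest native voxel dimension, and the axial voxel size must already
#' equal the target (the stage is meant for stacks acquired with a finer
#' lateral than axial sampling).
#'
#' @param vol a [volume_image()].
#' @param target_um target isotropic voxel size (um).
#' @return A [volume_image()] with voxel size `(target, target, target)`.
#' @export
isotropize <- function(vol, target_um = 1) {
  stopifnot(is_volume_image(vol), target_um > 0)
  vs <- vol$voxel_size_um
  if (target_um < max(vs) - 1e-9)
    stop("upsampling requested: target voxel size must be >= every native ",
         "voxel dimension")
  if (abs(vs[3] - target_um) > 1e-9 * target_um)
    stop("axial voxel size (", vs[3], " um) must already equal the target; ",
         "only lateral resampling is supported")
  d <- dim(vol$data)
  new_nx <- max(1L, round(d[1] * vs[1] / target_um))
  new_ny <- max(1L, round(d[2] * vs[2] / target_um))
  if (new_nx == d[1] && new_ny == d[2])
    return(volume_image(vol$data, rep(target_um, 3), vol$channel))
  out <- cpp_resample_lateral(vol$data, d, as.integer(new_nx),
                              as.integer(new_ny))
  volume_image(out, rep(target_um, 3), vol$channel)
}
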