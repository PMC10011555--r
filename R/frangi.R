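#' Scale-normalized 3D Hessian of a volume image
#'
#' Computes the six unique second derivatives of the image smoothed at scale
#' `sigma_um`, using separable sampled Gaussian-derivative kernels (truncated
#' at 4 sigma), and multiplies them by `sigma^2` (one factor of sigma per
#' derivative order). The scale normalization equalizes the response
#' magnitude across scales; without it, fine image details would dominate
#' coarser structures in any multiscale comparison.
#'
#' @param vol a [volume_image()] with isotropic voxels.
#' @param sigma_um analysis scale in micrometres, > 0.
#' @return A `hessian_field`: list with 3D arrays `hxx, hxy, hxz, hyy, hyz,
#'   hzz` (scale-normalized, in voxel units), plus `sigma_um`, `sigma_vox`
#'   and `voxel_size_um`.
#' @export
scale_space_hessian <- function(vol, sigma_um) {
  stopifnot(is_volume_image(vol), sigma_um > 0)
  h <- stopifnot_isotropic(vol)
  s <- sigma_um / h
  g0 <- gaussian_kernel(s, 0)
  g1 <- gaussian_kernel(s, 1)
  g2 <- gaussian_kernel(s, 2)
  x <- vol$data
  sn <- s^2
  a   <- conv_axis(x, g0, 2)   # G_z * I
  d1z <- conv_axis(x, g1, 2)   # G'_z * I
  d2z <- conv_axis(x, g2, 2)   # G''_z * I
  b   <- conv_axis(a, g0, 1)   # G_y G_z
  cc  <- conv_axis(a, g1, 1)   # G'_y G_z
  e   <- conv_axis(d1z, g1, 1) # G'_y G'_z
  out <- list(
    hxx = conv_axis(b, g2, 0) * sn,
    hxy = conv_axis(cc, g1, 0) * sn,
    hxz = conv_axis(conv_axis(d1z, g0, 1), g1, 0) * sn,
    hyy = conv_axis(conv_axis(a, g2, 1), g0, 0) * sn,
    hyz = conv_axis(e, g0, 0) * sn,
    hzz = conv_axis(conv_axis(d2z, g0, 1), g0, 0) * sn,
    sigma_um = sigma_um, sigma_vox = s, voxel_size_um = vol$voxel_size_um)
  class(out) <- "hessian_field"
  out
}

#' Per-voxel eigenanalysis of a Hessian field
#'
#' Full symmetric eigendecomposition at every voxel, with eigenvalues sorted
#' by increasing magnitude (`|l1| <= |l2| <= |l3|`) and orthonormal
#' eigenvectors matched to them. The dominant eigenvector `v1` (direction of
#' least intensity variation, i.e. the local fiber axis for tubular
#' structures) and the others are sign-normalized to the `z >= 0` hemisphere
#' (ties: `y >= 0`, then `x >= 0`) -- orientations are axial, so a fixed
#' hemisphere makes outputs reproducible.
#'
#' @param h a `hessian_field` from [scale_space_hessian()].
#' @return An `eigen_field`: list with 3D arrays `l1, l2, l3` and 4D arrays
#'   `v1, v2, v3` (last dimension = vector component).
#' @export
eigen_decompose <- function(h) {
  stopifnot(inherits(h, "hessian_field"))
  d <- dim(h$hxx)
  r <- cpp_eig3_full(h$hxx, h$hxy, h$hxz, h$hyy, h$hyz, h$hzz)
  shape_v <- function(m) array(m, c(d, 3))
  out <- list(l1 = array(r$lambda[, 1], d), l2 = array(r$lambda[, 2], d),
              l3 = array(r$lambda[, 3], d),
              v1 = shape_v(r$v1), v2 = shape_v(r$v2), v3 = shape_v(r$v3),
              sigma_um = h$sigma_um)
  class(out) <- "eigen_field"
  out
}

#' Geometric Frangi features from sorted eigenvalues
#'
#' Computes, per voxel, the blobness `R_B = |l1| / sqrt(|l2| |l3|)` (maximal
#' for locally isotropic structures), the aspect ratio
#' `R_A = |l2| / |l3|` (near zero only for plate-like structures), and the
#' structureness `S = sqrt(l1^2 + l2^2 + l3^2)` (the Frobenius norm of the
#' Hessian, small in low-contrast background). Degenerate voxels are guarded:
#' where `|l3| = 0` (and hence all eigenvalues vanish) the conventions
#' `R_B = 0`, `R_A = 1` are used -- such voxels are flat background and the
#' structureness term suppresses them regardless.
#'
#' @param e an `eigen_field` (or any list with arrays `l1, l2, l3`).
#' @return A `frangi_features` list with arrays `RB`, `RA`, `S` and the
#'   positivity mask `pos` (`l2 > 0 | l3 > 0`, the zero branch of the
#'   vesselness).
#' @export
frangi_features <- function(e) {
  a1 <- abs(e$l1); a2 <- abs(e$l2); a3 <- abs(e$l3)
  denom <- sqrt(a2 * a3)
  RB <- a1 * 0
  nz <- denom > 0
  RB[nz] <- a1[nz] / denom[nz]
  RA <- a1 * 0 + 1
  nz3 <- a3 > 0
  RA[nz3] <- a2[nz3] / a3[nz3]
  out <- list(RB = RB, RA = RA, S = sqrt(a1^2 + a2^2 + a3^2),
              pos = e$l2 > 0 | e$l3 > 0)
  class(out) <- "frangi_features"
  out
}

#' Automatic structureness sensitivity
#'
#' Sets the structureness sensitivity to half the maximum Hessian norm of
#' the processed (sub-)volume at the current scale, `gamma = max(S) / 2`. On
#' an all-zero structureness volume (flat chunk) the fallback `gamma = 1` is
#' returned; the vesselness of such a chunk is identically zero anyway since
#' its structureness term vanishes.
#'
#' @param s numeric array of structureness values.
#' @param tol numerical-zero tolerance: maxima below it (e.g. the
#'   floating-point residue of a constant image's Hessian, many orders of
#'   magnitude under any real 8/16-bit structure) trigger the flat-chunk
#'   fallback.
#' @return Scalar gamma.
#' @export
auto_gamma <- function(s, tol = 1e-8) {
  m <- max(s)
  if (m <= tol) 1 else m / 2
}

#' Single-scale vesselness from Frangi features
#'
#' Combines the geometric features into the tubularity score
#' `V = exp(-R_B^2 / 2 beta^2) * (1 - exp(-R_A^2 / 2 alpha^2)) *
#' (1 - exp(-S^2 / 2 gamma^2))`, set to zero wherever `l2 > 0` or `l3 > 0`
#' (bright-on-dark polarity: a bright tube has two large negative
#' eigenvalues). Output is in \[0, 1\].
#'
#' @param f a `frangi_features` object.
#' @param alpha sensitivity to the aspect-ratio feature (> 0); small values
#'   amplify the response to elongated structures. Default 0.001.
#' @param beta sensitivity to blobness (> 0). Default 1.
#' @param gamma structureness sensitivity; `NULL` uses [auto_gamma()].
#' @return Numeric array of vesselness values.
#' @export
vesselness <- function(f, alpha = 0.001, beta = 1, gamma = NULL) {
  stopifnot(inherits(f, "frangi_features"))
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be > 0")
  if (is.null(gamma)) gamma <- auto_gamma(f$S)
  if (gamma <= 0) stop("gamma must be > 0")
  v <- exp(-f$RB^2 / (2 * beta^2)) *
    (1 - exp(-f$RA^2 / (2 * alpha^2))) *
    (1 - exp(-f$S^2 / (2 * gamma^2)))
  v[f$pos] <- 0
  v
}

#' Multiscale Frangi filter with orientation extraction
#'
#' Runs the single-scale vesselness at each requested scale and takes the
#' voxel-wise maximum over scales. The per-voxel orientation is the dominant
#' Hessian eigenvector `v1` at the scale attaining the maximum (ties:
#' smallest scale). Scales are evaluated independently, so the result is
#' identical however the per-scale work is ordered or parallelized.
#'
#' @param vol a [volume_image()] with isotropic voxels.
#' @param scales_um positive, strictly ascending analysis scales (um).
#' @param alpha,beta Frangi sensitivities (see [vesselness()]).
#' @param gamma `NULL` for per-scale automatic tailoring ([auto_gamma()]
#'   computed on this volume), or a numeric vector of per-scale values (e.g.
#'   precomputed globally over a whole chunked volume).
#' @return A `vesselness_result`: list with arrays `V` (multiscale maximum),
#'   `scale_idx` (argmax scale index, 0 where `V = 0`), `vx, vy, vz`
#'   (orientation components, unit-norm where `V > 0`), plus `scales_um`,
#'   `gammas` (values used) and `smax` (per-scale maximum structureness).
#' @export
multiscale_frangi <- function(vol, scales_um, alpha = 0.001, beta = 1,
                              gamma = NULL) {
  stopifnot(is_volume_image(vol))
  scales_um <- as.numeric(scales_um)
  if (length(scales_um) == 0) stop("empty scale list")
  if (any(scales_um <= 0)) stop("scales must be > 0")
  if (is.unsorted(scales_um, strictly = FALSE))
    stop("scales must be ascending")
  if (!is.null(gamma) && length(gamma) != length(scales_um))
    stop("gamma must be NULL or one value per scale")
  d <- dim(vol$data)
  V <- array(0, d)
  scale_idx <- array(0L, d)
  vx <- array(0, d); vy <- array(0, d); vz <- array(1, d)
  gammas <- numeric(length(scales_um))
  smax <- numeric(length(scales_um))
  for (k in seq_along(scales_um)) {
    hh <- scale_space_hessian(vol, scales_um[k])
    eg <- cpp_eig3_v1(hh$hxx, hh$hxy, hh$hxz, hh$hyy, hh$hyz, hh$hzz)
    rm(hh)
    f <- frangi_features(list(l1 = eg$l1, l2 = eg$l2, l3 = eg$l3))
    smax[k] <- max(f$S)
    gammas[k] <- if (is.null(gamma)) auto_gamma(f$S) else gamma[k]
    vk <- vesselness(f, alpha = alpha, beta = beta, gamma = gammas[k])
    upd <- vk > V
    V[upd] <- vk[upd]
    scale_idx[upd] <- k
    vx[upd] <- eg$vx[upd]
    vy[upd] <- eg$vy[upd]
    vz[upd] <- eg$vz[upd]
  }
  out <- list(V = V, scale_idx = scale_idx, vx = vx, vy = vy, vz = vz,
              scales_um = scales_um, gammas = gammas, smax = smax,
              voxel_size_um = vol$voxel_size_um,
              alpha = alpha, beta = beta)
  class(out) <- "vesselness_result"
  out
}

# Per-scale maximum structureness without eigendecomposition:
# S^2 = ||H||_F^2 = hxx^2 + hyy^2 + hzz^2 + 2 (hxy^2 + hxz^2 + hyz^2).
# Used by the chunked pipeline to precompute global gammas cheaply.
structureness_max <- function(vol, scales_um) {
  vapply(scales_um, function(s) {
    hh <- scale_space_hessian(vol, s)
    sqrt(max(hh$hxx^2 + hh$hyy^2 + hh$hzz^2 +
               2 * (hh$hxy^2 + hh$hxz^2 + hh$hyz^2)))
  }, numeric(1))
}

#' Axial orientation vectors to azimuth and elevation angles
#'
#' Converts unit orientation vectors to the in-plane azimuth `phi_xy` and
#' the out-of-plane elevation `theta_zy` (the angle between the fiber and
#' the XY plane; the spherical polar angle is `90 - theta_zy` degrees).
#' Orientations are axial (`v` and `-v` are the same fiber axis), so each
#' vector is first folded to the representative with azimuth in
#' \[-90, 90) degrees: the vector is negated when `vx < 0`, when `vx = 0,
#' vy > 0`, or when `vx = vy = 0, vz < 0`. The elevation sign follows the
#' folded representative and lies in \[-90, 90\].
#'
#' @param v numeric 3-vector, or an n x 3 matrix of unit vectors.
#' @return A data.frame with columns `phi_xy` and `theta_zy` (degrees).
#' @examples
#' vectors_to_angles(c(1, 1, 0) / sqrt(2))   # azimuth 45, elevation 0
#' vectors_to_angles(c(0, 0, 1))             # elevation 90
#' @export
vectors_to_angles <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  stopifnot(ncol(v) == 3)
  n <- sqrt(rowSums(v^2))
  if (any(n == 0 | !is.finite(n))) stop("zero or non-finite vector")
  v <- v / n
  flip <- v[, 1] < 0 |
    (v[, 1] == 0 & v[, 2] > 0) |
    (v[, 1] == 0 & v[, 2] == 0 & v[, 3] < 0)
  v[flip, ] <- -v[flip, , drop = FALSE]
  phi <- atan2(v[, 2], v[, 1]) * 180 / pi
  phi[phi >= 90] <- -90   # guard: vx = 0 rounding can land exactly on +90
  theta <- asin(pmin(pmax(v[, 3], -1), 1)) * 180 / pi
  data.frame(phi_xy = phi, theta_zy = theta)
}
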