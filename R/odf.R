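#' Real symmetric spherical harmonic basis function
#'
#' Evaluates the real even-order spherical harmonic of order `l` and degree
#' `m` at spherical coordinates (`theta` polar, `phi` azimuth, radians):
#' `N_l^m P_l^|m|(cos theta)` times `cos(m phi)` for `m > 0`,
#' `sin(|m| phi)` for `m < 0`, and 1 for `m = 0`, where the normalization is
#' `N_l^0 = sqrt((2l+1) / 4 pi)` and, for `m != 0`,
#' `N_l^m = (-1)^m sqrt(2) sqrt((2l+1)/(4 pi) (l-|m|)!/(l+|m|)!)`. The
#' associated Legendre functions carry the Condon-Shortley phase, which the
#' `(-1)^m` factor cancels; the `sqrt(2)` factor makes the real basis
#' orthonormal. The ordering and normalization are compatible with the
#' real even-order convention used by common ODF viewers (MRtrix).
#'
#' @param l order, even and >= 0 for symmetric (axial) distributions.
#' @param m degree, `|m| <= l`.
#' @param theta,phi polar and azimuth angles in radians (vectorized).
#' @return Numeric vector of basis values.
#' @examples
#' real_sh(0, 0, 0.3, 1.2)          # 1 / (2 sqrt(pi))
#' real_sh(2, 0, 0, 0)              # sqrt(5 / (4 pi))
#' @export
real_sh <- function(l, m, theta, phi) {
  if (abs(m) > l) stop("|m| must be <= l")
  am <- abs(m)
  nlm <- sqrt((2 * l + 1) / (4 * pi))
  if (am > 0)
    nlm <- (-1)^am * sqrt(2) * nlm *
      sqrt(factorial(l - am) / factorial(l + am))
  p <- if (l == 0) rep(1, length(theta))
  else pracma::legendre(l, cos(theta))[am + 1, ]
  trig <- if (m > 0) cos(m * phi) else if (m < 0) sin(am * phi) else 1
  nlm * p * trig
}

#' (l, m) index table of the real even-order basis
#'
#' @param lmax maximum (even) order.
#' @return data.frame with columns `l` and `m`: even `l` ascending, `m` from
#'   `-l` to `l` -- 28 rows for `lmax = 6`.
#' @export
sh_index_table <- function(lmax = 6) {
  ls <- seq(0, lmax, by = 2)
  do.call(rbind, lapply(ls, function(l) data.frame(l = l, m = -l:l)))
}

#' Analytical spherical harmonic coefficients of a set of fiber orientations
#'
#' Models the `K` orientations in a compartment as Dirac deltas on the unit
#' sphere; the sifting property then gives each coefficient in closed form
#' as the mean of the corresponding basis function over the orientations,
#' `c_lm = (1/K) sum_k Y_lm(theta_k, phi_k)`, with no binning or quadrature.
#' Only even orders are stored: fiber orientations are axial (sign-free),
#' so every orientation contributes as an axis and all odd-order terms
#' vanish identically.
#'
#' @param orientations matrix with `K` rows: either 2 columns
#'   `(theta, phi)` in radians, or 3 columns of (unit) direction vectors.
#' @param lmax maximum even order of the expansion (default 6).
#' @return Numeric coefficient vector ordered as [sh_index_table()] (length
#'   28 for `lmax = 6`), with attribute `K`. `K = 0` input yields all-zero
#'   coefficients with `K = 0` (an empty compartment, not an error).
#' @export
sh_coefficients <- function(orientations, lmax = 6) {
  idx <- sh_index_table(lmax)
  if (is.null(dim(orientations)))
    orientations <- matrix(orientations, ncol = length(orientations))
  if (nrow(orientations) == 0)
    return(structure(numeric(nrow(idx)), K = 0L))
  if (ncol(orientations) == 3) {
    v <- orientations / sqrt(rowSums(orientations^2))
    theta <- acos(pmin(pmax(v[, 3], -1), 1))
    phi <- atan2(v[, 2], v[, 1])
  } else if (ncol(orientations) == 2) {
    theta <- orientations[, 1]
    phi <- orientations[, 2]
  } else stop("orientations must have 2 (theta, phi) or 3 (x, y, z) columns")
  if (any(!is.finite(theta)) || any(!is.finite(phi)))
    stop("non-finite orientation angles")
  coef <- vapply(seq_len(nrow(idx)), function(i)
    mean(real_sh(idx$l[i], idx$m[i], theta, phi)), numeric(1))
  structure(coef, K = length(theta))
}

#' Super-voxel ODF map from a masked orientation field
#'
#' Partitions the volume into axis-aligned cubes of side `sv_size_um`
#' (edge super-voxels may be partial and are retained) and computes the
#' analytical spherical harmonic coefficients of the masked orientations
#' inside each. Every native-resolution orientation vector contributes
#' individually, whatever the super-voxel size. Super-voxels containing no
#' orientations carry all-zero coefficients and `K = 0`.
#'
#' @param field an `orientation_field` from [apply_masks()].
#' @param sv_size_um super-voxel edge length in micrometres (>= voxel size).
#' @param lmax maximum even order (default 6).
#' @return An `odf_field`: list with `coef` (4D array: super-voxel grid x
#'   number of coefficients), `K` (orientation counts), `sv_size_um`,
#'   `lmax`, `sv_vox` (super-voxel edge in voxels) and `voxel_size_um`.
#' @export
supervoxel_odfs <- function(field, sv_size_um, lmax = 6) {
  stopifnot(inherits(field, "orientation_field"))
  vs <- field$voxel_size_um
  if (sv_size_um < max(vs)) stop("sv_size_um must be >= the voxel size")
  if (diff(range(vs)) > 1e-9 * max(vs))
    stop("orientation field must have isotropic voxels")
  sv_vox <- max(1L, round(sv_size_um / vs[1]))
  d <- dim(field$mask)
  grid <- pmax(1L, as.integer(ceiling(d / sv_vox)))
  idx <- sh_index_table(lmax)
  ncoef <- nrow(idx)
  coef <- array(0, c(grid, ncoef))
  K <- array(0L, grid)
  w <- which(field$mask)
  if (length(w)) {
    vox <- arrayInd(w, d)
    sv <- (vox - 1L) %/% sv_vox         # 0-based super-voxel coordinates
    svid <- sv[, 1] + grid[1] * (sv[, 2] + grid[2] * sv[, 3]) + 1L
    v <- cbind(field$vx[w], field$vy[w], field$vz[w])
    theta <- acos(pmin(pmax(v[, 3], -1), 1))
    phi <- atan2(v[, 2], v[, 1])
    basis <- vapply(seq_len(ncoef), function(i)
      real_sh(idx$l[i], idx$m[i], theta, phi), numeric(length(theta)))
    basis <- matrix(basis, ncol = ncoef)
    sums <- rowsum(basis, group = svid)
    ids <- as.integer(rownames(sums))
    counts <- as.vector(rowsum(rep(1L, length(svid)), group = svid))
    K[ids] <- counts
    nsv <- prod(grid)
    for (i in seq_len(ncoef))
      coef[ids + (i - 1) * nsv] <- sums[, i] / counts
  }
  structure(list(coef = coef, K = K, sv_size_um = sv_size_um, lmax = lmax,
                 sv_vox = sv_vox, voxel_size_um = vs),
            class = "odf_field")
}

#' Synthesize ODF amplitudes from spherical harmonic coefficients
#'
#' Evaluates the truncated expansion `f(theta, phi) = sum c_lm Y_lm` at the
#' given directions; useful for locating ODF lobe maxima on a dense sphere
#' grid.
#'
#' @param coef coefficient vector ordered as [sh_index_table()].
#' @param theta,phi polar and azimuth angles in radians (vectorized).
#' @return Numeric vector of amplitudes.
#' @export
sh_synthesize <- function(coef, theta, phi) {
  lmax <- (sqrt(8 * length(coef) + 1) - 3) / 2
  idx <- sh_index_table(round(lmax))
  if (nrow(idx) != length(coef)) stop("coefficient length does not match an even-order basis")
  out <- numeric(length(theta))
  for (i in seq_len(nrow(idx)))
    if (coef[i] != 0)
      out <- out + coef[i] * real_sh(idx$l[i], idx$m[i], theta, phi)
  out
}

#' Write an ODF field as a NIfTI coefficient image
#'
#' Stores the coefficients as a 4D volume (super-voxel grid x coefficients,
#' float64 so a round trip is bit-identical) with the super-voxel size
#' recorded as the voxel spacing, in the real even-order coefficient
#' ordering common to ODF viewers (MRtrix). A JSON sidecar records `lmax`,
#' the super-voxel size and the path of the orientation-count (K) map,
#' which is written alongside as a 16-bit multi-page TIFF.
#'
#' @param odf an `odf_field` from [supervoxel_odfs()].
#' @param path output NIfTI path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_odf <- function(odf, path) {
  stopifnot(inherits(odf, "odf_field"))
  coef <- odf$coef
  attr(coef, "pixdim") <- c(rep(odf$sv_size_um, 3), 1)
  img <- RNifti::asNifti(coef, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  kpath <- paste0(tools::file_path_sans_ext(path, compression = TRUE), "_K.tif")
  kvol <- volume_image(array(as.numeric(odf$K), dim(odf$K)),
                       odf$sv_size_um)
  write_volume(kvol, kpath, bits = 16)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(lmax = odf$lmax, sv_size_um = odf$sv_size_um,
         n_coefficients = dim(odf$coef)[4], k_map = basename(kpath),
         n_empty_supervoxels = sum(odf$K == 0)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back an ODF coefficient image
#'
#' @param path NIfTI path written by [write_odf()].
#' @return List with `coef` (4D array), `sv_size_um` and `lmax`.
#' @export
read_odf <- function(path) {
  img <- RNifti::readNifti(path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  list(coef = array(as.numeric(img), dim(img)),
       sv_size_um = RNifti::pixdim(img)[1],
       lmax = meta$lmax)
}
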