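# Scale-response characterization of the vesselness filter on ideal
# cylinders: cross-sectional response against the scale-to-radius ratio (or
# against the fiber diameter at fixed scale).

# Full width at half maximum of a 1D profile, measured between the outermost
# half-maximum crossings with linear interpolation. NA when the profile
# never drops below half maximum on either side.
profile_fwhm <- function(p) {
  m <- max(p)
  if (m <= 0) return(NA_real_)
  half <- m / 2
  above <- which(p >= half)
  i1 <- above[1]
  i2 <- above[length(above)]
  if (i1 == 1 || i2 == length(p)) return(NA_real_)
  left <- (i1 - 1) + (half - p[i1 - 1]) / (p[i1] - p[i1 - 1])
  right <- i2 + (half - p[i2]) / (p[i2 + 1] - p[i2])
  right - left
}

# Cross-sectional vesselness profile of a z-aligned cylinder phantom at the
# axis midpoint: V along x through the center. Only a central z-slab
# covering the Gaussian support (4 sigma) is filtered; the mid-slice values
# are identical to a full-volume run since the kernel never reaches the slab
# boundary from the center.
cylinder_profile <- function(phantom, sigma_um, alpha = 0.001, beta = 1) {
  h <- phantom$volume$voxel_size_um[1]
  d <- dim(phantom$volume$data)
  midz <- (d[3] + 1) %/% 2
  hw <- min(ceiling(4 * sigma_um / h), (d[3] - 1) %/% 2)
  slab <- phantom$volume$data[, , (midz - hw):(midz + hw), drop = FALSE]
  res <- multiscale_frangi(volume_image(slab, h), sigma_um,
                           alpha = alpha, beta = beta)
  dd <- dim(res$V)
  mid <- (dd + 1) %/% 2
  res$V[, mid[2], mid[3]]
}

sweep_row <- function(profile, diameter_px) {
  mid <- (length(profile) + 1) %/% 2
  data.frame(peak = max(profile), center = profile[mid],
             fwhm_norm = profile_fwhm(profile) / diameter_px)
}

#' Vesselness response of a cylinder across scale-to-radius ratios
#'
#' Generates one noiseless cylinder phantom (axis along z) and filters it
#' with a single-scale vesselness filter at `sigma = ratio * radius` for
#' each requested ratio. Each cross-sectional 1D response profile at the
#' axis midpoint is summarized by its peak, its value on the axis (the
#' vesselness is already normalized: a perfectly preserved structure of unit
#' contrast responds at the ideal-tube ceiling `1 - exp(-2)` under automatic
#' gamma), and its FWHM relative to the true diameter. Scales much smaller
#' than the radius yield a spurious high-probability ridge at the fiber edge
#' with a hollow axis (`center` collapses); scales much larger smear the
#' response beyond the true cross-section (`fwhm_norm` grows past 1).
#'
#' @param radius_um cylinder radius (um).
#' @param px_per_um sampling density of the phantom.
#' @param aspect_ratio cylinder length / diameter (default 12).
#' @param ratios scale-to-radius ratios to sweep.
#' @param alpha,beta Frangi sensitivities.
#' @return data.frame with columns `ratio`, `sigma_um`, `peak`, `center`
#'   and `fwhm_norm`.
#' @seealso [optimal_response_row()] for the matched-scale selection.
#' @export
scale_sweep_cylinder <- function(radius_um = 1, px_per_um = 10,
                                 aspect_ratio = 12,
                                 ratios = seq(0.1, 1.5, by = 0.1),
                                 alpha = 0.001, beta = 1) {
  stopifnot(all(ratios > 0))
  ph <- make_cylinder(radius_um, aspect_ratio = aspect_ratio,
                      px_per_um = px_per_um,
                      sigma_max_um = max(ratios) * radius_um)
  out <- lapply(ratios, function(r) {
    p <- cylinder_profile(ph, r * radius_um, alpha, beta)
    cbind(data.frame(ratio = r, sigma_um = r * radius_um),
          sweep_row(p, 2 * radius_um * px_per_um))
  })
  do.call(rbind, out)
}

#' Vesselness response across fiber diameters at a fixed scale
#'
#' Complements [scale_sweep_cylinder()]: the filter scale is held fixed and
#' the cylinder diameter swept, asking which fiber caliber the scale is
#' matched to.
#'
#' @param sigma_um fixed filter scale (um).
#' @param diameters_um fiber diameters to sweep (um).
#' @param px_per_um phantom sampling density (1 px/um emulates
#'   isotropically resampled stacks).
#' @param aspect_ratio cylinder length / diameter.
#' @param alpha,beta Frangi sensitivities.
#' @return data.frame with columns `diameter_um`, `ratio` (scale-to-radius),
#'   `peak`, `center` and `fwhm_norm`.
#' @export
diameter_sweep <- function(sigma_um = 1.25, diameters_um = 3:7,
                           px_per_um = 1, aspect_ratio = 12,
                           alpha = 0.001, beta = 1) {
  stopifnot(all(diameters_um > 0), sigma_um > 0)
  out <- lapply(diameters_um, function(d) {
    ph <- make_cylinder(d / 2, aspect_ratio = aspect_ratio,
                        px_per_um = px_per_um,
                        sigma_max_um = max(sigma_um, d / 2))
    p <- cylinder_profile(ph, sigma_um, alpha, beta)
    cbind(data.frame(diameter_um = d, ratio = sigma_um / (d / 2)),
          sweep_row(p, d * px_per_um))
  })
  do.call(rbind, out)
}

#' Matched-scale row of a cylinder response sweep
#'
#' Selects the sweep entry that best preserves both the original intensity
#' and the original cross-sectional size of the tubular structure. The
#' axis-midpoint response separates the two failure regimes sharply: below
#' the matched scale-to-radius ratio the filter responds with a spurious
#' ridge at the fiber edge and a hollow (near-zero) axis, while at and above
#' it the axis response sits at the sweep ceiling -- but the response FWHM
#' then grows monotonically past the true diameter. The optimum is
#' therefore the preservation boundary: among rows whose axis response
#' reaches at least `preserve` (default 95%) of the sweep-wide maximum, the
#' one with the smallest scale-to-radius ratio (for a diameter sweep at
#' fixed scale, equivalently the largest fiber caliber the scale still
#' fully engages).
#'
#' @param sweep data.frame from [scale_sweep_cylinder()] or
#'   [diameter_sweep()] (columns `ratio`, `peak`, `center`).
#' @param preserve intensity-preservation threshold as a fraction of the
#'   sweep maximum.
#' @return The index of the optimal row.
#' @export
optimal_response_row <- function(sweep, preserve = 0.95) {
  ceiling_v <- max(sweep$peak)
  ok <- which(sweep$center >= preserve * ceiling_v)
  if (!length(ok)) stop("no sweep row preserves the axis response")
  ok[which.min(sweep$ratio[ok])]
}
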