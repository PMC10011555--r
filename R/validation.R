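# Rotation-based validation of the orientation pipeline: random patches are
# sliced from image stacks, rotated in- and out-of-plane by known angles,
# re-analyzed, and the recovered angular distributions compared (after
# rotating the angular reference system) with those of the unrotated patch.

N_ANGLE_BINS <- 180L

new_angular_distribution <- function(counts, kind) {
  stopifnot(length(counts) == N_ANGLE_BINS, kind %in% c("phi", "theta"))
  structure(list(counts = as.numeric(counts), kind = kind),
            class = "angular_distribution")
}

angle_bin_centers <- function() seq(-89.5, by = 1, length.out = N_ANGLE_BINS)

bin_angles <- function(deg) {
  idx <- floor(deg + 90) + 1
  idx[idx > N_ANGLE_BINS] <- N_ANGLE_BINS   # +90 degrees folds onto the last bin
  idx[idx < 1] <- 1L
  tabulate(idx, N_ANGLE_BINS)
}

# Maximum extent along the second axis of an (a x b) rectangle rotated by up
# to 45 degrees in its plane.
rotated_extent <- function(a, b) {
  if (atan2(a, b) <= pi / 4) sqrt(a^2 + b^2) else (a + b) / sqrt(2)
}

#' Randomly sample analysis patches from an image stack
#'
#' Extracts `n` patches whose core measures `patch_um` (x, y, z), extended
#' on every side by a margin that accommodates both the fill-in of in-plane
#' (about z) and out-of-plane (about x) rotations up to 45 degrees of the
#' core region, and the boundary artifacts of Gaussian filtering up to
#' `sigma_max_um` (4 sigma). Patch corners are drawn uniformly over the
#' valid region; each patch is independently flipped along each axis with
#' probability 1/2, decorrelating the results from the stack's preferential
#' orientation. Sampling is deterministic given `seed`.
#'
#' @param stack a [volume_image()] with isotropic voxels.
#' @param n number of patches (0 gives an empty list).
#' @param seed RNG seed.
#' @param patch_um core patch extent in micrometres (x, y, z).
#' @param sigma_max_um largest filter scale the patches will be analyzed at.
#' @param flip logical: apply the random axis inversions.
#' @return List of `patch` objects: each carries the extended flipped
#'   sub-volume (`volume`), the core index ranges within it (`core`), the
#'   per-axis margins, the applied `flips`, and the extended-patch `corner`
#'   in the stack.
#' @export
sample_patches <- function(stack, n, seed = 1, patch_um = c(75, 75, 15),
                           sigma_max_um = 1.5, flip = TRUE) {
  stopifnot(is_volume_image(stack), n >= 0)
  h <- stopifnot_isotropic(stack)
  core <- pmax(1L, round(patch_um / h))
  pad <- ceiling(4 * sigma_max_um / h)
  # the rotated valid region must cover the filter support of every core
  # voxel, so the rotation fill-in margin is computed for the pad-dilated core
  cp <- core + 2 * pad
  margin <- c(
    ceiling((rotated_extent(cp[2], cp[1]) - cp[1]) / 2),
    ceiling(max(rotated_extent(cp[1], cp[2]),
                rotated_extent(cp[3], cp[2])) / 2 - cp[2] / 2),
    ceiling((rotated_extent(cp[2], cp[3]) - cp[3]) / 2)) + pad
  ext <- core + 2L * margin
  d <- dim(stack$data)
  hi <- d - ext + 1L
  if (any(hi < 1L))
    stop(sprintf("stack (%s voxels) too small for %s-voxel extended patches",
                 paste(d, collapse = "x"), paste(ext, collapse = "x")))
  if (n == 0) return(list())
  draws <- with_seed(seed, list(
    corner = cbind(sample.int(hi[1], n, replace = TRUE),
                   sample.int(hi[2], n, replace = TRUE),
                   sample.int(hi[3], n, replace = TRUE)),
    flips = matrix(runif(3 * n) < 0.5, ncol = 3) & flip))
  lapply(seq_len(n), function(i) {
    co <- draws$corner[i, ]
    sub <- stack$data[co[1]:(co[1] + ext[1] - 1),
                      co[2]:(co[2] + ext[2] - 1),
                      co[3]:(co[3] + ext[3] - 1), drop = FALSE]
    fl <- draws$flips[i, ]
    if (fl[1]) sub <- sub[ext[1]:1, , , drop = FALSE]
    if (fl[2]) sub <- sub[, ext[2]:1, , drop = FALSE]
    if (fl[3]) sub <- sub[, , ext[3]:1, drop = FALSE]
    structure(list(
      volume = volume_image(sub, h, stack$channel),
      core = list(x = margin[1] + seq_len(core[1]),
                  y = margin[2] + seq_len(core[2]),
                  z = margin[3] + seq_len(core[3])),
      margin = margin, flips = fl, corner = co, id = i,
      valid = NULL, rotation = NULL), class = "patch")
  })
}

#' Rotate a patch about the z- or x-axis
#'
#' Resamples the patch volume under an in-plane (about z) or out-of-plane
#' (about x) rotation through the patch center, using cubic B-spline
#' interpolation with prefiltering. Positive angles rotate the content
#' right-handedly about the +axis. Voxels whose source position falls
#' outside the original patch are flagged invalid (and excluded from any
#' later angular statistics) rather than trusted as zero-filled intensities.
#'
#' @param patch a `patch` from [sample_patches()], or a [volume_image()].
#' @param axis `"z"` or `"x"`.
#' @param angle_deg rotation angle in degrees, `|angle| <= 45`.
#' @return The input object with the rotated volume, a logical `valid`
#'   array, and the rotation recorded.
#' @export
rotate_patch <- function(patch, axis = c("z", "x"), angle_deg) {
  axis <- match.arg(axis)
  if (abs(angle_deg) > 45) stop("|angle_deg| must be <= 45")
  vol <- if (inherits(patch, "patch")) patch$volume else patch
  stopifnot(is_volume_image(vol))
  ax <- if (axis == "z") 2L else 0L
  r <- cpp_rotate_axis(vol$data, dim(vol$data), ax, angle_deg)
  out_vol <- volume_image(r$volume, vol$voxel_size_um, vol$channel)
  if (inherits(patch, "patch")) {
    patch$volume <- out_vol
    patch$valid <- r$valid
    patch$rotation <- list(axis = axis, angle_deg = angle_deg)
    patch
  } else {
    structure(list(volume = out_vol, valid = r$valid,
                   rotation = list(axis = axis, angle_deg = angle_deg)),
              class = "rotated_volume")
  }
}

#' Angular distributions of a masked orientation field
#'
#' Converts the retained orientation vectors to azimuth and elevation
#' angles ([vectors_to_angles()]) and bins each into 180 contiguous 1-degree
#' bins spanning the 180-degree axial range (-90 to 90 degrees; both
#' histograms use the same layout so downstream overlap measures apply
#' uniformly).
#'
#' @param field an `orientation_field` from [apply_masks()].
#' @param exclude optional logical array (same shape): voxels to leave out,
#'   e.g. rotation fill-in and filter margins.
#' @return List with elements `phi` and `theta`, each an
#'   `angular_distribution` (`counts`, `kind`).
#' @export
angle_histograms <- function(field, exclude = NULL) {
  stopifnot(inherits(field, "orientation_field"))
  keep <- field$mask
  if (!is.null(exclude)) keep <- keep & !exclude
  w <- which(keep)
  if (length(w)) {
    ang <- vectors_to_angles(cbind(field$vx[w], field$vy[w], field$vz[w]))
    list(phi = new_angular_distribution(bin_angles(ang$phi_xy), "phi"),
         theta = new_angular_distribution(bin_angles(ang$theta_zy), "theta"))
  } else {
    list(phi = new_angular_distribution(numeric(N_ANGLE_BINS), "phi"),
         theta = new_angular_distribution(numeric(N_ANGLE_BINS), "theta"))
  }
}

#' Rotate the angular reference system of a distribution
#'
#' Shifts a reference angular histogram circularly by the applied rotation
#' angle (integer-degree bins, wrapping on the 180-degree axial circle), so
#' that it can be compared directly with the distribution measured on the
#' rotated image. In-plane rotations (about z) act on azimuth
#' distributions; out-of-plane rotations (about x) act on elevation
#' distributions.
#'
#' @param dist an `angular_distribution`.
#' @param axis rotation axis, `"z"` or `"x"`; must match the distribution
#'   kind (z with azimuth, x with elevation).
#' @param angle_deg applied rotation angle (degrees; rounded to whole bins).
#' @return The shifted `angular_distribution`.
#' @export
correct_reference <- function(dist, axis = c("z", "x"), angle_deg) {
  axis <- match.arg(axis)
  stopifnot(inherits(dist, "angular_distribution"))
  want <- if (axis == "z") "phi" else "theta"
  if (dist$kind != want)
    stop(sprintf("%s-rotations correct %s distributions, not %s",
                 axis, want, dist$kind))
  k <- round(angle_deg) %% N_ANGLE_BINS
  src <- ((seq_len(N_ANGLE_BINS) - 1 - k) %% N_ANGLE_BINS) + 1
  new_angular_distribution(dist$counts[src], dist$kind)
}

#' Circular median of an axial angular distribution
#'
#' The median of 180-degree-periodic (axial) angles, computed by an
#' exhaustive scan over the bin centers: the candidate minimizing the
#' count-weighted sum of axial angular distances (`min(|d|, 180 - |d|)`).
#' Ties resolve to the smallest candidate angle.
#'
#' @param dist an `angular_distribution` with nonzero mass.
#' @return The median angle in degrees (a bin center).
#' @export
circular_median <- function(dist) {
  stopifnot(inherits(dist, "angular_distribution"))
  if (sum(dist$counts) <= 0) stop("zero-mass distribution")
  centers <- angle_bin_centers()
  d <- abs(outer(centers, centers, "-"))
  d <- pmin(d, 180 - d)
  centers[which.min(as.vector(d %*% dist$counts))]
}

#' Inter-median distance between two axial angular distributions
#'
#' Difference of the two circular medians on the 180-degree axial circle,
#' `median(q) - median(p)`, wrapped into (-90, 90\] degrees; antipodally
#' close medians (e.g. -85 and 85 degrees) are 10 degrees apart, not 170.
#'
#' @param p,q `angular_distribution`s with nonzero mass.
#' @return Signed distance in degrees.
#' @export
inter_median_distance <- function(p, q) {
  d <- circular_median(q) - circular_median(p)
  d <- ((d + 90) %% 180) - 90
  if (d == -90) d <- 90
  d
}

#' Bhattacharyya coefficient of two angular distributions
#'
#' Overlap measure `sum(sqrt(p * q))` over the 180 bins of the normalized
#' distributions; 1 for identical distributions, 0 for disjoint supports.
#'
#' @param p,q `angular_distribution`s with nonzero total mass (normalized
#'   internally).
#' @return Coefficient in \[0, 1\].
#' @export
bhattacharyya <- function(p, q) {
  stopifnot(inherits(p, "angular_distribution"),
            inherits(q, "angular_distribution"))
  sp <- sum(p$counts)
  sq <- sum(q$counts)
  if (sp <= 0 || sq <= 0) stop("zero-mass distribution")
  sum(sqrt((p$counts / sp) * (q$counts / sq)))
}

# Analyze one (possibly rotated) patch: multiscale vesselness, Li fiber
# mask, orientations, and angular histograms over core, valid, fiber voxels.
process_patch <- function(patch, scales_um, alpha = 0.001, beta = 1) {
  res <- multiscale_frangi(patch$volume, scales_um, alpha = alpha,
                           beta = beta)
  fiber <- suppressWarnings(li_fiber_mask(res$V))
  d <- dim(res$V)
  keep <- array(FALSE, d)
  keep[patch$core$x, patch$core$y, patch$core$z] <- TRUE
  if (!is.null(patch$valid)) keep <- keep & patch$valid
  field <- apply_masks(res, fiber & keep)
  hist <- angle_histograms(field)
  list(phi = hist$phi, theta = hist$theta,
       fiber_fraction = sum(fiber & keep) / sum(keep))
}

#' Run the rotation-based validation protocol
#'
#' For each stack, `n_patches` extended patches are sampled and randomly
#' flipped; each is analyzed unrotated (the reference) and after every test
#' rotation about the z-axis (in-plane) and the x-axis (out-of-plane). The
#' azimuth distribution is scored for z-rotations and the elevation
#' distribution for x-rotations, against the reference distribution with
#' its angular reference system rotated by the applied angle (expressed in
#' each patch's own flipped frame: an axis inversion of the patch reverses
#' the sense in which an out-of-plane rotation tilts its content, so the
#' elevation correction sign follows the x/y flip parity). Patches whose
#' fiber fraction falls below `fiber_fraction_min` at any tested rotation
#' (or unrotated) are dropped entirely, so every retained angle aggregates
#' the same patches.
#'
#' @param stacks a [volume_image()] or list of them (isotropic voxels).
#' @param seed RNG seed controlling patch sampling and flips.
#' @param scales_um Frangi scales (um); the defaults 1, 1.25 and 1.5 um are
#'   matched to fiber diameters of 4, 5 and 6 um.
#' @param n_patches patches sampled per stack.
#' @param angles_deg nonzero test rotation angles (degrees; default
#'   -45 to 45 in 5-degree steps, 18 rotations).
#' @param alpha,beta Frangi sensitivities.
#' @param patch_um core patch extent (um).
#' @param fiber_fraction_min minimum fraction of fiber-classified voxels
#'   (default 1%).
#' @param verbose print per-patch progress.
#' @return A `validation_result`: list with `records` (one row per retained
#'   patch, axis and angle: inter-median distances and Bhattacharyya
#'   coefficients of the matched angle kind; unmatched kinds are `NA`),
#'   `summary` (per axis and angle: median and IQR of the absolute
#'   inter-median distance and of the Bhattacharyya coefficient),
#'   `n_retained`, `n_dropped` and the protocol parameters.
#' @export
run_validation <- function(stacks, seed = 1, scales_um = c(1, 1.25, 1.5),
                           n_patches = 10,
                           angles_deg = setdiff(seq(-45, 45, by = 5), 0),
                           alpha = 0.001, beta = 1,
                           patch_um = c(75, 75, 15),
                           fiber_fraction_min = 0.01, verbose = FALSE) {
  if (is_volume_image(stacks)) stacks <- list(stacks)
  if (!length(stacks)) stop("need at least one stack")
  stopifnot(all(vapply(stacks, is_volume_image, logical(1))))
  sigma_max <- max(scales_um)
  records <- list()
  n_retained <- 0L
  n_dropped <- 0L
  for (s in seq_along(stacks)) {
    patches <- sample_patches(stacks[[s]], n_patches,
                              seed = seed + 7919L * s,
                              patch_um = patch_um, sigma_max_um = sigma_max)
    for (patch in patches) {
      ref <- process_patch(patch, scales_um, alpha, beta)
      ok <- ref$fiber_fraction >= fiber_fraction_min
      rows <- list()
      if (ok) {
        parity <- if (sum(patch$flips[1:2]) %% 2 == 0) 1 else -1
        for (axis in c("z", "x")) {
          for (ang in angles_deg) {
            pr <- process_patch(rotate_patch(patch, axis, ang),
                                scales_um, alpha, beta)
            if (pr$fiber_fraction < fiber_fraction_min) {
              ok <- FALSE
              break
            }
            if (axis == "z") {
              cref <- correct_reference(ref$phi, "z", ang)
              rows[[length(rows) + 1]] <- data.frame(
                stack = s, patch = patch$id, axis = axis, angle_deg = ang,
                dmed_phi = inter_median_distance(cref, pr$phi),
                bc_phi = bhattacharyya(cref, pr$phi),
                dmed_theta = NA_real_, bc_theta = NA_real_,
                fiber_fraction = pr$fiber_fraction)
            } else {
              cref <- correct_reference(ref$theta, "x", parity * ang)
              rows[[length(rows) + 1]] <- data.frame(
                stack = s, patch = patch$id, axis = axis, angle_deg = ang,
                dmed_phi = NA_real_, bc_phi = NA_real_,
                dmed_theta = inter_median_distance(cref, pr$theta),
                bc_theta = bhattacharyya(cref, pr$theta),
                fiber_fraction = pr$fiber_fraction)
            }
          }
          if (!ok) break
        }
      }
      if (ok) {
        n_retained <- n_retained + 1L
        records <- c(records, rows)
      } else {
        n_dropped <- n_dropped + 1L
      }
      if (verbose)
        message(sprintf("stack %d patch %d: %s", s, patch$id,
                        if (ok) "retained" else "dropped"))
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(stack = integer(), patch = integer(), axis = character(),
               angle_deg = numeric(), dmed_phi = numeric(),
               bc_phi = numeric(), dmed_theta = numeric(),
               bc_theta = numeric(), fiber_fraction = numeric())
  summary <- summarize_validation(records)
  structure(list(records = records, summary = summary,
                 n_retained = n_retained, n_dropped = n_dropped,
                 scales_um = scales_um, angles_deg = angles_deg,
                 patch_um = patch_um,
                 fiber_fraction_min = fiber_fraction_min, seed = seed),
            class = "validation_result")
}

summarize_validation <- function(records) {
  if (!nrow(records))
    return(data.frame(axis = character(), angle_deg = numeric(),
                      n = integer(), med_abs_dmed = numeric(),
                      iqr_abs_dmed = numeric(), med_bc = numeric()))
  parts <- split(records, list(records$axis, records$angle_deg), drop = TRUE)
  out <- lapply(parts, function(g) {
    dmed <- if (g$axis[1] == "z") g$dmed_phi else g$dmed_theta
    bc <- if (g$axis[1] == "z") g$bc_phi else g$bc_theta
    data.frame(axis = g$axis[1], angle_deg = g$angle_deg[1], n = nrow(g),
               med_abs_dmed = median(abs(dmed)),
               iqr_abs_dmed = stats::IQR(abs(dmed)),
               med_bc = median(bc))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$axis, out$angle_deg), ]
}

#' Write validation results to disk
#'
#' @param res a `validation_result`.
#' @param dir output directory (created if missing): per-record table as
#'   CSV, per-rotation summary and protocol parameters as JSON.
#' @return `dir`, invisibly.
#' @export
write_validation <- function(res, dir) {
  stopifnot(inherits(res, "validation_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$records, file.path(dir, "validation_records.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = res$summary, n_retained = res$n_retained,
         n_dropped = res$n_dropped, scales_um = res$scales_um,
         patch_um = res$patch_um,
         fiber_fraction_min = res$fiber_fraction_min, seed = res$seed),
    file.path(dir, "validation_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
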