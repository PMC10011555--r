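#' @name phantoms
#' @title Synthetic phantom volumes with known ground-truth orientations
#'
#' @description Generators for simple solids (cylinders, blobs, plates,
#' crossings, soma-like spheres, multi-fiber stacks) rendered on a voxel grid
#' with positive contrast (bright structure on a dark background, the
#' polarity the vesselness filter is built for). Edge voxels receive
#' partial-volume intensities from 3x3x3 supersampling, so that structure
#' boundaries are anti-aliased rather than staircased; hard intensity steps
#' would otherwise create spurious Hessian ridges. Each generator returns a
#' `phantom` object carrying the rendered [volume_image()], a boolean
#' `structure_mask`, and ground-truth axial orientations per structure.
#'
#' Grids are auto-sized to the structure bounding box plus a padding of
#' `ceil(4 * sigma_max_um)` voxels per side, so that later Gaussian filtering
#' at scales up to `sigma_max_um` never wraps boundary artifacts onto the
#' structure.
NULL

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  expr
}

new_phantom <- function(volume, structure_mask, truth, params) {
  structure(list(volume = volume, structure_mask = structure_mask,
                 truth = truth, params = params),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s, %s voxels, %d structure voxel(s)\n",
              x$params$kind, paste(dim(x$volume$data), collapse = " x "),
              sum(x$structure_mask)))
  invisible(x)
}

# Voxel-center coordinates (um) of an n-voxel axis at sampling h um/voxel,
# centred on the grid midpoint.
grid_coords <- function(n, h) (seq_len(n) - (n + 1) / 2) * h

# Render a solid from an approximate signed boundary distance function
# (negative inside, in um). Voxels within one voxel of the boundary are
# supersampled 3x per axis; all others are classified by their center.
render_solid <- function(dims, h, signed_dist) {
  cx <- grid_coords(dims[1], h)
  cy <- grid_coords(dims[2], h)
  cz <- grid_coords(dims[3], h)
  px <- array(cx, dims)
  py <- array(rep(cy, each = dims[1]), dims)
  pz <- array(rep(cz, each = dims[1] * dims[2]), dims)
  m <- signed_dist(px, py, pz)
  coverage <- array(0, dims)
  coverage[m < -h] <- 1
  shell <- which(abs(m) <= h)
  if (length(shell)) {
    offs <- (c(-1, 0, 1) / 3) * h
    cnt <- numeric(length(shell))
    sx <- px[shell]; sy <- py[shell]; sz <- pz[shell]
    for (ox in offs) for (oy in offs) for (oz in offs)
      cnt <- cnt + (signed_dist(sx + ox, sy + oy, sz + oz) < 0)
    coverage[shell] <- cnt / 27
  }
  coverage
}

finish_phantom <- function(coverage, h, intensity, background, kind,
                           truth, params, noise_sd = 0, seed = NULL,
                           channel = "fiber") {
  if (background > intensity)
    stop("background intensity must not exceed the structure intensity")
  img <- background + (intensity - background) * coverage
  if (noise_sd > 0) {
    img <- img + with_seed(seed, array(rnorm(length(img), sd = noise_sd),
                                       dim(img)))
    img[img < 0] <- 0
  }
  mask <- coverage > 0.5
  vol <- volume_image(img, 1 / params$px_per_um, channel = channel)
  params$kind <- kind
  new_phantom(vol, mask, truth, params)
}

check_grid <- function(dims, max_grid_px) {
  if (any(dims > max_grid_px))
    stop(sprintf(paste0("phantom grid %s exceeds max_grid_px = %d; the ",
                        "structure (plus filter padding) does not fit"),
                 paste(dims, collapse = " x "), max_grid_px))
  dims
}

unit3 <- function(v) {
  v <- as.numeric(v)
  n <- sqrt(sum(v^2))
  if (length(v) != 3L || !is.finite(n) || n == 0) stop("axis must be a non-zero 3-vector")
  v / n
}

#' Straight cylinder phantom
#'
#' One straight cylinder of diameter `2 * radius_um` and length
#' `aspect_ratio * 2 * radius_um`, centred in the grid, oriented along
#' `axis`. Ground truth carries the normalized axis for every structure
#' voxel.
#'
#' @param radius_um cylinder radius (um), > 0.
#' @param aspect_ratio length / diameter ratio (default 12).
#' @param px_per_um sampling density (voxels per um).
#' @param axis cylinder axis direction (any non-zero 3-vector).
#' @param intensity,background structure / background gray levels on an
#'   8-bit-like scale (defaults 200 / 10).
#' @param sigma_max_um largest filter scale the phantom is intended for;
#'   sets the boundary padding `ceil(4 * sigma_max_um)` voxels.
#' @param noise_sd optional additive Gaussian noise sigma (gray levels).
#' @param seed RNG seed for the noise.
#' @param max_grid_px sizing guard: error if any grid dimension would
#'   exceed this.
#' @return A `phantom` object.
#' @examples
#' ph <- make_cylinder(2, aspect_ratio = 4, px_per_um = 1, sigma_max_um = 1)
#' ph
#' @export
make_cylinder <- function(radius_um, aspect_ratio = 12, px_per_um = 1,
                          axis = c(0, 0, 1), intensity = 200, background = 10,
                          sigma_max_um = 1.5 * radius_um, noise_sd = 0,
                          seed = NULL, max_grid_px = 2048) {
  stopifnot(radius_um > 0, px_per_um > 0, aspect_ratio > 0)
  a <- unit3(axis)
  h <- 1 / px_per_um
  half_len <- aspect_ratio * radius_um
  pad <- ceiling(4 * sigma_max_um * px_per_um)
  ext <- half_len * abs(a) + radius_um * sqrt(pmax(0, 1 - a^2))
  dims <- check_grid(2 * (ceiling(ext * px_per_um) + pad) + 1, max_grid_px)
  sd_fun <- function(x, y, z) {
    t <- x * a[1] + y * a[2] + z * a[3]
    r2 <- pmax(x^2 + y^2 + z^2 - t^2, 0)
    pmax(sqrt(r2) - radius_um, abs(t) - half_len)
  }
  coverage <- render_solid(dims, h, sd_fun)
  params <- list(radius_um = radius_um, aspect_ratio = aspect_ratio,
                 px_per_um = px_per_um, axis = a, intensity = intensity,
                 background = background, sigma_max_um = sigma_max_um,
                 pad_px = pad)
  finish_phantom(coverage, h, intensity, background, "cylinder",
                 truth = list(list(mask = coverage > 0.5, axis = a)),
                 params = params, noise_sd = noise_sd, seed = seed)
}

#' Solid sphere (blob) phantom
#'
#' @inheritParams make_cylinder
#' @return A `phantom`; blobs carry no orientation ground truth.
#' @export
make_blob <- function(radius_um, px_per_um = 1, intensity = 200,
                      background = 10, sigma_max_um = radius_um / 2,
                      noise_sd = 0, seed = NULL, max_grid_px = 2048) {
  stopifnot(radius_um > 0, px_per_um > 0)
  h <- 1 / px_per_um
  pad <- ceiling(4 * sigma_max_um * px_per_um)
  dims <- check_grid(rep(2 * (ceiling(radius_um * px_per_um) + pad) + 1, 3),
                     max_grid_px)
  coverage <- render_solid(dims, h, function(x, y, z)
    sqrt(x^2 + y^2 + z^2) - radius_um)
  params <- list(radius_um = radius_um, px_per_um = px_per_um,
                 intensity = intensity, background = background,
                 sigma_max_um = sigma_max_um, pad_px = pad)
  finish_phantom(coverage, h, intensity, background, "blob",
                 truth = list(), params = params,
                 noise_sd = noise_sd, seed = seed)
}

#' Solid slab (plate) phantom
#'
#' A slab of thickness `thickness_um`, normal to z, spanning the full lateral
#' (XY) extent of the grid.
#'
#' @inheritParams make_cylinder
#' @param thickness_um slab thickness (um).
#' @param extent_um lateral grid extent (um).
#' @export
make_plate <- function(thickness_um, extent_um = 20, px_per_um = 1,
                       intensity = 200, background = 10,
                       sigma_max_um = thickness_um / 2, noise_sd = 0,
                       seed = NULL, max_grid_px = 2048) {
  stopifnot(thickness_um > 0, px_per_um > 0, extent_um > 0)
  h <- 1 / px_per_um
  pad <- ceiling(4 * sigma_max_um * px_per_um)
  nl <- ceiling(extent_um * px_per_um)
  # even z-extent: the slab midplane falls between voxel centers, so a
  # slab of k voxels thickness covers exactly k voxels
  nz <- 2 * (ceiling(thickness_um / 2 * px_per_um) + pad)
  dims <- check_grid(c(nl, nl, nz), max_grid_px)
  coverage <- render_solid(dims, h, function(x, y, z)
    abs(z) - thickness_um / 2)
  params <- list(thickness_um = thickness_um, extent_um = extent_um,
                 px_per_um = px_per_um, intensity = intensity,
                 background = background, sigma_max_um = sigma_max_um,
                 pad_px = pad)
  finish_phantom(coverage, h, intensity, background, "plate",
                 truth = list(), params = params,
                 noise_sd = noise_sd, seed = seed)
}

#' Crossing-fiber phantom
#'
#' A superposition (voxel-wise maximum) of in-plane cylinders through the
#' volume center, one per azimuth angle. Ground truth retains one axial
#' orientation per cylinder; voxels in the overlap region belong to every
#' crossing structure.
#'
#' @inheritParams make_cylinder
#' @param angles_deg at least two distinct in-plane (azimuth) angles in
#'   degrees; angles equal modulo 180 are rejected.
#' @export
make_crossing <- function(angles_deg, radius_um, aspect_ratio = 12,
                          px_per_um = 1, intensity = 200, background = 10,
                          sigma_max_um = 1.5 * radius_um, noise_sd = 0,
                          seed = NULL, max_grid_px = 2048) {
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) < 2)
    stop("need at least two crossing angles")
  if (anyDuplicated(round(angles_deg %% 180, 8)))
    stop("crossing angles must be distinct (modulo 180 degrees)")
  stopifnot(radius_um > 0, px_per_um > 0)
  h <- 1 / px_per_um
  half_len <- aspect_ratio * radius_um
  pad <- ceiling(4 * sigma_max_um * px_per_um)
  ext <- c(half_len, half_len, radius_um)
  dims <- check_grid(2 * (ceiling(ext * px_per_um) + pad) + 1, max_grid_px)
  coverage <- array(0, dims)
  truth <- list()
  for (ang in angles_deg) {
    a <- c(cos(ang * pi / 180), sin(ang * pi / 180), 0)
    sd_fun <- function(x, y, z) {
      t <- x * a[1] + y * a[2] + z * a[3]
      r2 <- pmax(x^2 + y^2 + z^2 - t^2, 0)
      pmax(sqrt(r2) - radius_um, abs(t) - half_len)
    }
    cov_k <- render_solid(dims, h, sd_fun)
    coverage <- pmax(coverage, cov_k)
    truth[[length(truth) + 1]] <- list(mask = cov_k > 0.5, axis = a,
                                       angle_deg = ang)
  }
  params <- list(angles_deg = angles_deg, radius_um = radius_um,
                 aspect_ratio = aspect_ratio, px_per_um = px_per_um,
                 intensity = intensity, background = background,
                 sigma_max_um = sigma_max_um, pad_px = pad)
  finish_phantom(coverage, h, intensity, background, "crossing",
                 truth = truth, params = params,
                 noise_sd = noise_sd, seed = seed)
}

#' Soma-channel phantom
#'
#' Bright spheres on a dark background emulating lipofuscin-laden neuronal
#' somata in a second imaging channel, used to exercise soma rejection.
#'
#' @inheritParams make_cylinder
#' @param centers_um matrix (k x 3) of sphere centers in um, relative to the
#'   grid origin (voxel 1 center at 0); may have zero rows.
#' @param size_um grid extent (um), scalar or length 3.
#' @export
make_soma_channel <- function(centers_um, radius_um, size_um, px_per_um = 1,
                              intensity = 200, background = 10, noise_sd = 0,
                              seed = NULL, max_grid_px = 2048) {
  centers_um <- matrix(as.numeric(centers_um), ncol = 3)
  stopifnot(radius_um > 0, px_per_um > 0)
  if (length(size_um) == 1) size_um <- rep(size_um, 3)
  h <- 1 / px_per_um
  dims <- check_grid(pmax(ceiling(size_um * px_per_um), 2), max_grid_px)
  if (nrow(centers_um) > 0) {
    lo <- rep(0, 3)
    hi <- (dims - 1) * h
    for (k in seq_len(nrow(centers_um)))
      if (any(centers_um[k, ] < lo) || any(centers_um[k, ] > hi))
        stop("soma center outside the grid")
  }
  # centers are given in origin-based coordinates; shift to the centred frame
  shift <- (dims - 1) * h / 2
  coverage <- array(0, dims)
  if (nrow(centers_um) > 0) {
    for (k in seq_len(nrow(centers_um))) {
      ck <- centers_um[k, ] - shift
      coverage <- pmax(coverage, render_solid(dims, h, function(x, y, z)
        sqrt((x - ck[1])^2 + (y - ck[2])^2 + (z - ck[3])^2) - radius_um))
    }
  }
  params <- list(centers_um = centers_um, radius_um = radius_um,
                 size_um = size_um, px_per_um = px_per_um,
                 intensity = intensity, background = background)
  finish_phantom(coverage, h, intensity, background, "soma",
                 truth = list(), params = params,
                 noise_sd = noise_sd, seed = seed, channel = "soma")
}

#' Multi-fiber stack phantom for the validation protocol
#'
#' A stack-sized volume containing `n_fibers` straight in-plane fibers
#' (infinite cylinders clipped to the box) whose azimuth angles are drawn
#' around a dominant direction, emulating a densely packed, coherently
#' oriented fiber bundle (the defaults give roughly a 10% fiber volume
#' fraction, in the range of white-matter tissue). Fibers are laid at
#' random positions, at constant depth each, with zero elevation, and with
#' calibers drawn from `radius_um`. Azimuths are clamped to `azimuth_range`
#' so the bundle stays roughly perpendicular to the x-axis; the
#' out-of-plane reference-rotation correction used by the validation
#' protocol is exact only for such fibers.
#'
#' @inheritParams make_cylinder
#' @param size_um stack extent (um), scalar or length 3 (x, y, z).
#' @param n_fibers number of fibers.
#' @param mean_azimuth_deg dominant in-plane orientation (degrees).
#' @param azimuth_sd_deg per-fiber normal spread around the dominant
#'   orientation (degrees).
#' @param azimuth_range clamp interval for fiber azimuths (degrees).
#' @param radius_um fiber radius (um); a vector gives the set of calibers
#'   sampled uniformly per fiber.
#' @param z_band fraction interval of the stack depth where fiber axes are
#'   placed (keeps fibers clear of the z borders).
#' @param min_separation_um minimum distance between fiber axes inside the
#'   box (rejection-sampled); keeps fibers resolved so that orientation
#'   estimates at touching structures do not contaminate the ground truth.
#' @param seed RNG seed (fiber placement and noise); generators are
#'   deterministic given identical parameters and seed.
#' @export
make_fiber_stack <- function(size_um = c(160, 160, 100), n_fibers = 110,
                             mean_azimuth_deg = 82, azimuth_sd_deg = 3,
                             azimuth_range = c(72, 89.5),
                             radius_um = c(2, 2.5, 3),
                             px_per_um = 1, intensity = 200, background = 10,
                             z_band = c(0.2, 0.8),
                             min_separation_um = 2 * max(radius_um) + 1,
                             noise_sd = 0, seed = NULL, max_grid_px = 2048) {
  if (length(size_um) == 1) size_um <- rep(size_um, 3)
  stopifnot(all(radius_um > 0), px_per_um > 0, n_fibers >= 1)
  h <- 1 / px_per_um
  dims <- check_grid(pmax(ceiling(size_um * px_per_um), 2), max_grid_px)
  half <- (dims - 1) * h / 2
  draws <- with_seed(seed, {
    az <- pmin(pmax(rnorm(n_fibers, mean_azimuth_deg, azimuth_sd_deg),
                    azimuth_range[1]), azimuth_range[2])
    rad <- radius_um[sample.int(length(radius_um), n_fibers, replace = TRUE)]
    # axis sample points of accepted fibers, for the separation check
    tt <- seq(-1, 1, length.out = 9) * max(half)
    pts <- list()
    ox <- oy <- oz <- numeric(n_fibers)
    for (k in seq_len(n_fibers)) {
      a <- c(cos(az[k] * pi / 180), sin(az[k] * pi / 180), 0)
      for (try in 1:400) {
        cand <- c(runif(1, -half[1], half[1]), runif(1, -half[2], half[2]),
                  runif(1, (z_band[1] - 0.5) * 2 * half[3],
                        (z_band[2] - 0.5) * 2 * half[3]))
        pk <- cbind(cand[1] + tt * a[1], cand[2] + tt * a[2], cand[3])
        sep_ok <- all(vapply(pts, function(q) {
          d2 <- outer(pk[, 1], q[, 1], "-")^2 +
            outer(pk[, 2], q[, 2], "-")^2 +
            outer(pk[, 3], q[, 3], "-")^2
          min(d2) >= min_separation_um^2
        }, logical(1)))
        if (sep_ok || try == 400) {
          ox[k] <- cand[1]; oy[k] <- cand[2]; oz[k] <- cand[3]
          pts[[k]] <- pk
          break
        }
      }
    }
    list(az = az, rad = rad, ox = ox, oy = oy, oz = oz,
         noise = if (noise_sd > 0) rnorm(prod(dims), sd = noise_sd) else NULL)
  })
  coverage <- array(0, dims)
  truth <- list()
  cz <- grid_coords(dims[3], h)
  for (k in seq_len(n_fibers)) {
    a <- c(cos(draws$az[k] * pi / 180), sin(draws$az[k] * pi / 180), 0)
    p0 <- c(draws$ox[k], draws$oy[k], draws$oz[k])
    rk <- draws$rad[k]
    sd_fun <- function(x, y, z) {
      dx <- x - p0[1]; dy <- y - p0[2]; dz <- z - p0[3]
      t <- dx * a[1] + dy * a[2] + dz * a[3]
      sqrt(pmax(dx^2 + dy^2 + dz^2 - t^2, 0)) - rk
    }
    # an in-plane fiber only touches the z-slab within its radius (plus the
    # supersampling shell): rasterize there only
    zi <- which(abs(cz - p0[3]) <= rk + 1.5 * h)
    cov_k <- array(0, dims)
    cov_k[, , zi] <- render_solid(c(dims[1:2], length(zi)), h, function(x, y, z)
      sd_fun(x, y, cz[zi[1]] + (z - grid_coords(length(zi), h)[1])))
    coverage <- pmax(coverage, cov_k)
    # per-fiber truth stored as sparse voxel indices (dense masks for a
    # hundred fibers would dwarf the stack itself)
    truth[[k]] <- list(voxels = which(cov_k > 0.5), axis = a,
                       azimuth_deg = draws$az[k], radius_um = rk)
  }
  img <- background + (intensity - background) * coverage
  if (!is.null(draws$noise)) {
    img <- img + array(draws$noise, dims)
    img[img < 0] <- 0
  }
  params <- list(size_um = size_um, n_fibers = n_fibers,
                 mean_azimuth_deg = mean_azimuth_deg,
                 azimuth_sd_deg = azimuth_sd_deg,
                 azimuth_range = azimuth_range,
                 min_separation_um = min_separation_um, radius_um = radius_um,
                 px_per_um = px_per_um, intensity = intensity,
                 background = background, seed = seed,
                 azimuths_deg = draws$az, radii_um = draws$rad,
                 kind = "fiber_stack")
  new_phantom(volume_image(img, h, channel = "fiber"), coverage > 0.5,
              truth, params)
}

#' Write a phantom to disk (TIFF plus sidecar metadata)
#'
#' The rendered volume goes to a multi-page TIFF; voxel size and generator
#' parameters go to the JSON sidecar.
#'
#' @param phantom a `phantom` object.
#' @param path output TIFF path.
#' @param bits bits per sample for the intensity data.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path, bits = 8) {
  stopifnot(inherits(phantom, "phantom"))
  meta <- phantom$params
  meta$axis <- NULL   # sidecar keeps scalars / plain vectors only
  meta <- lapply(meta, function(x) if (is.matrix(x)) as.vector(t(x)) else x)
  write_volume(phantom$volume, path, bits = bits, metadata = meta)
}
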