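# End-to-end orchestration: optional PSF compensation and isotropization,
# chunked multiscale Frangi filtering, masking, and super-voxel ODF
# estimation, for volumes that may not fit in memory at once.

#' Plan the chunked iteration over a volume
#'
#' Splits the volume into near-cubic cores that tile it exactly (no gaps, no
#' double-writes); each chunk is read with a symmetric margin of
#' `ceil(4 * sigma_max)` voxels (clamped at the volume faces), which covers
#' the Gaussian kernel support at the largest filter scale so chunk cores
#' are seam-exact under global normalization. The core edge is the largest
#' size whose margin-extended chunk fits the memory budget at 4 bytes per
#' voxel.
#'
#' @param shape volume dimensions in voxels (x, y, z).
#' @param voxel_size_um voxel size (um), scalar or length 3.
#' @param chunk_mb memory budget per chunk in MB.
#' @param sigma_max_um largest Frangi scale (um).
#' @return A `chunk_plan`: list with `chunks` (data.frame of 1-based
#'   inclusive core ranges `x0, x1, y0, y1, z0, z1` in iteration order, x
#'   fastest), `margin_vox`, `core_edge` and `n_chunks`.
#' @export
plan_chunks <- function(shape, voxel_size_um, chunk_mb, sigma_max_um) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), chunk_mb > 0,
            sigma_max_um > 0)
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  margin <- as.integer(ceiling(4 * sigma_max_um / min(voxel_size_um)))
  budget_vox <- chunk_mb * 2^20 / 4
  core <- floor(budget_vox^(1 / 3)) - 2 * margin
  if (core < 1)
    stop("chunk_mb too small for the filter margin (",
         margin, " voxels per side)")
  core <- as.integer(min(core, max(shape)))
  splits <- lapply(shape, function(n) {
    k <- ceiling(n / core)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    cbind(start = c(1L, head(ends, -1) + 1L), end = ends)
  })
  grid <- expand.grid(ix = seq_len(nrow(splits[[1]])),
                      iy = seq_len(nrow(splits[[2]])),
                      iz = seq_len(nrow(splits[[3]])))
  chunks <- data.frame(
    x0 = splits[[1]][grid$ix, "start"], x1 = splits[[1]][grid$ix, "end"],
    y0 = splits[[2]][grid$iy, "start"], y1 = splits[[2]][grid$iy, "end"],
    z0 = splits[[3]][grid$iz, "start"], z1 = splits[[3]][grid$iz, "end"])
  structure(list(chunks = chunks, margin_vox = margin,
                 core_edge = core, n_chunks = nrow(chunks), shape = shape),
            class = "chunk_plan")
}

#' Pipeline configuration
#'
#' Collects and validates every knob of the processing pipeline. The
#' defaults reproduce the standard configuration: Frangi sensitivities
#' `alpha = 0.001`, `beta = 1`, per-chunk automatic structureness
#' normalization, Li fiber masking, optional Yen soma rejection, and
#' ODF super-voxels of 10 um.
#'
#' @param input fiber-channel input: a [volume_image()], a `phantom`, or a
#'   TIFF path readable by [read_volume()].
#' @param soma optional soma-channel input (same forms), or `NULL`.
#' @param scales_um ascending Frangi scales (um).
#' @param alpha,beta Frangi sensitivities.
#' @param sv_size_um ODF super-voxel edge (um).
#' @param chunk_mb chunk memory budget (MB).
#' @param psf_fwhm_um PSF FWHM (x, y, z) in um for the anisotropy blur, or
#'   `NULL` to skip.
#' @param blur apply the PSF anisotropy compensation.
#' @param isotropize resample to isotropic `target_um` voxels when needed.
#' @param target_um target isotropic voxel size (um).
#' @param soma_rejection mask somata out of the orientation field.
#' @param global_normalization compute the per-scale structureness
#'   sensitivities and the fiber threshold once over the whole volume
#'   instead of per chunk: seam-free output at the cost of a second pass.
#' @param lmax maximum even spherical harmonic order.
#' @param seed seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @param outdir output directory, or `NULL` for in-memory results only.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input, soma = NULL,
                            scales_um = c(1, 1.25, 1.5),
                            alpha = 0.001, beta = 1, sv_size_um = 10,
                            chunk_mb = 50, psf_fwhm_um = NULL,
                            blur = !is.null(psf_fwhm_um),
                            isotropize = TRUE, target_um = 1,
                            soma_rejection = !is.null(soma),
                            global_normalization = FALSE, lmax = 6,
                            seed = 1, outdir = NULL) {
  stopifnot(length(scales_um) >= 1, all(scales_um > 0),
            !is.unsorted(scales_um), alpha > 0, beta > 0, sv_size_um > 0,
            chunk_mb > 0, target_um > 0, lmax >= 0, lmax %% 2 == 0)
  if (!is.null(psf_fwhm_um)) stopifnot(length(psf_fwhm_um) == 3,
                                       all(psf_fwhm_um > 0))
  if (blur && is.null(psf_fwhm_um))
    stop("blur = TRUE requires psf_fwhm_um")
  structure(list(input = input, soma = soma, scales_um = scales_um,
                 alpha = alpha, beta = beta, sv_size_um = sv_size_um,
                 chunk_mb = chunk_mb, psf_fwhm_um = psf_fwhm_um,
                 blur = blur, isotropize = isotropize,
                 target_um = target_um, soma_rejection = soma_rejection,
                 global_normalization = global_normalization, lmax = lmax,
                 seed = seed, outdir = outdir),
            class = "pipeline_config")
}

resolve_input <- function(x, what = "fiber") {
  if (is.null(x)) return(NULL)
  if (inherits(x, "phantom")) return(x$volume)
  if (is_volume_image(x)) return(x)
  if (is.character(x) && length(x) == 1) return(read_volume(x))
  stop("cannot interpret ", what, " input")
}

preprocess_volume <- function(vol, config) {
  if (config$blur)
    vol <- lateral_blur(vol, anisotropy_sigmas(
      psf_model(config$psf_fwhm_um[1], config$psf_fwhm_um[2],
                config$psf_fwhm_um[3])))
  if (config$isotropize &&
      diff(range(vol$voxel_size_um)) > 1e-9 * max(vol$voxel_size_um))
    vol <- isotropize(vol, config$target_um)
  vol
}

#' Run the full fiber orientation analysis pipeline
#'
#' Stages: (1) optional PSF anisotropy blur and isotropic resampling of the
#' fiber (and soma) channel; (2) chunked multiscale Frangi filtering with
#' orientation extraction -- each chunk is read with its filter margin, so
#' core voxels are unaffected by chunk boundaries; the structureness
#' sensitivity gamma is tailored per chunk and per scale by default, or
#' precomputed globally with `global_normalization` (then chunked and
#' whole-volume runs agree exactly on every core); (3) Li fiber masking
#' (per chunk, or global under `global_normalization`) and optional Yen
#' soma rejection; (4) super-voxel ODF estimation on the stitched
#' orientation field. With an output directory set, the vesselness map
#' (32-bit TIFF), orientation vectors (NIfTI), masks (8-bit TIFF), ODF
#' coefficients (NIfTI + sidecar + K map), a config snapshot, a log and an
#' MD5 manifest are written.
#'
#' @param config a [pipeline_config()].
#' @return List with `v` (vesselness [volume_image()]), `scale_idx`,
#'   `orientations` (`orientation_field`), `masks` (`mask_set`), `odf`
#'   (`odf_field`), `plan` (`chunk_plan`), `gammas` (per-scale values or
#'   matrix per chunk), `fiber_threshold`, `config` and `files` (paths
#'   written, if any).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  vol <- preprocess_volume(resolve_input(config$input), config)
  soma_vol <- resolve_input(config$soma, "soma")
  if (!is.null(soma_vol)) soma_vol <- preprocess_volume(soma_vol, config)
  say("input: %s voxels at %.3g um", paste(dim(vol$data), collapse = "x"),
      vol$voxel_size_um[1])
  d <- dim(vol$data)
  plan <- plan_chunks(d, vol$voxel_size_um, config$chunk_mb,
                      max(config$scales_um))
  say("chunk plan: %d chunk(s), core edge %d, margin %d",
      plan$n_chunks, plan$core_edge, plan$margin_vox)
  m <- plan$margin_vox
  nsc <- length(config$scales_um)
  extract <- function(ch) {
    xr <- max(1, ch$x0 - m):min(d[1], ch$x1 + m)
    yr <- max(1, ch$y0 - m):min(d[2], ch$y1 + m)
    zr <- max(1, ch$z0 - m):min(d[3], ch$z1 + m)
    list(sub = volume_image(vol$data[xr, yr, zr, drop = FALSE],
                            vol$voxel_size_um, vol$channel),
         cx = ch$x0:ch$x1 - xr[1] + 1, cy = ch$y0:ch$y1 - yr[1] + 1,
         cz = ch$z0:ch$z1 - zr[1] + 1)
  }
  gamma_global <- NULL
  if (config$global_normalization) {
    smax <- matrix(0, plan$n_chunks, nsc)
    for (i in seq_len(plan$n_chunks)) {
      ex <- extract(plan$chunks[i, ])
      smax[i, ] <- structureness_max(ex$sub, config$scales_um)
    }
    gamma_global <- vapply(seq_len(nsc), function(k) auto_gamma(smax[, k]),
                           numeric(1))
    say("global gammas: %s", paste(signif(gamma_global, 4), collapse = ", "))
  }
  V <- array(0, d)
  scale_idx <- array(0L, d)
  vx <- array(0, d); vy <- array(0, d); vz <- array(0, d)
  gammas <- matrix(0, plan$n_chunks, nsc)
  for (i in seq_len(plan$n_chunks)) {
    ch <- plan$chunks[i, ]
    ex <- extract(ch)
    res <- multiscale_frangi(ex$sub, config$scales_um, alpha = config$alpha,
                             beta = config$beta, gamma = gamma_global)
    gammas[i, ] <- res$gammas
    xr <- ch$x0:ch$x1; yr <- ch$y0:ch$y1; zr <- ch$z0:ch$z1
    V[xr, yr, zr] <- res$V[ex$cx, ex$cy, ex$cz]
    scale_idx[xr, yr, zr] <- res$scale_idx[ex$cx, ex$cy, ex$cz]
    vx[xr, yr, zr] <- res$vx[ex$cx, ex$cy, ex$cz]
    vy[xr, yr, zr] <- res$vy[ex$cx, ex$cy, ex$cz]
    vz[xr, yr, zr] <- res$vz[ex$cx, ex$cy, ex$cz]
    say("chunk %d/%d done", i, plan$n_chunks)
  }
  result <- structure(list(V = V, scale_idx = scale_idx, vx = vx, vy = vy,
                           vz = vz, scales_um = config$scales_um,
                           gammas = gammas, smax = NULL,
                           voxel_size_um = vol$voxel_size_um,
                           alpha = config$alpha, beta = config$beta),
                      class = "vesselness_result")
  # fiber mask: per chunk by default (streaming behavior), global on demand
  fiber_threshold <- NA_real_
  if (config$global_normalization) {
    fiber_threshold <- suppressWarnings(li_threshold(V))
    fiber <- suppressWarnings(li_fiber_mask(V, threshold = fiber_threshold))
  } else {
    fiber <- array(FALSE, d)
    for (i in seq_len(plan$n_chunks)) {
      ch <- plan$chunks[i, ]
      xr <- ch$x0:ch$x1; yr <- ch$y0:ch$y1; zr <- ch$z0:ch$z1
      fiber[xr, yr, zr] <- suppressWarnings(
        li_fiber_mask(V[xr, yr, zr, drop = FALSE]))
    }
  }
  soma_mask <- NULL
  if (config$soma_rejection && !is.null(soma_vol)) {
    if (!identical(dim(soma_vol$data), d))
      stop("soma channel shape does not match the fiber channel")
    soma_mask <- suppressWarnings(yen_soma_mask(soma_vol))
    say("soma rejection: %d voxel(s) masked", sum(soma_mask))
  }
  masks <- mask_set(fiber, soma_mask)
  orientations <- apply_masks(result, masks)
  say("fiber voxels: %d (%.2f%%)", sum(masks$combined),
      100 * mean(masks$combined))
  odf <- supervoxel_odfs(orientations, config$sv_size_um, lmax = config$lmax)
  say("ODF grid: %s super-voxels of %g um",
      paste(dim(odf$K), collapse = "x"), config$sv_size_um)
  say("total runtime: %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
  files <- NULL
  if (!is.null(config$outdir)) {
    files <- write_pipeline_outputs(config, vol, result, masks, odf,
                                    log_lines)
  }
  list(v = volume_image(V, vol$voxel_size_um, "vesselness"),
       scale_idx = scale_idx, orientations = orientations, masks = masks,
       odf = odf, plan = plan, gammas = gammas,
       fiber_threshold = fiber_threshold, config = config, files = files,
       log = log_lines)
}

write_pipeline_outputs <- function(config, vol, result, masks, odf,
                                   log_lines) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$outdir, f)
  snap <- config
  snap$input <- if (is.character(config$input)) config$input else "<in-memory>"
  snap$soma <- if (is.character(config$soma)) config$soma
  else if (is.null(config$soma)) NULL else "<in-memory>"
  snap$outdir <- NULL
  yaml::write_yaml(unclass(snap), p("config.yaml"))
  write_volume(volume_image(result$V, vol$voxel_size_um), p("vesselness.tif"),
               bits = 32)
  write_volume(volume_image(array(result$scale_idx / max(1, length(
    config$scales_um)), dim(result$scale_idx)), vol$voxel_size_um),
    p("scale_index.tif"), bits = 8,
    metadata = list(n_scales = length(config$scales_um)))
  ov <- array(c(result$vx * masks$combined, result$vy * masks$combined,
                result$vz * masks$combined), c(dim(result$V), 3))
  attr(ov, "pixdim") <- c(vol$voxel_size_um, 1)
  RNifti::writeNifti(RNifti::asNifti(ov, datatype = "double"),
                     p("orientations.nii.gz"), datatype = "double")
  write_volume(volume_image(array(as.numeric(masks$fiber_mask),
                                  dim(masks$fiber_mask)),
                            vol$voxel_size_um), p("fiber_mask.tif"), bits = 8)
  if (!is.null(masks$soma_mask))
    write_volume(volume_image(array(as.numeric(masks$soma_mask),
                                    dim(masks$soma_mask)),
                              vol$voxel_size_um), p("soma_mask.tif"),
                 bits = 8)
  write_odf(odf, p("odf.nii.gz"))
  writeLines(log_lines, p("run.log"))
  written <- list.files(config$outdir, full.names = TRUE)
  written <- written[!grepl("manifest\\.json$", written)]
  hashes <- tools::md5sum(written)
  jsonlite::write_json(as.list(hashes), p("manifest.json"),
                       auto_unbox = TRUE)
  c(written, p("manifest.json"))
}
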