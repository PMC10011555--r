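#' 3D scalar volume image with voxel size metadata
#'
#' A `volume_image` is the basic data container of the package: a 3D numeric
#' array of intensities (dimensions ordered x, y, z) together with the
#' physical voxel size in micrometres along each axis and an optional channel
#' label (e.g. `"fiber"` for the myelinated-fiber autofluorescence channel,
#' `"soma"` for the cell-body channel).
#'
#' @param data 3D numeric array, dimension order (x, y, z).
#' @param voxel_size_um numeric length-3 vector, voxel size in micrometres
#'   along (x, y, z); a scalar is recycled to all axes.
#' @param channel optional character label for the imaging channel.
#' @return An object of class `volume_image`: a list with elements `data`,
#'   `voxel_size_um` and `channel`.
#' @examples
#' v <- volume_image(array(0, c(4, 4, 4)), 1)
#' dim(v$data)
#' @export
volume_image <- function(data, voxel_size_um = 1, channel = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1L) voxel_size_um <- rep(voxel_size_um, 3L)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("`voxel_size_um` must be 1 or 3 positive finite values")
  structure(list(data = data, voxel_size_um = voxel_size_um,
                 channel = channel),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("volume_image: %d x %d x %d voxels, %.3g x %.3g x %.3g um%s\n",
              d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3],
              if (is.null(x$channel)) "" else paste0(", channel: ", x$channel)))
  invisible(x)
}

is_volume_image <- function(x) inherits(x, "volume_image")

stopifnot_isotropic <- function(vol) {
  vs <- vol$voxel_size_um
  if (diff(range(vs)) > 1e-9 * max(vs))
    stop("volume has anisotropic voxels (", paste(signif(vs, 4), collapse = " x "),
         " um); run isotropize() first")
  vs[1]
}

#' Read a multi-page TIFF stack as a volume image
#'
#' Pages are stacked along z. Intensities are returned as numeric values on
#' the stored scale (the `tiff` package maps integer samples to \[0, 1\]; they
#' are rescaled back to the native bit depth). Voxel size is taken from a
#' JSON sidecar file (`<path>.json`, as written by [write_volume()]) when
#' present, else from the `voxel_size_um` argument.
#'
#' @param path TIFF file path.
#' @param voxel_size_um fallback voxel size in micrometres.
#' @param channel optional channel label.
#' @return A [volume_image()].
#' @export
read_volume <- function(path, voxel_size_um = 1, channel = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  bps <- attr(first, "bits.per.sample")
  # 8/16-bit samples are integers mapped to [0, 1] by the reader; 32-bit
  # samples are floating point and come back on their native scale
  scale <- 1
  if (!is.null(bps) && bps %in% c(8, 16)) scale <- 2^bps - 1
  nz <- length(pages)
  nxy <- dim(first)   # rows = y, cols = x in the tiff package
  data <- array(0, c(nxy[2], nxy[1], nz))
  for (z in seq_len(nz)) data[, , z] <- t(pages[[z]]) * scale
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size_um)) voxel_size_um <- meta$voxel_size_um
    if (is.null(channel) && !is.null(meta$channel)) channel <- meta$channel
  }
  volume_image(data, voxel_size_um, channel)
}

#' Write a volume image as a multi-page TIFF plus JSON sidecar
#'
#' Intensities are stored as grayscale pages stacked along z. `bits` selects
#' the sample depth: 8 or 16 for integer data (values are clamped to the bit
#' range), 32 for floating point data in \[0, 1\] (e.g. vesselness maps).
#' Voxel size and channel metadata go to a `<path>.json` sidecar; extra
#' named values can be added through `metadata`.
#'
#' @param vol a [volume_image()].
#' @param path output TIFF path.
#' @param bits bits per sample (8, 16 or 32).
#' @param metadata named list merged into the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, bits = 8, metadata = list()) {
  stopifnot(is_volume_image(vol))
  d <- dim(vol$data)
  scale <- if (bits %in% c(8, 16)) 2^bits - 1 else 1
  pages <- lapply(seq_len(d[3]), function(z) {
    page <- t(vol$data[, , z]) / scale
    page[page < 0] <- 0
    page[page > 1] <- 1
    page
  })
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits),
                  compression = "none")
  meta <- c(list(voxel_size_um = vol$voxel_size_um, channel = vol$channel,
                 dim = d, bits = bits), metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
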