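#' Minimum cross-entropy (Li) threshold
#'
#' Iterative threshold minimizing the cross entropy between the classified
#' foreground and the foreground mean, and the background and the background
#' mean. Operates directly on the floating-point values (no requantization):
#' starting from the sample mean, the threshold is updated as
#' `t <- (mu_fg - mu_bg) / (log(mu_fg) - log(mu_bg))` until convergence,
#' where `mu_bg` and `mu_fg` are the means of the values below and above the
#' current threshold.
#'
#' @param x numeric vector or array of values.
#' @param tol convergence tolerance as a fraction of the data range.
#' @return The threshold, or `NA` (with a warning) for constant input.
#' @export
li_threshold <- function(x, tol = 1e-6) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    warning("constant input: no Li threshold")
    return(NA_real_)
  }
  span <- rng[2] - rng[1]
  # shift to strictly positive support for the logarithms
  d <- span * 1e-6
  y <- x - rng[1] + d
  t <- mean(y)
  for (i in 1:200) {
    lo <- y[y <= t]
    hi <- y[y > t]
    if (!length(lo) || !length(hi)) break
    mb <- mean(lo)
    mf <- mean(hi)
    t_new <- (mf - mb) / (log(mf) - log(mb))
    if (abs(t_new - t) < tol * span) {
      t <- t_new
      break
    }
    t <- t_new
  }
  t + rng[1] - d
}

#' Maximum correlation (Yen) threshold
#'
#' Histogram-based threshold maximizing Yen's criterion
#' `2 log(P (1 - P)) - log(G_bg G_fg)`, where `P` is the cumulative
#' probability below the cut and `G_bg`, `G_fg` are the sums of squared bin
#' probabilities on either side.
#'
#' @param x numeric vector or array of values.
#' @param nbins number of histogram bins.
#' @return The threshold (a bin edge), or `NA` (with a warning) for constant
#'   input.
#' @export
yen_threshold <- function(x, nbins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (!all(is.finite(rng)) || rng[1] == rng[2]) {
    warning("constant input: no Yen threshold")
    return(NA_real_)
  }
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  p <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins) / length(x)
  P1 <- cumsum(p)
  G1 <- cumsum(p^2)
  G2 <- sum(p^2) - G1
  cuts <- seq_len(nbins - 1)
  crit <- rep(-Inf, nbins - 1)
  ok <- P1[cuts] > 0 & P1[cuts] < 1 & G1[cuts] > 0 & G2[cuts] > 0
  crit[ok] <- 2 * log(P1[cuts[ok]] * (1 - P1[cuts[ok]])) -
    log(G1[cuts[ok]] * G2[cuts[ok]])
  breaks[which.max(crit) + 1]
}

#' Fiber mask from a vesselness map (Li threshold)
#'
#' Classifies voxels whose multiscale vesselness exceeds the iteratively
#' found minimum cross-entropy threshold as myelinated-fiber structures.
#'
#' @param v a `vesselness_result`, a [volume_image()], or a numeric array of
#'   vesselness values.
#' @param threshold optional fixed threshold overriding the Li estimate
#'   (e.g. one computed globally over a chunked volume).
#' @return Logical array: `TRUE` for fiber voxels (empty for constant input,
#'   with a warning).
#' @export
li_fiber_mask <- function(v, threshold = NULL) {
  x <- if (inherits(v, "vesselness_result")) v$V
  else if (is_volume_image(v)) v$data
  else v
  t <- if (is.null(threshold)) li_threshold(x) else threshold
  if (is.na(t)) return(array(FALSE, dim(x)))
  x > t
}

#' Soma mask from the second channel (Yen threshold)
#'
#' Segments bright neuronal bodies (e.g. lipofuscin autofluorescence in a
#' red-shifted channel) with Yen's maximum correlation criterion, for
#' optional rejection from the fiber orientation maps.
#'
#' @param soma a [volume_image()] or numeric array of the soma channel, or
#'   `NULL` to skip soma rejection.
#' @param threshold optional fixed threshold overriding the Yen estimate.
#' @return Logical array (`TRUE` inside somata), or `NULL` when `soma` is
#'   `NULL`. Constant input gives an empty mask with a warning.
#' @export
yen_soma_mask <- function(soma, threshold = NULL) {
  if (is.null(soma)) return(NULL)
  x <- if (is_volume_image(soma)) soma$data else soma
  t <- if (is.null(threshold)) yen_threshold(x) else threshold
  if (is.na(t)) return(array(FALSE, dim(x)))
  x > t
}

#' Bundle fiber and soma masks
#'
#' @param fiber_mask logical array from [li_fiber_mask()].
#' @param soma_mask logical array from [yen_soma_mask()], or `NULL` (no soma
#'   rejection; the combined mask then equals the fiber mask).
#' @return A `mask_set`: list with `fiber_mask`, `soma_mask` and
#'   `combined = fiber_mask & !soma_mask`.
#' @export
mask_set <- function(fiber_mask, soma_mask = NULL) {
  stopifnot(is.logical(fiber_mask))
  if (!is.null(soma_mask)) {
    stopifnot(is.logical(soma_mask),
              identical(dim(fiber_mask), dim(soma_mask)))
    combined <- fiber_mask & !soma_mask
  } else {
    combined <- fiber_mask
  }
  structure(list(fiber_mask = fiber_mask, soma_mask = soma_mask,
                 combined = combined), class = "mask_set")
}

#' Restrict orientation vectors to classified fiber voxels
#'
#' Keeps the voxel-wise orientation vectors of a Frangi result only on the
#' combined mask (fiber voxels not rejected as soma); everywhere else the
#' orientation is marked absent.
#'
#' @param orient a `vesselness_result` from [multiscale_frangi()].
#' @param m a `mask_set` (or a logical array used directly as the combined
#'   mask).
#' @return An `orientation_field`: list with arrays `vx, vy, vz` (`NA`
#'   outside the mask), logical `mask`, and `voxel_size_um`.
#' @export
apply_masks <- function(orient, m) {
  stopifnot(inherits(orient, "vesselness_result"))
  combined <- if (inherits(m, "mask_set")) m$combined else m
  stopifnot(is.logical(combined), identical(dim(combined), dim(orient$V)))
  vx <- orient$vx; vy <- orient$vy; vz <- orient$vz
  vx[!combined] <- NA_real_
  vy[!combined] <- NA_real_
  vz[!combined] <- NA_real_
  structure(list(vx = vx, vy = vy, vz = vz, mask = combined,
                 voxel_size_um = orient$voxel_size_um),
            class = "orientation_field")
}
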