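# Independent oracles used across the suite. They deliberately avoid the
# package's own fast paths: dense convolution by explicit summation, brute
# force threshold criteria on coarse histograms, and spherical quadrature.

# Dense 3D correlation with an odd-sized kernel, interior voxels only
# (boundary handling left undefined on purpose). Slow triple loop; use on
# tiny volumes.
dense_conv3 <- function(vol, kernel) {
  d <- dim(vol)
  kd <- dim(kernel)
  h <- (kd - 1) %/% 2
  out <- array(NA_real_, d)
  for (z in (1 + h[3]):(d[3] - h[3]))
    for (y in (1 + h[2]):(d[2] - h[2]))
      for (x in (1 + h[1]):(d[1] - h[1])) {
        block <- vol[(x - h[1]):(x + h[1]), (y - h[2]):(y + h[2]),
                     (z - h[3]):(z + h[3])]
        out[x, y, z] <- sum(block * kernel)
      }
  out
}

# Li's cross-entropy objective for a given threshold (additive g*log(g)
# terms dropped; values shifted positive as in the estimator).
li_cross_entropy <- function(x, t) {
  d <- diff(range(x)) * 1e-6
  y <- x - min(x) + d
  tt <- t - min(x) + d
  b <- y[y <= tt]
  f <- y[y > tt]
  if (!length(b) || !length(f)) return(Inf)
  -sum(b) * log(mean(b)) - sum(f) * log(mean(f))
}

# Li's minimum cross entropy, minimized exhaustively over histogram cuts.
brute_li <- function(x, nbins = 64) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2 - rng[1] +
    diff(rng) * 1e-6
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  best <- Inf
  best_t <- NA
  for (k in 1:(nbins - 1)) {
    wb <- sum(h[1:k]); wf <- sum(h[(k + 1):nbins])
    if (wb == 0 || wf == 0) next
    mb <- sum(h[1:k] * mids[1:k]) / wb
    mf <- sum(h[(k + 1):nbins] * mids[(k + 1):nbins]) / wf
    ce <- -sum(h[1:k] * mids[1:k]) * log(mb) -
      sum(h[(k + 1):nbins] * mids[(k + 1):nbins]) * log(mf)
    if (ce < best) {
      best <- ce
      best_t <- breaks[k + 1]
    }
  }
  best_t
}

# Yen's maximum correlation criterion, maximized exhaustively.
brute_yen <- function(x, nbins = 64) {
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1)
  p <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins) / length(x)
  best <- -Inf
  best_t <- NA
  for (k in 1:(nbins - 1)) {
    P <- sum(p[1:k])
    g1 <- sum(p[1:k]^2)
    g2 <- sum(p[(k + 1):nbins]^2)
    if (P <= 0 || P >= 1 || g1 <= 0 || g2 <= 0) next
    crit <- 2 * log(P * (1 - P)) - log(g1 * g2)
    if (crit > best) {
      best <- crit
      best_t <- breaks[k + 1]
    }
  }
  best_t
}

# Spherical-quadrature SH coefficients of a kernel-density approximation of
# a set of axial orientations: antipodally symmetrized Watson-like kernels
# exp(kappa (u . d)^2), integrated against the basis on a Gauss-Legendre
# (cos theta) x uniform (phi) product grid.
quadrature_sh <- function(dirs, lmax = 6, kappa = 8000, n_theta = 200,
                          n_phi = 400) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  ct <- rep(gl$x, times = n_phi)
  wq <- rep(gl$w, times = n_phi) * (2 * pi / n_phi)
  ph <- rep(phi, each = n_theta)
  st <- sqrt(pmax(0, 1 - ct^2))
  ux <- st * cos(ph); uy <- st * sin(ph); uz <- ct
  f <- 0
  for (k in seq_len(nrow(dirs))) {
    dk <- dirs[k, ] / sqrt(sum(dirs[k, ]^2))
    dot2 <- (ux * dk[1] + uy * dk[2] + uz * dk[3])^2
    fk <- exp(kappa * (dot2 - 1))
    f <- f + fk / sum(fk * wq)
  }
  f <- f / nrow(dirs)
  theta <- acos(pmin(pmax(ct, -1), 1))
  idx <- sh_index_table(lmax)
  vapply(seq_len(nrow(idx)), function(i)
    sum(f * real_sh(idx$l[i], idx$m[i], theta, ph) * wq), numeric(1))
}

# Tiny synthetic orientation_field for histogram-level tests.
toy_orientation_field <- function(v, voxel_size = 1) {
  n <- nrow(v)
  d <- c(n, 1, 1)
  structure(list(vx = array(v[, 1], d), vy = array(v[, 2], d),
                 vz = array(v[, 3], d), mask = array(TRUE, d),
                 voxel_size_um = rep(voxel_size, 3)),
            class = "orientation_field")
}

make_dist <- function(counts, kind = "phi") {
  fiber3d:::new_angular_distribution(counts, kind)
}

delta_dist <- function(angle_deg, kind = "phi", mass = 100) {
  counts <- numeric(180)
  counts[floor(angle_deg + 90) + 1] <- mass
  make_dist(counts, kind)
}
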