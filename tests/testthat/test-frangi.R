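test_that("Hessian of trivial images vanishes", {
  flat <- volume_image(array(5, c(12, 12, 12)), 1)
  h <- scale_space_hessian(flat, 1)
  expect_lt(max(abs(h$hxx)), 1e-10)
  expect_lt(max(abs(h$hxy)), 1e-10)
  ramp <- volume_image(array(rep(seq_len(16), 16 * 16), c(16, 16, 16)), 1)
  hr <- scale_space_hessian(ramp, 1)
  interior <- 6:11
  expect_lt(max(abs(hr$hxx[interior, interior, interior])), 1e-8)
  expect_lt(max(abs(hr$hxz[interior, interior, interior])), 1e-8)
})

test_that("Hessian matches the Gaussian-on-Gaussian closed form", {
  n <- 41; s <- 3; A <- 100
  co <- seq_len(n) - (n + 1) / 2
  x <- array(co, c(n, n, n))
  y <- aperm(x, c(2, 1, 3))
  z <- aperm(x, c(3, 2, 1))
  vol <- volume_image(A * exp(-(x^2 + y^2 + z^2) / (2 * s^2)), 1)
  mid <- (n + 1) / 2
  for (sig in c(1, 2)) {
    h <- scale_space_hessian(vol, sig)
    pred <- -sig^2 * A * (s^2 / (s^2 + sig^2))^(3 / 2) / (s^2 + sig^2)
    expect_equal(h$hxx[mid, mid, mid], pred, tolerance = 2e-3)
    expect_equal(h$hzz[mid, mid, mid], pred, tolerance = 2e-3)
    expect_lt(abs(h$hxy[mid, mid, mid]), 1e-8)
  }
})

test_that("separable Hessian path equals dense convolution with the same kernels", {
  set.seed(11)
  base <- array(rnorm(18^3), c(18, 18, 18))
  vol <- volume_image(fiber3d:::conv_axis(
    fiber3d:::conv_axis(fiber3d:::conv_axis(base,
      fiber3d:::gaussian_kernel(1.2), 0), fiber3d:::gaussian_kernel(1.2), 1),
    fiber3d:::gaussian_kernel(1.2), 2), 1)
  sig <- 1.0
  h <- scale_space_hessian(vol, sig)
  g0 <- fiber3d:::gaussian_kernel(sig, 0)
  g1 <- fiber3d:::gaussian_kernel(sig, 1)
  g2 <- fiber3d:::gaussian_kernel(sig, 2)
  k_xx <- outer(outer(g2, g0), g0)      # kernel(x, y, z) = g2(x) g0(y) g0(z)
  k_xy <- outer(outer(g1, g1), g0)
  k_yz <- outer(outer(g0, g1), g1)
  r <- (length(g0) - 1) / 2
  keep <- (1 + r):(18 - r)
  ref_xx <- dense_conv3(vol$data, k_xx) * sig^2
  ref_xy <- dense_conv3(vol$data, k_xy) * sig^2
  ref_yz <- dense_conv3(vol$data, k_yz) * sig^2
  rel <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(rel(h$hxx[keep, keep, keep], ref_xx[keep, keep, keep]), 1e-6)
  expect_lt(rel(h$hxy[keep, keep, keep], ref_xy[keep, keep, keep]), 1e-6)
  expect_lt(rel(h$hyz[keep, keep, keep], ref_yz[keep, keep, keep]), 1e-6)
})

test_that("eigendecomposition sorts by magnitude and reconstructs H", {
  # diagonal case with the hemisphere sign rule
  h <- list(hxx = array(0, c(1, 1, 1)), hxy = array(0, c(1, 1, 1)),
            hxz = array(0, c(1, 1, 1)), hyy = array(-4, c(1, 1, 1)),
            hyz = array(0, c(1, 1, 1)), hzz = array(-9, c(1, 1, 1)),
            sigma_um = 1, sigma_vox = 1, voxel_size_um = rep(1, 3))
  class(h) <- "hessian_field"
  e <- eigen_decompose(h)
  expect_equal(c(e$l1, e$l2, e$l3), c(0, -4, -9))
  expect_equal(as.vector(e$v1), c(1, 0, 0))
  # random symmetric matrices: |l1| <= |l2| <= |l3|, orthonormal vectors,
  # H v = lambda v, and reconstruction
  set.seed(21)
  n <- 200
  m <- matrix(rnorm(6 * n, sd = 3), n, 6)
  d <- c(n, 1, 1)
  hf <- structure(list(hxx = array(m[, 1], d), hxy = array(m[, 2], d),
                       hxz = array(m[, 3], d), hyy = array(m[, 4], d),
                       hyz = array(m[, 5], d), hzz = array(m[, 6], d),
                       sigma_um = 1, sigma_vox = 1,
                       voxel_size_um = rep(1, 3)), class = "hessian_field")
  e <- eigen_decompose(hf)
  expect_true(all(abs(e$l1) <= abs(e$l2) + 1e-12))
  expect_true(all(abs(e$l2) <= abs(e$l3) + 1e-12))
  for (i in seq_len(n)) {
    H <- matrix(c(m[i, 1], m[i, 2], m[i, 3],
                  m[i, 2], m[i, 4], m[i, 5],
                  m[i, 3], m[i, 5], m[i, 6]), 3, 3)
    V <- cbind(e$v1[i, 1, 1, ], e$v2[i, 1, 1, ], e$v3[i, 1, 1, ])
    lam <- c(e$l1[i], e$l2[i], e$l3[i])
    expect_lt(max(abs(V %*% diag(lam) %*% t(V) - H)), 1e-6 * max(abs(H)))
    expect_equal(crossprod(V), diag(3), tolerance = 1e-8)
    # hemisphere convention
    expect_true(all(V[3, ] >= -1e-15))
  }
  # the fast analytic path agrees with the LAPACK path
  fast <- fiber3d:::cpp_eig3_v1(hf$hxx, hf$hxy, hf$hxz, hf$hyy, hf$hyz,
                                hf$hzz)
  expect_equal(as.vector(fast$l1), as.vector(e$l1), tolerance = 1e-8)
  expect_equal(as.vector(fast$l3), as.vector(e$l3), tolerance = 1e-8)
  dotp <- abs(fast$vx * e$v1[, 1, 1, 1] + fast$vy * e$v1[, 1, 1, 2] +
                fast$vz * e$v1[, 1, 1, 3])
  expect_true(all(dotp > 1 - 1e-8))
})

test_that("cylinder interior shows the tube-like eigenvalue signature", {
  ph <- make_cylinder(2, aspect_ratio = 6, px_per_um = 2, sigma_max_um = 1)
  h <- scale_space_hessian(ph$volume, 1)
  e <- eigen_decompose(h)
  mid <- (dim(ph$volume$data) + 1) %/% 2
  i <- mid[1]; j <- mid[2]; k <- mid[3]
  expect_lt(abs(e$l1[i, j, k]), 0.1 * abs(e$l3[i, j, k]))
  expect_lt(e$l2[i, j, k], 0)
  expect_lt(e$l3[i, j, k], 0)
  expect_equal(e$l2[i, j, k] / e$l3[i, j, k], 1, tolerance = 0.1)
  ang <- acos(min(1, abs(e$v1[i, j, k, 3]))) * 180 / pi
  expect_lt(ang, 2)
})

test_that("geometric features implement the blobness/aspect/structureness rules", {
  mk <- function(l1, l2, l3) {
    d <- c(1, 1, 1)
    list(l1 = array(l1, d), l2 = array(l2, d), l3 = array(l3, d))
  }
  blob <- frangi_features(mk(-5, -5, -5))
  expect_equal(as.vector(blob$RB), 1)
  expect_equal(as.vector(blob$RA), 1)
  expect_equal(as.vector(blob$S), sqrt(75))
  plate <- frangi_features(mk(0, -1e-9, -5))
  expect_lt(as.vector(plate$RA), 1e-8)
  zero <- frangi_features(mk(0, 0, 0))
  expect_equal(as.vector(zero$RB), 0)
  expect_equal(as.vector(zero$RA), 1)
  expect_equal(as.vector(zero$S), 0)
  # features stay in range on random sorted eigenvalues
  set.seed(5)
  for (rep in 1:50) {
    lam <- sort(rnorm(3, sd = 4))
    lam <- lam[order(abs(lam))]
    f <- frangi_features(mk(lam[1], lam[2], lam[3]))
    expect_gte(as.vector(f$RB), 0); expect_lte(as.vector(f$RB), 1 + 1e-12)
    expect_gte(as.vector(f$RA), 0); expect_lte(as.vector(f$RA), 1 + 1e-12)
  }
})

test_that("automatic gamma and the vesselness zero branch behave as specified", {
  expect_equal(auto_gamma(array(c(0, 3, 10), c(3, 1, 1))), 5)
  expect_equal(auto_gamma(array(0, c(2, 2, 2))), 1)
  mkf <- function(l1, l2, l3) {
    f <- frangi_features(list(l1 = array(l1, c(1, 1, 1)),
                              l2 = array(l2, c(1, 1, 1)),
                              l3 = array(l3, c(1, 1, 1))))
    f
  }
  # positive lambda2 or lambda3 forces V = 0 (bright-on-dark polarity)
  expect_equal(as.vector(vesselness(mkf(0, 2, -5), gamma = 1)), 0)
  expect_equal(as.vector(vesselness(mkf(0, -2, 5), gamma = 1)), 0)
  # ideal tube at S = S_max under auto gamma: V = 1 - exp(-2)
  tube <- mkf(0, -5, -5)
  v <- vesselness(tube, alpha = 0.001, beta = 1,
                  gamma = as.vector(tube$S) / 2)
  expect_equal(as.vector(v), 1 - exp(-2), tolerance = 1e-12)
  # blob suppressed by exp(-1/2) relative to the tube term
  blob <- mkf(-5, -5, -5)
  vb <- vesselness(blob, alpha = 0.001, beta = 1,
                   gamma = as.vector(blob$S) / 2)
  expect_equal(as.vector(vb) / as.vector(v), exp(-0.5), tolerance = 1e-9)
  expect_error(vesselness(tube, alpha = -1, gamma = 1), "alpha")
  # constant-zero structureness: V identically zero
  flat <- volume_image(array(1, c(10, 10, 10)), 1)
  res <- multiscale_frangi(flat, 1)
  expect_equal(max(res$V), 0)
  expect_equal(res$gammas, 1)
})

test_that("multiscale projection is a scale-wise maximum with stable ties", {
  ph <- make_cylinder(1.5, aspect_ratio = 4, px_per_um = 2,
                      sigma_max_um = 1.5)
  single <- multiscale_frangi(ph$volume, 1)
  multi1 <- multiscale_frangi(ph$volume, c(1))
  expect_identical(single$V, multi1$V)
  # duplicated scale list behaves like the single scale (first tie wins)
  dup <- multiscale_frangi(ph$volume, c(1, 1))
  expect_identical(dup$V, single$V)
  expect_identical(dup$scale_idx > 0, single$scale_idx > 0)
  expect_true(all(dup$scale_idx %in% c(0L, 1L)))
  multi <- multiscale_frangi(ph$volume, c(0.75, 1.5))
  expect_true(all(multi$V >= multiscale_frangi(ph$volume, 0.75)$V - 1e-12))
  expect_error(multiscale_frangi(ph$volume, numeric(0)), "empty")
  expect_error(multiscale_frangi(ph$volume, c(2, 1)), "ascending")
  # orientation vectors are unit norm wherever V > 0
  w <- multi$V > 0
  nrm <- sqrt(multi$vx[w]^2 + multi$vy[w]^2 + multi$vz[w]^2)
  expect_equal(range(nrm), c(1, 1), tolerance = 1e-9)
})

test_that("anisotropic voxels are rejected with a pointer to isotropize", {
  vol <- volume_image(array(0, c(8, 8, 8)), c(0.5, 0.5, 1))
  expect_error(scale_space_hessian(vol, 1), "isotropize")
})

test_that("peak response is scale-invariant when the scale tracks the radius", {
  peaks <- vapply(c(1.5, 3), function(r) {
    ph <- make_cylinder(r, aspect_ratio = 6, px_per_um = 2,
                        sigma_max_um = r / 2)
    res <- multiscale_frangi(ph$volume, r / 2)
    mid <- (dim(res$V) + 1) %/% 2
    res$V[mid[1], mid[2], mid[3]]
  }, numeric(1))
  expect_equal(peaks[1], peaks[2], tolerance = 0.03)
})

test_that("filter orientations are equivariant under in-plane rotation", {
  ph <- make_cylinder(2, aspect_ratio = 5, px_per_um = 1, axis = c(1, 0, 0),
                      sigma_max_um = 1)
  rot <- rotate_patch(ph$volume, "z", 30)
  get_med_phi <- function(vol, valid = NULL) {
    res <- multiscale_frangi(vol, 1)
    mask <- suppressWarnings(li_fiber_mask(res$V))
    if (!is.null(valid)) mask <- mask & valid
    ang <- vectors_to_angles(cbind(res$vx[mask], res$vy[mask],
                                   res$vz[mask]))
    median(ang$phi_xy)
  }
  m0 <- get_med_phi(ph$volume)
  m30 <- get_med_phi(rot$volume, rot$valid)
  expect_equal(m0, 0, tolerance = 1)
  d <- ((m30 - m0 - 30 + 90) %% 180) - 90
  expect_lt(abs(d), 3)
})

test_that("axial vectors convert to azimuth/elevation with the stated folds", {
  a <- vectors_to_angles(rbind(c(1, 0, 0), c(0, 0, 1), c(1, 1, 0) / sqrt(2)))
  expect_equal(a$phi_xy, c(0, 0, 45))
  expect_equal(a$theta_zy, c(0, 90, 0))
  # axial equivalence: v and -v give identical angles
  set.seed(9)
  v <- matrix(rnorm(300), ncol = 3)
  expect_equal(vectors_to_angles(v), vectors_to_angles(-v))
  # azimuth stays in [-90, 90)
  ang <- vectors_to_angles(v)
  expect_true(all(ang$phi_xy >= -90 & ang$phi_xy < 90))
  expect_true(all(ang$theta_zy >= -90 & ang$theta_zy <= 90))
  expect_error(vectors_to_angles(c(0, 0, 0)), "zero")
})
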