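test_that("real spherical harmonic basis values match analytic anchors", {
  expect_equal(real_sh(0, 0, 0.7, 2.1), 1 / (2 * sqrt(pi)))
  expect_equal(real_sh(2, 0, 0, 0), sqrt(5 / (4 * pi)))
  expect_equal(real_sh(2, 1, 0, 0.4), 0)
  expect_equal(real_sh(2, -1, 0, 0.4), 0)
  expect_error(real_sh(2, 3, 0.5, 0.5), "m")
  # orthonormality on a quadrature grid for a few basis pairs
  gl <- pracma::gaussLegendre(40, -1, 1)
  phi <- (seq_len(80) - 0.5) * 2 * pi / 80
  ct <- rep(gl$x, 80)
  w <- rep(gl$w, 80) * (2 * pi / 80)
  th <- acos(ct)
  ph <- rep(phi, each = 40)
  pairs <- list(c(2, 0), c(2, 2), c(4, -3), c(6, 1))
  for (i in seq_along(pairs)) for (j in seq_along(pairs)) {
    a <- pairs[[i]]; b <- pairs[[j]]
    ip <- sum(real_sh(a[1], a[2], th, ph) * real_sh(b[1], b[2], th, ph) * w)
    expect_equal(ip, as.numeric(i == j), tolerance = 1e-10)
  }
})

test_that("the even-order index table counts 28 coefficients at lmax 6", {
  idx <- sh_index_table(6)
  expect_equal(nrow(idx), 28)
  expect_equal(unique(idx$l), c(0, 2, 4, 6))
  expect_equal(nrow(sh_index_table(0)), 1)
})

test_that("delta-model coefficients are basis means with exact c00", {
  # single orientation along z
  c1 <- sh_coefficients(cbind(0, 0), lmax = 6)
  expect_equal(c1[1], 1 / (2 * sqrt(pi)))
  idx <- sh_index_table(6)
  expect_equal(c1[idx$l == 2 & idx$m == 0], sqrt(5 / (4 * pi)))
  expect_true(all(abs(c1[idx$m != 0]) < 1e-12))
  # c00 is angle-independent for any orientation set
  set.seed(41)
  v <- matrix(rnorm(60), ncol = 3)
  cv <- sh_coefficients(v)
  expect_equal(cv[1], 1 / (2 * sqrt(pi)))
  # axial symmetry: sign flips do not change the coefficients
  flip <- v * sample(c(-1, 1), nrow(v), replace = TRUE)
  expect_equal(sh_coefficients(flip), cv)
  # empty set: zero coefficients flagged with K = 0
  c0 <- sh_coefficients(matrix(0, 0, 3))
  expect_equal(attr(c0, "K"), 0L)
  expect_true(all(c0 == 0))
})

test_that("uniform orientations leave only the l = 0 term", {
  set.seed(42)
  K <- 1000
  v <- matrix(rnorm(3 * K), ncol = 3)
  co <- sh_coefficients(v, lmax = 6)
  idx <- sh_index_table(6)
  expect_true(all(abs(co[idx$l >= 2]) < 3 / sqrt(K)))
})

test_that("analytical coefficients agree with spherical quadrature of a KDE", {
  set.seed(43)
  for (K in c(1, 3, 7)) {
    dirs <- matrix(rnorm(3 * K), ncol = 3)
    ana <- as.numeric(sh_coefficients(dirs, lmax = 6))
    quad <- quadrature_sh(dirs, lmax = 6, kappa = 8000)
    # the kernel width adds a small l-dependent attenuation; 2% of the
    # basis scale is ample at kappa = 8000
    expect_lt(max(abs(ana - quad)), 0.02)
  }
})

test_that("super-voxel ODFs reproduce the geometry of simple phantoms", {
  # single z-aligned cylinder, one super-voxel: lobe maximum within 2 deg of z
  ph <- make_cylinder(2, aspect_ratio = 5, px_per_um = 1, sigma_max_um = 1)
  res <- multiscale_frangi(ph$volume, 1)
  field <- apply_masks(res, li_fiber_mask(res))
  odf <- supervoxel_odfs(field, sv_size_um = max(dim(res$V)) + 1)
  expect_equal(dim(odf$coef), c(1, 1, 1, 28))
  expect_gt(odf$K[1, 1, 1], 0)
  # dense hemisphere grid synthesis
  th <- rep(seq(0, pi / 2, length.out = 91), times = 180)
  phg <- rep(seq(0, pi, length.out = 180), each = 91)
  amp <- sh_synthesize(odf$coef[1, 1, 1, ], th, phg)
  best <- which.max(amp)
  expect_lt(th[best] * 180 / pi, 2)
  # 90-degree crossing: two orthogonal in-plane lobe pairs
  cr <- make_crossing(c(0, 90), radius_um = 2, aspect_ratio = 6,
                      px_per_um = 1, sigma_max_um = 1)
  res2 <- multiscale_frangi(cr$volume, 1)
  f2 <- apply_masks(res2, li_fiber_mask(res2))
  odf2 <- supervoxel_odfs(f2, sv_size_um = max(dim(res2$V)) + 1)
  az <- seq(0, 175, by = 5) * pi / 180
  amp2 <- sh_synthesize(odf2$coef[1, 1, 1, ], rep(pi / 2, length(az)), az)
  expect_gt(amp2[1], max(amp2[5:14]))          # lobe at 0 beats 20..65 deg
  expect_gt(amp2[19], max(amp2[5:14]))         # lobe at 90 too
  expect_gt(amp2[1], 3 * min(amp2))
})

test_that("empty regions yield empty-flagged super-voxels and partials persist", {
  d <- c(25, 25, 25)
  field <- structure(list(vx = array(0, d), vy = array(0, d),
                          vz = array(1, d), mask = array(FALSE, d),
                          voxel_size_um = rep(1, 3)),
                     class = "orientation_field")
  field$mask[1:3, 1:3, 1:3] <- TRUE
  odf <- supervoxel_odfs(field, sv_size_um = 10)
  expect_equal(dim(odf$K), c(3, 3, 3))       # 25 voxels -> 3 partial-edged cells
  expect_equal(odf$K[1, 1, 1], 27L)
  expect_true(all(odf$K[-1] == 0))
  expect_true(all(odf$coef[2, , , ] == 0))
  expect_equal(odf$coef[1, 1, 1, 1], 1 / (2 * sqrt(pi)))
  expect_error(supervoxel_odfs(field, 0.5), "voxel size")
})

test_that("ODF maps round-trip bit-identically through NIfTI", {
  set.seed(44)
  d <- c(12, 12, 6)
  field <- structure(list(vx = array(rnorm(prod(d)), d),
                          vy = array(rnorm(prod(d)), d),
                          vz = array(rnorm(prod(d)), d),
                          mask = array(runif(prod(d)) < 0.4, d),
                          voxel_size_um = rep(1, 3)),
                     class = "orientation_field")
  nrm <- sqrt(field$vx^2 + field$vy^2 + field$vz^2)
  field$vx <- field$vx / nrm; field$vy <- field$vy / nrm
  field$vz <- field$vz / nrm
  odf <- supervoxel_odfs(field, sv_size_um = 4)
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(c(path, paste0(path, ".json"),
                   sub("\\.nii\\.gz$", "_K.tif", path),
                   sub("\\.nii\\.gz$", "_K.tif.json", path))))
  write_odf(odf, path)
  back <- read_odf(path)
  expect_identical(as.numeric(back$coef), as.numeric(odf$coef))
  expect_equal(back$sv_size_um, 4)
  expect_equal(back$lmax, 6)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$n_coefficients, 28)
})
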