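test_that("patch sampling is deterministic, bounded and uniform", {
  set.seed(1)
  stack <- volume_image(array(runif(60^3), c(60, 60, 60)), 1)
  a <- sample_patches(stack, 3, seed = 5, patch_um = c(10, 10, 6),
                      sigma_max_um = 0.5)
  b <- sample_patches(stack, 3, seed = 5, patch_um = c(10, 10, 6),
                      sigma_max_um = 0.5)
  expect_identical(lapply(a, `[[`, "corner"), lapply(b, `[[`, "corner"))
  expect_identical(lapply(a, `[[`, "flips"), lapply(b, `[[`, "flips"))
  expect_identical(a[[2]]$volume$data, b[[2]]$volume$data)
  expect_length(sample_patches(stack, 0, seed = 1,
                               patch_um = c(10, 10, 6),
                               sigma_max_um = 0.5), 0)
  expect_error(sample_patches(stack, 1, seed = 1,
                              patch_um = c(75, 75, 15)), "too small")
  # corner coordinates empirically uniform over the valid range
  many <- sample_patches(stack, 1000, seed = 9, patch_um = c(10, 10, 6),
                         sigma_max_um = 0.5, flip = FALSE)
  corners <- do.call(rbind, lapply(many, `[[`, "corner"))
  for (ax in 1:3) {
    hi <- max(corners[, ax])
    counts <- tabulate(cut(corners[, ax], breaks = seq(0.5, hi + 0.5,
                                                       length.out = 6),
                           labels = FALSE), 5)
    expect_gt(chisq.test(counts)$p.value, 0.01)
  }
})

test_that("patch rotation interpolates accurately and flags fill-in", {
  set.seed(2)
  vol <- volume_image(array(runif(40 * 40 * 20), c(40, 40, 20)), 1)
  sm <- lateral_blur(vol, c(1.5, 1.5))
  # zero rotation is an identity up to interpolation round-off
  r0 <- rotate_patch(sm, "z", 0)
  expect_lt(max(abs(r0$volume$data - sm$data)), 1e-3)
  expect_true(all(r0$valid))
  # +30 then -30 returns the core within interpolation tolerance
  r1 <- rotate_patch(sm, "z", 30)
  r2 <- rotate_patch(r1$volume, "z", -30)
  core <- 15:25
  expect_lt(max(abs(r2$volume$data[core, core, ] - sm$data[core, core, ])),
            5e-3)
  # x-axis rotation works on (y, z) planes; corners are flagged invalid
  rx <- rotate_patch(sm, "x", 45)
  expect_false(all(rx$valid))
  expect_true(all(rx$valid[, 18:22, 9:11]))
  expect_error(rotate_patch(sm, "y", 10))
  expect_error(rotate_patch(sm, "z", 60), "45")
  # the protocol tests 18 nonzero rotations per axis
  expect_length(setdiff(seq(-45, 45, by = 5), 0), 18)
})

test_that("angle histograms bin masked orientations into 180 1-degree bins", {
  field <- toy_orientation_field(matrix(rep(c(1, 0, 0), 50), ncol = 3,
                                        byrow = TRUE))
  h <- angle_histograms(field)
  expect_equal(sum(h$phi$counts), 50)
  expect_equal(h$phi$counts[91], 50)    # bin [0, 1)
  expect_equal(sum(h$theta$counts), 50)
  expect_equal(h$theta$counts[91], 50)
  # empty mask: zero mass
  field$mask[] <- FALSE
  h0 <- angle_histograms(field)
  expect_equal(sum(h0$phi$counts), 0)
  # excluded voxels are left out
  field$mask[] <- TRUE
  excl <- field$mask
  excl[1:25, , ] <- TRUE
  excl[26:50, , ] <- FALSE
  h1 <- angle_histograms(field, exclude = excl)
  expect_equal(sum(h1$phi$counts), 25)
  # uniform axial vectors give a flat azimuth histogram (3 sigma bands)
  set.seed(3)
  v <- matrix(rnorm(3 * 18000), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  hu <- angle_histograms(toy_orientation_field(v))
  expected <- 18000 / 180
  band <- 3 * sqrt(18000 * (1 / 180) * (179 / 180))
  expect_true(all(abs(hu$phi$counts - expected) < band + 1))
})

test_that("reference correction shifts circularly on the axial circle", {
  d <- delta_dist(10.5, "phi")
  expect_equal(correct_reference(d, "z", 0)$counts, d$counts)
  expect_equal(correct_reference(d, "z", 180)$counts, d$counts)
  shifted <- correct_reference(d, "z", 30)
  expect_equal(circular_median(shifted), 40.5)
  # measured distribution after a +30 rotation of a 10-degree bundle
  measured <- delta_dist(40.5, "phi")
  expect_equal(inter_median_distance(shifted, measured), 0)
  # wrap across +90: a bundle at 80 rotated by 30 appears at -70
  d80 <- delta_dist(80.5, "phi")
  s80 <- correct_reference(d80, "z", 30)
  expect_equal(circular_median(s80), -69.5)
  # kind mismatch is refused
  expect_error(correct_reference(d, "x", 10), "elevation|theta")
  th <- delta_dist(0.5, "theta")
  expect_error(correct_reference(th, "z", 10), "phi|azimuth")
})

test_that("circular medians and inter-median distances wrap at 90 degrees", {
  expect_equal(inter_median_distance(delta_dist(10.5), delta_dist(10.5)), 0)
  expect_equal(inter_median_distance(delta_dist(10.5), delta_dist(15.5)), 5)
  expect_equal(inter_median_distance(delta_dist(15.5), delta_dist(10.5)), -5)
  # antipodally close medians: -85 and 85 are 10 degrees apart
  expect_equal(abs(inter_median_distance(delta_dist(-85),
                                         delta_dist(85))), 10)
  # antisymmetry and invariance under joint reference rotation
  set.seed(4)
  for (i in 1:10) {
    p <- make_dist(rmultinom(1, 500, prob = dnorm(1:180, runif(1, 30, 150),
                                                  8))[, 1])
    q <- make_dist(rmultinom(1, 500, prob = dnorm(1:180, runif(1, 30, 150),
                                                  8))[, 1])
    expect_equal(inter_median_distance(p, q),
                 -inter_median_distance(q, p))
    k <- sample(0:179, 1)
    pk <- correct_reference(p, "z", k)
    qk <- correct_reference(q, "z", k)
    expect_equal(inter_median_distance(pk, qk),
                 inter_median_distance(p, q))
  }
  expect_error(circular_median(make_dist(numeric(180))), "zero-mass")
})

test_that("Bhattacharyya coefficient is a bounded symmetric overlap measure", {
  u <- make_dist(rep(1, 180))
  expect_equal(bhattacharyya(u, u), 1)
  half <- make_dist(c(rep(1, 90), rep(0, 90)))
  expect_equal(bhattacharyya(u, half), 1 / sqrt(2))
  disjoint <- make_dist(c(rep(0, 90), rep(1, 90)))
  expect_equal(bhattacharyya(half, disjoint), 0)
  set.seed(6)
  for (i in 1:10) {
    p <- make_dist(rmultinom(1, 300, prob = runif(180))[, 1])
    q <- make_dist(rmultinom(1, 300, prob = runif(180))[, 1])
    b <- bhattacharyya(p, q)
    expect_gte(b, 0)
    expect_lte(b, 1 + 1e-12)
    expect_equal(b, bhattacharyya(q, p))
    # 1 only for identical normalized distributions
    expect_lt(b, 1 - 1e-6)
  }
  expect_error(bhattacharyya(u, make_dist(numeric(180))), "zero-mass")
})

test_that("the validation protocol validates inputs and drops empty patches", {
  expect_error(run_validation(list(), seed = 1), "at least one")
  # an all-background stack yields no retained patches and an empty table
  flat <- volume_image(array(10, c(135, 135, 90)), 1)
  res <- run_validation(flat, seed = 2, n_patches = 1,
                        angles_deg = c(-45, 45))
  expect_equal(res$n_retained, 0)
  expect_equal(res$n_dropped, 1)
  expect_equal(nrow(res$records), 0)
})
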