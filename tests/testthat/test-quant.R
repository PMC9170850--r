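test_that("background activity is the volume-weighted mean over both spheres", {
  u <- uniform_volume(2, dim = c(30L, 30L, 30L))
  bg <- background_activity(u, sphere(c(7, 15, 15), 5),
                            sphere(c(22, 15, 15), 5))
  expect_equal(bg$value, 2)
  expect_equal(bg$total_volume_cm3, sum(bg$volume_cm3))

  # two equal-radius spheres in homogeneous blocks of SUV 1 and 3
  a <- array(1, dim = c(30, 30, 30)); a[16:30, , ] <- 3
  two <- scalar_volume(a, c(1, 1, 1), c(0, 0, 0))
  bg2 <- background_activity(two, sphere(c(7, 15, 15), 5),
                             sphere(c(22, 15, 15), 5))
  expect_equal(bg2$value, 2)
})

test_that("an 8-mm blood-pool sphere on a 1-mm grid has the expected volume", {
  u <- uniform_volume(1.5, dim = c(25L, 25L, 25L), origin = c(-12, -12, -12))
  m <- sphere_mask(u, sphere(c(0, 0, 0), 8))
  vol_cm3 <- sum(m$mask) * voxel_volume_mm3(u) / 1000
  expect_lt(abs(vol_cm3 - 2.145) / 2.145, 0.02)
})

test_that("overlapping blood-pool spheres warn but still compute", {
  u <- uniform_volume(2, dim = c(20L, 20L, 20L))
  expect_warning(
    bg <- background_activity(u, sphere(c(9, 10, 10), 5),
                              sphere(c(11, 10, 10), 5)),
    "overlap")
  expect_equal(bg$value, 2)
})

test_that("threshold_from_sphere returns the in-sphere maximum", {
  u <- uniform_volume(3, dim = c(15L, 15L, 15L))
  expect_equal(threshold_from_sphere(u, sphere(c(7, 7, 7), 4)), 3)
  v <- u; v$data[7, 7, 7] <- 7; v$data[1, 1, 1] <- 50
  expect_equal(threshold_from_sphere(v, sphere(c(7, 7, 7), 4)), 7)
})

test_that("a blurred hotspot's threshold lies between background and peak", {
  u <- uniform_volume(1, dim = c(31L, 31L, 31L))
  u$data[16, 16, 16] <- 10
  b <- blur_volume(u, 4)
  thr <- threshold_from_sphere(b, sphere(c(15, 15, 15), 6))
  expect_lt(thr, 10)
  expect_gt(thr, 1)
  # oracle: direct convolution at the hotspot centre. Image = uniform 1
  # plus a delta of height 9; with zero padding the uniform part loses the
  # one out-of-grid kernel tap per axis end.
  w <- dnorm(-16:16, sd = 4); w <- w / sum(w)
  f <- 1 - 2 * w[1]
  peak_direct <- f^3 + 9 * w[17]^3
  expect_equal(b$data[16, 16, 16], peak_direct, tolerance = 1e-10)
})

test_that("accumulate applies a strict upper threshold with ties retained", {
  v <- scalar_volume(array(c(1, 2, 3, 4, rep(0, 4)), dim = c(2, 2, 2)),
                     c(10, 10, 10))
  m <- array(FALSE, c(2, 2, 2)); m[1:4] <- TRUE
  voi <- voi_mask(m, v)
  acc <- accumulate(v, voi)
  expect_equal(acc$cumulative_suv, 10)
  expect_equal(acc$suv_mean, 2.5)
  expect_equal(acc$suv_max, 4)

  acc3 <- accumulate(v, voi, threshold = 3)
  expect_equal(acc3$cumulative_suv, 6)
  expect_equal(acc3$volume_cm3, 3)
  expect_equal(acc3$suv_mean, 2)
  expect_equal(acc3$suv_max, 3)
  expect_equal(acc3$excluded_voxel_count, 1)

  expect_error(accumulate(v, voi, threshold = 0.5), "entire region")
  empty <- voi_mask(array(FALSE, c(2, 2, 2)), v)
  expect_error(accumulate(v, empty), "empty")
})

test_that("accumulate equals a brute-force voxel loop under a percentile threshold", {
  set.seed(7)
  v <- scalar_volume(array(runif(20^3, 0, 10), dim = c(20, 20, 20)),
                     c(2, 2, 2))
  m <- brute_sphere_mask(v, c(19, 19, 19), 14)
  voi <- voi_mask(m, v)
  thr <- quantile(v$data[m], 0.9)
  acc <- accumulate(v, voi, threshold = thr)

  cum <- 0; nkept <- 0L; mx <- -Inf; excl <- 0L
  for (i in 1:20) for (j in 1:20) for (k in 1:20) {
    if (!m[i, j, k]) next
    x <- v$data[i, j, k]
    if (x > thr) { excl <- excl + 1L; next }
    cum <- cum + x; nkept <- nkept + 1L; mx <- max(mx, x)
  }
  vv <- 8 / 1000
  expect_equal(acc$cumulative_suv, cum * vv)
  expect_equal(acc$volume_cm3, nkept * vv)
  expect_equal(acc$suv_max, mx)
  expect_equal(acc$excluded_voxel_count, excl)
})

test_that("an infinite threshold reproduces the unthresholded result exactly", {
  set.seed(8)
  v <- scalar_volume(array(rnorm(10^3, 5), dim = c(10, 10, 10)), c(1, 1, 1))
  voi <- voi_mask(array(TRUE, c(10, 10, 10)), v)
  expect_identical(accumulate(v, voi, threshold = Inf)[1:4],
                   accumulate(v, voi)[1:4])
})

test_that("AMA ratios follow their defining arithmetic", {
  u <- uniform_volume(4, dim = c(15L, 15L, 15L))
  voi <- voi_mask(brute_sphere_mask(u, c(7, 7, 7), 5), u)
  bg <- list(value = 2)
  class(bg) <- "background_activity"
  r <- ama_region(u, voi, bg)
  expect_equal(r$ama_mean, 2)
  expect_equal(r$ama_max, 2)

  v <- scalar_volume(array(c(2, 2, 8, rep(0, 5)), dim = c(2, 2, 2)),
                     c(10, 10, 10))
  m <- array(FALSE, c(2, 2, 2)); m[1:3] <- TRUE
  r2 <- ama_region(v, voi_mask(m, v), bg, threshold = 4)
  expect_equal(r2$ama_mean, 1)
  # the excluded voxel (8) contributes to neither ratio: the region max is
  # the largest retained value
  expect_equal(r2$ama_max, 1)
  expect_equal(r2$excluded_voxel_count, 1)
  # invariants under thresholding
  expect_lte(r2$suv_max, 4)
  expect_lte(r2$ama_mean, 4 / bg$value)
})

test_that("TBR aggregates slab means unweighted and slab maxes globally", {
  u <- uniform_volume(3, dim = c(21L, 21L, 6L), origin = c(-10, -10, 0))
  slabs <- slice_disk_masks(u, slice_region(1, 6, c(0, 0), 8), 3)
  bg <- structure(list(value = 1.5), class = "background_activity")
  r <- tbr_region(u, slabs, bg)
  expect_equal(r$tbr_mean, 2)
  expect_equal(r$tbr_max, 2)

  # two slabs with means exactly {2, 4} and maxes {5, 6}
  a <- array(2, dim = c(5, 5, 2))
  a[1, 1, 1] <- 5; a[2, 1, 1] <- -1        # slab 1: mean 2, max 5
  a[, , 2] <- 4
  a[1, 1, 2] <- 6; a[2, 1, 2] <- 2         # slab 2: mean 4, max 6
  v <- scalar_volume(a, c(1, 1, 3))
  full <- function(k) {
    m <- array(FALSE, dim = dim(a)); m[, , k] <- TRUE
    voi_mask(m, v)
  }
  bg2 <- structure(list(value = 2), class = "background_activity")
  r2 <- tbr_region(v, list(full(1), full(2)), bg2)
  expect_equal(r2$tbr_mean, 1.5)
  expect_equal(r2$tbr_max, 3)
})

test_that("exclusion masks lower TBR in the presence of spill-over", {
  # intense vertebral uptake so the spill-over field clearly dominates the
  # excluded voxels' genuine content
  ph <- make_phantom(phantom_spec(noise_sd = 0, vertebra_suv = 50))
  spec <- ph$truth$spec
  x0 <- ph$truth$axis_xy[1]; y0 <- ph$truth$axis_xy[2]
  reg <- ph$truth$regions$aneurysm
  sph <- phantom_study_spheres(ph)
  bg <- background_activity(ph$pet, sph$blood[[1]], sph$blood[[2]])
  zs <- ph$pet$origin[3] +
    (seq_len(dim(ph$pet$data)[3]) - 1) * ph$pet$spacing[3]
  kidx <- which(zs >= reg$z_lo & zs <= reg$z_hi)
  prof <- ph$truth$radius_mm
  rr <- approx(prof$z, prof$r, xout = zs[kidx], rule = 2)$y
  sr <- slice_region(min(kidx), max(kidx), c(x0, y0), rr)
  slabs <- slice_disk_masks(ph$pet, sr, 3)
  # exclusion covering the spill-over field: the band of aortic tissue
  # within 8 mm of the vertebral surface
  excl <- array(FALSE, dim = dim(ph$pet$data))
  ys <- ph$pet$origin[2] +
    (seq_len(dim(ph$pet$data)[2]) - 1) * ph$pet$spacing[2]
  yv <- ph$truth$vertebra_axis_y
  excl[, ys > yv - spec$vertebra_radius_mm - 8, ] <- TRUE
  excl <- voi_mask(excl, ph$pet)
  with_ex <- tbr_region(ph$pet, slabs, bg, exclusion = excl)
  without <- tbr_region(ph$pet, slabs, bg)
  expect_lt(with_ex$tbr_mean, without$tbr_mean)
})

test_that("AMA and TBR agree exactly on a uniform unblurred region", {
  ph <- make_phantom(quiet_spec(blood_suv = 4, wall_suv = 4))
  # background measured on a separate uniform blood volume of SUV 2
  bgvol <- uniform_volume(2, dim = c(24L, 24L, 24L))
  bg <- background_activity(bgvol, sphere(c(6, 12, 12), 5),
                            sphere(c(17, 12, 12), 5))
  sel <- ph$centerline$labels == "aneurysm"
  sub <- centerline(ph$centerline$points[sel, ], ph$centerline$radii[sel])
  tm <- tube_mask(ph$pet, sub)
  r_ama <- ama_region(ph$pet, tm, bg)
  zs <- ph$pet$origin[3] +
    (seq_len(dim(ph$pet$data)[3]) - 1) * ph$pet$spacing[3]
  kidx <- which(zs >= min(sub$points[, 3]) & zs <= max(sub$points[, 3]))
  prof <- approx(sub$points[, 3], sub$radii, xout = zs[kidx], rule = 2)$y
  sr <- slice_region(min(kidx), max(kidx),
                     ph$truth$axis_xy, prof)
  r_tbr <- tbr_region(ph$pet, slice_disk_masks(ph$pet, sr, 3), bg)
  expect_equal(r_ama$ama_mean, 2)
  expect_equal(r_tbr$tbr_mean, 2)
  expect_equal(r_ama$ama_mean, r_tbr$tbr_mean)
})

test_that("analyze_study is consistent across radius modes and options", {
  # constant radius: variable and fixed modes must coincide
  ph <- make_phantom(quiet_spec(neck_radius_mm = 8,
                                aneurysm_max_radius_mm = 8))
  sph <- phantom_study_spheres(ph, blood_radius_mm = 4)
  on <- analyze_study(ph$pet, ph$centerline, sph, method = "ama",
                      variable_radius = TRUE)
  off <- analyze_study(ph$pet, ph$centerline, sph, method = "ama",
                       variable_radius = FALSE)
  expect_equal(on$ama_mean, off$ama_mean)

  # aneurysm: fixed-at-max VOI strictly contains the variable VOI
  ph2 <- make_phantom(quiet_spec())
  sph2 <- phantom_study_spheres(ph2, blood_radius_mm = 4)
  v_on <- analyze_study(ph2$pet, ph2$centerline, sph2, method = "ama",
                        variable_radius = TRUE)
  v_off <- analyze_study(ph2$pet, ph2$centerline, sph2, method = "ama",
                         variable_radius = FALSE)
  expect_gt(v_off$volume_cm3[v_off$label == "aneurysm"],
            v_on$volume_cm3[v_on$label == "aneurysm"])

  expect_error(
    analyze_study(ph2$pet, ph2$centerline, list(blood = sph2$blood),
                  method = "ama", threshold = TRUE),
    "missing threshold sphere")
  expect_error(
    analyze_study(ph2$pet, ph2$centerline, sph2, regions = "iliac"),
    "missing region label")
})
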