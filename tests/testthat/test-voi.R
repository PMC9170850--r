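test_that("sphere mask matches the analytic volume and the brute-force loop", {
  vol <- centered_grid(25, 1)
  s <- sphere(c(0, 0, 0), 8)
  m <- sphere_mask(vol, s)
  analytic <- 4 / 3 * pi * 8^3
  expect_lt(abs(sum(m$mask) * 1 - analytic) / analytic, 0.02)
  expect_identical(m$mask, brute_sphere_mask(vol, c(0, 0, 0), 8))
})

test_that("sphere mask boundary conventions are strict center-in", {
  vol <- centered_grid(11, 1)
  expect_equal(sum(sphere_mask(vol, sphere(c(0, 0, 0), 0))$mask), 0)
  # center equidistant from 8 voxel centers, radius below half-diagonal
  expect_equal(sum(sphere_mask(vol, sphere(c(0.5, 0.5, 0.5), 0.4))$mask), 0)
  # voxel centers exactly at the radius are included
  expect_equal(sum(sphere_mask(vol, sphere(c(0, 0, 0), 1))$mask), 7)
})

test_that("spheres outside or clipped by the grid are rejected", {
  vol <- centered_grid(11, 1)
  expect_error(sphere_mask(vol, sphere(c(100, 0, 0), 2)), "outside")
  err <- tryCatch(sphere_mask(vol, sphere(c(5, 0, 0), 4)),
                  error = conditionMessage)
  expect_match(err, "clipped")
  expect_match(err, "%")
})

test_that("tube mask reproduces cylinder and frustum volumes", {
  vol <- scalar_volume(array(0, dim = c(31, 31, 40)), c(1, 1, 1),
                       c(-15, -15, -3.5))
  cyl <- tube_mask(vol, centerline(rbind(c(0, 0, 0), c(0, 0, 30)),
                                   c(10, 10)), fixed_radius = 10)
  v_cyl <- pi * 10^2 * 30
  expect_lt(abs(sum(cyl$mask) - v_cyl) / v_cyl, 0.03)

  cone <- tube_mask(vol, centerline(rbind(c(0, 0, 0), c(0, 0, 30)),
                                    c(5, 10)))
  v_fru <- pi * 30 / 3 * (10^2 + 10 * 5 + 5^2)
  expect_lt(abs(sum(cone$mask) - v_fru) / v_fru, 0.03)
})

test_that("variable radii equal everywhere reproduce the fixed-radius mask", {
  vol <- centered_grid(21, 1)
  pts <- rbind(c(0, 0, -8), c(0, 0, 0), c(0, 0, 8))
  m_var <- tube_mask(vol, centerline(pts, c(6, 6, 6)))
  m_fix <- tube_mask(vol, centerline(pts, c(1, 1, 1)), fixed_radius = 6)
  expect_identical(m_var$mask, m_fix$mask)
})

test_that("tube mask agrees exactly with the brute-force loop, bends included", {
  vol <- centered_grid(17, 1)
  pts <- rbind(c(-5, -4, -6), c(0, 0, 0), c(2, 5, 6))
  radii <- c(3, 5, 4)
  m <- tube_mask(vol, centerline(pts, radii))
  expect_identical(m$mask, brute_tube_mask(vol, pts, radii))
  expect_gt(sum(m$mask), 0)
})

test_that("tube mask is invariant under joint rigid translation", {
  shift <- c(3.2, -1.7, 2.9)
  vol1 <- centered_grid(19, 1)
  vol2 <- scalar_volume(vol1$data, vol1$spacing, vol1$origin + shift)
  # radii/points chosen so no voxel centre sits exactly on the boundary,
  # where float rounding after translation could flip membership
  pts <- rbind(c(0.15, 0.1, -6.2), c(1.1, 2.2, 0.1), c(0.2, -0.1, 6.3))
  m1 <- tube_mask(vol1, centerline(pts, c(4.3, 5.2, 4.1)))
  m2 <- tube_mask(vol2, centerline(sweep(pts, 2, shift, "+"),
                                   c(4.3, 5.2, 4.1)))
  expect_identical(m1$mask, m2$mask)
})

test_that("geometric masks converge to analytic volumes with grid refinement", {
  sph_err <- sapply(c(2, 1, 0.5), function(sp) {
    n <- ceiling(24 / sp); if (n %% 2 == 0) n <- n + 1
    vol <- centered_grid(n, sp)
    v <- sum(sphere_mask(vol, sphere(c(0, 0, 0), 8))$mask) * sp^3
    abs(v - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3)
  })
  expect_true(all(diff(sph_err) < 0))

  cyl_err <- sapply(c(2, 1, 0.5), function(sp) {
    n <- ceiling(32 / sp) + 1; nz <- ceiling(38 / sp)
    vol <- scalar_volume(array(0, dim = c(n, n, nz)), rep(sp, 3),
                         c(-16, -16, -4 + sp / 2))
    m <- tube_mask(vol, centerline(rbind(c(0, 0, 0), c(0, 0, 30)),
                                   c(10, 10)), fixed_radius = 10)
    abs(sum(m$mask) * sp^3 - pi * 3000) / (pi * 3000)
  })
  expect_true(all(diff(cyl_err) < 0))
})

test_that("slice slabs partition the z range as requested", {
  vol <- scalar_volume(array(0, dim = c(25, 25, 10)), c(1, 1, 3),
                       c(-12, -12, 0))
  sr <- slice_region(1, 10, c(0, 0), 8)
  slabs <- slice_disk_masks(vol, sr, 3)
  expect_length(slabs, 10)

  vol1 <- scalar_volume(array(0, dim = c(25, 25, 10)), c(1, 1, 1),
                        c(-12, -12, 0))
  slabs1 <- slice_disk_masks(vol1, slice_region(1, 10, c(0, 0), 8), 3)
  expect_length(slabs1, 4)
  nz <- sapply(slabs1, function(m) length(unique(which(m$mask,
                                                       arr.ind = TRUE)[, 3])))
  expect_equal(nz, c(3, 3, 3, 1))
})

test_that("a single 3-mm disk slab matches the analytic disk volume", {
  vol <- scalar_volume(array(0, dim = c(31, 31, 12)), c(1, 1, 1),
                       c(-15, -15, 0))
  slabs <- slice_disk_masks(vol, slice_region(3, 5, c(0, 0), 10), 3)
  expect_length(slabs, 1)
  v <- pi * 10^2 * 3
  expect_lt(abs(sum(slabs[[1]]$mask) - v) / v, 0.03)
})

test_that("slab thickness below the slice spacing is rejected", {
  vol <- scalar_volume(array(0, dim = c(5, 5, 5)), c(1, 1, 3), c(0, 0, 0))
  expect_error(slice_disk_masks(vol, slice_region(1, 5, c(2, 2), 2), 2),
               "z spacing")
})

test_that("mask subtraction obeys the set identities", {
  vol <- centered_grid(15, 1)
  a <- sphere_mask(vol, sphere(c(0, 0, 0), 5))
  b <- sphere_mask(vol, sphere(c(2, 0, 0), 3))
  empty <- voi_mask(array(FALSE, dim = dim(vol$data)), vol)
  expect_identical(subtract_mask(a, empty)$mask, a$mask)
  expect_equal(sum(subtract_mask(a, a)$mask), 0)
  expect_equal(sum(subtract_mask(a, b)$mask),
               sum(a$mask) - sum(a$mask & b$mask))
  small <- uniform_volume(0, dim = c(3L, 3L, 3L))
  c3 <- voi_mask(array(TRUE, dim = c(3, 3, 3)), small)
  expect_error(subtract_mask(a, c3), "mismatch")
})
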