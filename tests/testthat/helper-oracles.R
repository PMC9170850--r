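# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive per-voxel loops and explicit summation so they
# share no code path with the package implementations they check.

# grid whose voxel centres are symmetric about the physical origin
centered_grid <- function(n, spacing) {
  scalar_volume(array(0, dim = rep(n, 3L)), rep(spacing, 3L),
                rep(-((n - 1) / 2) * spacing, 3L))
}

uniform_volume <- function(value, dim = c(12L, 12L, 12L), spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  scalar_volume(array(value, dim = dim), spacing, origin)
}

# brute-force center-in sphere membership, voxel by voxel
brute_sphere_mask <- function(vol, center, radius) {
  d <- dim(vol$data)
  m <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- vol$origin + (c(i, j, k) - 1) * vol$spacing
    if (sum((p - center)^2) <= radius^2) m[i, j, k] <- TRUE
  }
  m
}

# brute-force tube membership: perpendicular projection onto some segment
# within its span, or the wedge between adjacent segments caught by the
# vertex ball; radius interpolated linearly in arc length at the projected
# position
brute_tube_mask <- function(vol, pts, radii) {
  d <- dim(vol$data)
  n <- nrow(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  m <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    p <- vol$origin + (c(i, j, k) - 1) * vol$spacing
    tq <- numeric(n - 1L)
    for (q in seq_len(n - 1L)) {
      dv <- pts[q + 1L, ] - pts[q, ]
      tq[q] <- sum((p - pts[q, ]) * dv) / sum(dv^2)
    }
    best <- Inf; bs <- NA_real_
    for (q in seq_len(n - 1L)) {
      if (tq[q] < 0 || tq[q] > 1) next
      dv <- pts[q + 1L, ] - pts[q, ]
      d2 <- sum((p - pts[q, ] - tq[q] * dv)^2)
      if (d2 < best) { best <- d2; bs <- s[q] + tq[q] * seg[q] }
    }
    if (n > 2L) for (q in 2:(n - 1L)) {
      if (!(tq[q - 1L] > 1 && tq[q] < 0)) next
      d2 <- sum((p - pts[q, ])^2)
      if (d2 < best) { best <- d2; bs <- s[q] }
    }
    if (is.finite(best)) {
      r <- approx(s, radii, xout = bs, rule = 2)$y
      if (best <= r^2) m[i, j, k] <- TRUE
    }
  }
  m
}

# explicit-summation two-way ANOVA mean squares and ICC(C,1)
brute_icc <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  g <- mean(mat)
  ss_rows <- 0
  for (i in seq_len(n)) ss_rows <- ss_rows + k * (mean(mat[i, ]) - g)^2
  ss_cols <- 0
  for (j in seq_len(k)) ss_cols <- ss_cols + n * (mean(mat[, j]) - g)^2
  ss_tot <- 0
  for (i in seq_len(n)) for (j in seq_len(k))
    ss_tot <- ss_tot + (mat[i, j] - g)^2
  ms_rows <- ss_rows / (n - 1)
  ms_err <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

# explicit-summation Bland-Altman bias and limits
brute_bland_altman <- function(a, b) {
  n <- length(a)
  d <- numeric(n)
  for (i in seq_len(n)) d[i] <- b[i] - a[i]
  bias <- sum(d) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - bias)^2
  s <- sqrt(ss / (n - 1))
  c(bias = bias, lo = bias - 1.96 * s, hi = bias + 1.96 * s)
}

brute_cr <- function(a, b) {
  n <- length(a)
  d <- b - a
  m <- sum(d) / n
  ss <- 0
  for (i in seq_len(n)) ss <- ss + (d[i] - m)^2
  1.96 * sqrt(ss / (n - 1))
}

# small unblurred noiseless phantom spec for fast exact checks; overrides
# win over the helper's defaults
quiet_spec <- function(...) {
  args <- list(shape = c(48L, 44L, 70L), spacing = c(2, 2, 2),
               psf_sigma_mm = 0, noise_sd = 0,
               neck_radius_mm = 8, aneurysm_max_radius_mm = 14,
               aneurysm_center_z_mm = 45, aneurysm_extent_mm = 35,
               vertebra_offset_mm = 28, vertebra_radius_mm = 9,
               blood_pool_offset_mm = 30, blood_pool_radius_mm = 10,
               region_length_mm = 24)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_spec, args)
}
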