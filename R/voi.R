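# Geometry -> mask conversion. Voxel inclusion is strictly center-in-geometry:
# a voxel belongs to a mask iff its centre satisfies the geometric predicate.
# No partial-volume weighting anywhere; this keeps every mask reproducible
# and checkable against a brute-force loop over voxel centres.

# index window on one axis covering [lo, hi] in physical mm
axis_window <- function(vol, axis, lo, hi) {
  ax <- voxel_axis(vol, axis)
  idx <- which(ax >= lo - vol$spacing[axis] & ax <= hi + vol$spacing[axis])
  if (length(idx) == 0L) integer(0) else seq(min(idx), max(idx))
}

#' Spherical volume of interest
#'
#' Selects every voxel whose centre lies within `s$radius` mm of `s$center`
#' (Euclidean distance, boundary inclusive). Used for the atrial blood-pool
#' spheres and the per-region threshold spheres, which are always placed
#' fully inside the scanned volume; a sphere poking outside the grid is an
#' error, not a silent clip.
#'
#' @param vol a [scalar_volume()].
#' @param s a [sphere()].
#' @return a [voi_mask()].
#' @export
sphere_mask <- function(vol, s) {
  b <- grid_bounds(vol)
  if (any(s$center < b$lo) || any(s$center > b$hi)) {
    stop("sphere center (", paste(signif(s$center, 6), collapse = ", "),
         ") lies outside the volume grid")
  }
  if (s$radius > 0 &&
      (any(s$center - s$radius < b$lo) || any(s$center + s$radius > b$hi))) {
    frac <- clipped_sphere_fraction(s, b)
    stop(sprintf(
      "sphere extends outside the volume grid (%.1f%% of its volume clipped)",
      100 * frac))
  }
  m <- array(FALSE, dim = dim(vol$data))
  if (s$radius > 0) {
    iw <- axis_window(vol, 1, s$center[1] - s$radius, s$center[1] + s$radius)
    jw <- axis_window(vol, 2, s$center[2] - s$radius, s$center[2] + s$radius)
    kw <- axis_window(vol, 3, s$center[3] - s$radius, s$center[3] + s$radius)
    if (length(iw) && length(jw) && length(kw)) {
      dx2 <- (voxel_axis(vol, 1)[iw] - s$center[1])^2
      dy2 <- (voxel_axis(vol, 2)[jw] - s$center[2])^2
      dz2 <- (voxel_axis(vol, 3)[kw] - s$center[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      m[iw, jw, kw] <- d2 <= s$radius^2
    }
  }
  voi_mask(m, vol, provenance = sprintf(
    "sphere r=%g mm at (%g, %g, %g)", s$radius,
    s$center[1], s$center[2], s$center[3]))
}

# fraction of sphere volume outside the grid box, by uniform sampling
clipped_sphere_fraction <- function(s, b) {
  step <- s$radius / 12
  g <- seq(-s$radius, s$radius, by = step)
  pts <- as.matrix(expand.grid(g, g, g))
  inside_sphere <- rowSums(pts^2) <= s$radius^2
  pts <- sweep(pts[inside_sphere, , drop = FALSE], 2L, s$center, "+")
  out <- pts[, 1] < b$lo[1] | pts[, 1] > b$hi[1] |
         pts[, 2] < b$lo[2] | pts[, 2] > b$hi[2] |
         pts[, 3] < b$lo[3] | pts[, 3] > b$hi[3]
  mean(out)
}

#' Tubular volume of interest along a centerline
#'
#' Sweeps a tube along the centerline polyline. A voxel is selected iff its
#' centre projects perpendicularly onto some segment at a distance no
#' greater than the local radius, or sits in the wedge between two adjacent
#' segments within the vertex's ball (which fills the outside of a bend).
#' The tube has flat ends: voxels beyond the first or last point are never
#' selected, so a straight two-point centerline yields an exact right
#' cylinder.
#'
#' With `fixed_radius` set, the same radius applies everywhere (the uniform
#' 3-D cylinder mode). Otherwise the per-point radii are interpolated
#' linearly in arc length, evaluated at the arc-length position of the
#' voxel's nearest point on the polyline — the variable-radius mode that
#' tracks the changing aneurysm diameter.
#'
#' @param vol a [scalar_volume()].
#' @param line a [centerline()].
#' @param fixed_radius single radius in mm, or `NULL` to use the per-point
#'   annotated radii.
#' @return a [voi_mask()].
#' @export
tube_mask <- function(vol, line, fixed_radius = NULL) {
  pts <- line$points
  n <- nrow(pts)
  if (n < 2L) stop("degenerate centerline: need at least 2 points")
  radii <- if (is.null(fixed_radius)) line$radii else rep(fixed_radius, n)
  if (any(radii <= 0)) stop("tube radius must be strictly positive")
  rmax <- max(radii)
  s <- arc_length(pts)

  iw <- axis_window(vol, 1, min(pts[, 1]) - rmax, max(pts[, 1]) + rmax)
  jw <- axis_window(vol, 2, min(pts[, 2]) - rmax, max(pts[, 2]) + rmax)
  kw <- axis_window(vol, 3, min(pts[, 3]) - rmax, max(pts[, 3]) + rmax)
  m <- array(FALSE, dim = dim(vol$data))
  if (!length(iw) || !length(jw) || !length(kw))
    return(voi_mask(m, vol, "tube (outside grid)"))

  xs <- voxel_axis(vol, 1)[iw]
  ys <- voxel_axis(vol, 2)[jw]
  zs <- voxel_axis(vol, 3)[kw]
  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  X <- rep(xs, times = ny * nz)
  Y <- rep(rep(ys, each = nx), times = nz)
  Z <- rep(zs, each = nx * ny)

  best_d2 <- rep(Inf, nx * ny * nz)
  best_s <- rep(NA_real_, nx * ny * nz)

  t_prev <- NULL
  for (i in seq_len(n - 1L)) {
    p1 <- pts[i, ]; p2 <- pts[i + 1L, ]
    d <- p2 - p1
    L2 <- sum(d^2)
    t <- ((X - p1[1]) * d[1] + (Y - p1[2]) * d[2] + (Z - p1[3]) * d[3]) / L2
    elig <- t >= 0 & t <= 1
    if (any(elig)) {
      px <- p1[1] + t * d[1]; py <- p1[2] + t * d[2]; pz <- p1[3] + t * d[3]
      d2 <- (X - px)^2 + (Y - py)^2 + (Z - pz)^2
      upd <- elig & d2 < best_d2
      best_d2[upd] <- d2[upd]
      best_s[upd] <- s[i] + t[upd] * sqrt(L2)
    }
    # wedge at the interior vertex between segments i-1 and i: voxels whose
    # projection falls past the previous segment but before this one belong
    # to the vertex ball (never past the terminal flat ends)
    if (i > 1L) {
      wedge <- t_prev > 1 & t < 0
      if (any(wedge)) {
        d2v <- (X - p1[1])^2 + (Y - p1[2])^2 + (Z - p1[3])^2
        upd <- wedge & d2v < best_d2
        best_d2[upd] <- d2v[upd]
        best_s[upd] <- s[i]
      }
    }
    t_prev <- t
  }

  rloc <- stats::approx(s, radii, xout = best_s, rule = 2)$y
  sel <- is.finite(best_d2) & !is.na(rloc) & best_d2 <= rloc^2
  sel[is.na(sel)] <- FALSE
  m[iw, jw, kw] <- array(sel, dim = c(nx, ny, nz))
  mode <- if (is.null(fixed_radius)) "variable radius"
          else sprintf("fixed radius %g mm", fixed_radius)
  voi_mask(m, vol, provenance = sprintf(
    "tube along %d-point centerline, %s, length %.1f mm", n, mode, s[n]))
}

#' Trans-axial slice region
#'
#' Describes a stack of in-plane circular regions of interest around the
#' aorta: an inclusive z-index range on the parent grid plus, per slice in
#' that range, a disk centre (x, y in mm) and radius (mm). This is the
#' substrate of the slice-wise TBR measurement, where circular ROIs are
#' drawn around the aorta on consecutive trans-axial planes.
#'
#' @param z_start,z_end inclusive 1-based slice indices, `z_start <= z_end`.
#' @param centers numeric matrix (nslice x 2) of per-slice disk centres in
#'   mm, or a single length-2 point recycled to every slice.
#' @param radii per-slice disk radii in mm (recycled if length 1), > 0.
#' @return an object of class `slice_region`.
#' @export
slice_region <- function(z_start, z_end, centers, radii) {
  z_start <- as.integer(z_start); z_end <- as.integer(z_end)
  if (z_start > z_end) stop("z_start must be <= z_end")
  ns <- z_end - z_start + 1L
  centers <- matrix(as.numeric(centers), ncol = 2L)
  if (nrow(centers) == 1L) centers <- centers[rep(1L, ns), , drop = FALSE]
  if (nrow(centers) != ns) stop("need one disk center per slice")
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, ns)
  if (length(radii) != ns) stop("need one disk radius per slice")
  if (any(radii <= 0)) stop("disk radii must be strictly positive")
  structure(list(z_start = z_start, z_end = z_end,
                 centers = centers, radii = radii),
            class = "slice_region")
}

#' Slab-wise disk masks in the trans-axial plane
#'
#' Partitions the slice range of a [slice_region()] into consecutive slabs
#' of the requested thickness (the last slab may be thinner) and returns one
#' mask per slab, in cranio-caudal order. Within a slab each voxel is tested
#' against the disk of its own slice, so the ROI follows the vessel centre
#' slice by slice. The default 3 mm slab reproduces ROIs of 3 mm thickness
#' tiled along the region.
#'
#' @param vol a [scalar_volume()].
#' @param region a [slice_region()].
#' @param slab_thickness_mm slab thickness in mm; must be at least the z
#'   spacing of the grid.
#' @return list of [voi_mask()], one per slab.
#' @export
slice_disk_masks <- function(vol, region, slab_thickness_mm = 3) {
  zsp <- vol$spacing[3]
  if (slab_thickness_mm < zsp - 1e-9)
    stop("slab thickness (", slab_thickness_mm,
         " mm) must be at least the z spacing (", zsp, " mm)")
  nzv <- dim(vol$data)[3]
  if (region$z_start < 1L || region$z_end > nzv)
    stop("slice region exceeds the volume's z extent")
  idx <- region$z_start:region$z_end
  per <- max(1L, as.integer(floor(slab_thickness_mm / zsp + 1e-9)))
  groups <- split(idx, (seq_along(idx) - 1L) %/% per)

  xs <- voxel_axis(vol, 1); ys <- voxel_axis(vol, 2)
  lapply(seq_along(groups), function(g) {
    m <- array(FALSE, dim = dim(vol$data))
    for (k in groups[[g]]) {
      sl <- k - region$z_start + 1L
      cx <- region$centers[sl, 1]; cy <- region$centers[sl, 2]
      r2 <- region$radii[sl]^2
      m[, , k] <- outer((xs - cx)^2, (ys - cy)^2, "+") <= r2
    }
    voi_mask(m, vol, provenance = sprintf(
      "disk slab %d/%d (slices %d-%d)", g, length(groups),
      min(groups[[g]]), max(groups[[g]])))
  })
}

#' Subtract one mask from another
#'
#' `a AND NOT b`: removes from `a` every voxel selected by `b`. This is how
#' regions of vertebral spill-over are explicitly excluded from a
#' measurement mask.
#'
#' @param a,b [voi_mask()] objects on congruent grids.
#' @return a [voi_mask()].
#' @export
subtract_mask <- function(a, b) {
  if (!identical(dim(a$mask), dim(b$mask)))
    stop("mask shape mismatch: ", paste(dim(a$mask), collapse = "x"),
         " vs ", paste(dim(b$mask), collapse = "x"))
  structure(list(mask = a$mask & !b$mask, spacing = a$spacing,
                 provenance = paste0(a$provenance, " minus [",
                                     b$provenance, "]")),
            class = "voi_mask")
}

# restrict a mask to slices whose z centre lies in [zlo, zhi] (mm)
clip_mask_z <- function(m, vol, zlo, zhi) {
  zs <- voxel_axis(vol, 3)
  keep <- zs >= zlo - 1e-9 & zs <= zhi + 1e-9
  mm <- m$mask
  mm[, , !keep] <- FALSE
  structure(list(mask = mm, spacing = m$spacing,
                 provenance = paste0(m$provenance,
                                     sprintf(", clipped to z in [%.1f, %.1f]",
                                             zlo, zhi))),
            class = "voi_mask")
}
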