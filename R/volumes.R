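#' Scalar image volume
#'
#' A 3-D voxel grid of scalar intensities (SUV for PET, Hounsfield units for
#' CT) together with its physical geometry. Physical coordinates are in
#' millimetres; axis order is (x, y, z) with z the cranio-caudal axis along
#' which trans-axial slices are taken. Voxel `(i, j, k)` (1-based R indices)
#' has its centre at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data numeric 3-D array of voxel intensities; must be finite.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm,
#'   strictly positive.
#' @param origin numeric length-3 physical position (mm) of the centre of
#'   voxel (1, 1, 1).
#' @return an object of class `scalar_volume` with fields `data`, `spacing`,
#'   `origin`.
#' @export
scalar_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  nbad <- sum(!is.finite(data))
  if (nbad > 0)
    stop("volume contains ", nbad, " non-finite voxel(s)")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = " x "),
      " mm, origin (", paste(x$origin, collapse = ", "), ") mm\n", sep = "")
  cat("  intensity range [", min(x$data), ", ", max(x$data), "]\n", sep = "")
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param vol a [scalar_volume()].
#' @return product of the three spacings (mm^3).
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing)

#' Physical centres of voxels
#'
#' Maps 1-based voxel indices to physical millimetre coordinates:
#' `origin + (ijk - 1) * spacing`.
#'
#' @param vol a [scalar_volume()].
#' @param ijk integer matrix (n x 3) of 1-based voxel indices, or `NULL` for
#'   every voxel in array order.
#' @return numeric matrix (n x 3) of physical points in mm.
#' @export
voxel_centers <- function(vol, ijk = NULL) {
  if (is.null(ijk)) {
    ijk <- as.matrix(expand.grid(
      seq_len(dim(vol$data)[1]), seq_len(dim(vol$data)[2]),
      seq_len(dim(vol$data)[3])))
    dimnames(ijk) <- NULL
  }
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(sweep(ijk - 1, 2L, vol$spacing, "*"), 2L, vol$origin, "+")
}

# physical coordinates of voxel centres along one axis
voxel_axis <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

# physical bounding box of the grid, voxel-edge convention
grid_bounds <- function(vol) {
  d <- dim(vol$data)
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (d - 1) * vol$spacing + vol$spacing / 2
  list(lo = lo, hi = hi)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3-D NIfTI-1 image into a [scalar_volume()]. Only axis-aligned
#' geometries are supported: the voxel-to-world affine must be diagonal with
#' positive scales. Oblique or flipped affines are rejected rather than
#' silently resampled.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  img <- RNifti::readNifti(path, internal = FALSE)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3-D image, got ", length(d), "-D image in ", path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(diag(rot)))))
    stop("oblique affine in ", path, ": only axis-aligned volumes are supported")
  if (any(diag(rot) <= 0))
    stop("flipped or degenerate affine in ", path,
         ": axis scales must be positive")
  data <- array(as.numeric(img), dim = d)
  nbad <- sum(!is.finite(data))
  if (nbad > 0)
    stop("volume ", path, " contains ", nbad, " non-finite voxel(s)")
  scalar_volume(data, spacing = diag(rot), origin = aff[1:3, 4])
}

#' Write a NIfTI-1 volume
#'
#' Writes a [scalar_volume()] as NIfTI-1 with the spacing and origin encoded
#' in the qform/sform affine. Data are stored as 32-bit float by default
#' (lossless for float32-representable values); pass `datatype = "double"`
#' for full double precision.
#'
#' @param vol a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, `"float"` or `"double"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, datatype = "float") {
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  a <- vol$data
  attr(a, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(a, datatype = datatype)
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::`qform<-`(img, value = structure(aff, code = 2L)) -> img
  RNifti::`sform<-`(img, value = structure(aff, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Aortic centerline
#'
#' An ordered polyline through the vessel lumen, in physical millimetres,
#' with a radius annotated at every point (the maximal luminal radius at
#' that level) and an optional region label per point. Labels must form
#' contiguous runs along the ordering, mirroring how the aorta is divided
#' into consecutive segments (thoracic, suprarenal, neck, aneurysm).
#'
#' @param points numeric matrix (n x 3) of ordered physical points (mm).
#' @param radii numeric vector of per-point radii (mm), strictly positive.
#' @param labels optional character vector of per-point region tags.
#' @return an object of class `centerline`.
#' @export
centerline <- function(points, radii, labels = NULL) {
  points <- matrix(as.numeric(points), ncol = 3L)
  radii <- as.numeric(radii)
  n <- nrow(points)
  if (n < 2L) stop("a centerline needs at least 2 points")
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (length(radii) != n) stop("radii length must match number of points")
  if (any(!is.finite(points)) || any(!is.finite(radii)))
    stop("centerline points and radii must be finite")
  if (any(radii <= 0)) stop("centerline radii must be strictly positive")
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-n, , drop = FALSE])^2))
  if (any(seg == 0)) stop("consecutive centerline points must be distinct")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) stop("labels length must match number of points")
    runs <- rle(labels)$values
    if (anyDuplicated(runs))
      stop("region labels must form contiguous runs along the centerline")
  }
  structure(list(points = points, radii = radii, labels = labels),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat("<centerline> ", nrow(x$points), " points, radii ",
      signif(min(x$radii), 4), "-", signif(max(x$radii), 4), " mm", sep = "")
  if (!is.null(x$labels))
    cat(", regions: ", paste(rle(x$labels)$values, collapse = " > "), sep = "")
  cat("\n")
  invisible(x)
}

# cumulative arc length from the first point
arc_length <- function(points) {
  n <- nrow(points)
  c(0, cumsum(sqrt(rowSums((points[-1, , drop = FALSE] -
                            points[-n, , drop = FALSE])^2))))
}

#' Sphere geometry
#' @param center numeric length-3 physical centre (mm).
#' @param radius radius in mm, non-negative.
#' @return an object of class `sphere`.
#' @export
sphere <- function(center, radius) {
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("sphere center must be 3 finite coordinates (mm)")
  radius <- as.numeric(radius)
  if (length(radius) != 1L || !is.finite(radius) || radius < 0)
    stop("sphere radius must be a single non-negative number (mm)")
  structure(list(center = center, radius = radius), class = "sphere")
}

#' Write / read centerline JSON
#'
#' The on-disk format is a JSON object with fields `points` (n x 3 array),
#' `radii` and optional `labels`.
#'
#' @param line a [centerline()].
#' @param path file path.
#' @return `read_centerline` returns a [centerline()]; `write_centerline`
#'   returns `path` invisibly.
#' @export
write_centerline <- function(line, path) {
  obj <- list(points = unname(line$points), radii = line$radii)
  if (!is.null(line$labels)) obj$labels <- line$labels
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_centerline
#' @export
read_centerline <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centerline(points = obj$points, radii = obj$radii, labels = obj$labels)
}

#' Write / read sphere JSON
#'
#' Format: `{"center": [x, y, z], "radius_mm": r}`.
#'
#' @param s a [sphere()].
#' @param path file path.
#' @export
write_sphere <- function(s, path) {
  jsonlite::write_json(list(center = s$center, radius_mm = s$radius),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_sphere
#' @export
read_sphere <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sphere(center = obj$center, radius = obj$radius_mm)
}

#' Volume-of-interest mask
#'
#' A boolean voxel selection congruent with a specific [scalar_volume()]
#' grid. All geometry operations produce `voi_mask` objects and all uptake
#' accumulation consumes them.
#'
#' @param mask logical array with the same dimensions as `vol$data`.
#' @param vol the parent [scalar_volume()].
#' @param provenance free-text description of the generating geometry.
#' @return an object of class `voi_mask` with fields `mask`, `spacing`,
#'   `provenance`.
#' @export
voi_mask <- function(mask, vol, provenance = "") {
  if (!identical(dim(mask), dim(vol$data)))
    stop("mask shape (", paste(dim(mask), collapse = "x"),
         ") does not match volume grid (",
         paste(dim(vol$data), collapse = "x"), ")")
  storage.mode(mask) <- "logical"
  structure(list(mask = mask, spacing = vol$spacing,
                 provenance = provenance),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask> ", sum(x$mask), " voxels selected (",
      signif(sum(x$mask) * prod(x$spacing) / 1000, 4), " cm^3)  ",
      x$provenance, "\n", sep = "")
  invisible(x)
}

#' Export a mask as a NIfTI byte volume for visual inspection
#' @param m a [voi_mask()].
#' @param vol the parent [scalar_volume()] (for geometry).
#' @param path output path.
#' @export
write_mask <- function(m, vol, path) {
  mv <- scalar_volume(array(as.numeric(m$mask), dim = dim(m$mask)),
                      spacing = vol$spacing, origin = vol$origin)
  write_volume(mv, path, datatype = "float")
}
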