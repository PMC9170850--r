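# Measurement core: blood-pool background, thresholded accumulation, TBR
# and AMA per aortic region.
#
# Units: voxel intensities are SUV (dimensionless); "cumulative SUV" is the
# voxel-volume-weighted sum in SUV*cm^3, so cumulative / volume is the mean
# voxel SUV. This makes AMA_mean = (cumulative / volume) / background a
# dimensionless ratio on the same scale as TBR_mean, and the two coincide
# exactly on a uniform region.

#' Blood-pool background activity
#'
#' Estimates the mean circulating blood SUV from two spheres placed in the
#' blood pool (in patients, 8-mm-radius spheres in the centres of the right
#' and left atria). Each sphere's cumulative SUV (SUV x cm^3) is summed and
#' corrected for the spheres' total volume, i.e. the result is the
#' volume-weighted mean voxel SUV across both spheres combined. The value is
#' the denominator of every TBR and AMA ratio.
#'
#' @param pet a [scalar_volume()] in SUV units.
#' @param s1,s2 [sphere()] objects fully interior to the grid.
#' @return an object of class `background_activity` with fields `value`
#'   (mean SUV), `cumulative_suv` and `volume_cm3` (per sphere), and
#'   `total_volume_cm3`.
#' @export
background_activity <- function(pet, s1, s2) {
  m1 <- sphere_mask(pet, s1)
  m2 <- sphere_mask(pet, s2)
  if (sum(m1$mask) == 0L || sum(m2$mask) == 0L)
    stop("blood-pool sphere selects no voxels")
  note <- character(0)
  if (any(m1$mask & m2$mask)) {
    note <- "blood-pool spheres overlap"
    warning("blood-pool spheres overlap; overlapping voxels are counted twice")
  }
  vv <- voxel_volume_mm3(pet) / 1000  # cm^3
  cum <- c(sum(pet$data[m1$mask]) * vv, sum(pet$data[m2$mask]) * vv)
  vol <- c(sum(m1$mask) * vv, sum(m2$mask) * vv)
  structure(list(value = sum(cum) / sum(vol),
                 cumulative_suv = cum, volume_cm3 = vol,
                 total_volume_cm3 = sum(vol), notes = note),
            class = "background_activity")
}

#' @export
print.background_activity <- function(x, ...) {
  cat(sprintf(
    "<background_activity> mean blood-pool SUV %.4g (total volume %.3g cm^3)\n",
    x$value, x$total_volume_cm3))
  invisible(x)
}

#' Upper-intensity threshold from a reference sphere
#'
#' Returns the maximum voxel SUV inside the sphere. In the spill-over
#' correction workflow the sphere is drawn over the visually highest aortic
#' uptake clearly distinct from the vertebra; its SUV_max is then applied as
#' an upper voxel intensity threshold for that region's VOI, so that voxels
#' dominated by vertebral spill-over (which exceed any genuine aortic
#' signal) are excluded.
#'
#' @param pet a [scalar_volume()] in SUV units.
#' @param s a [sphere()].
#' @return the maximum SUV within the sphere (single number).
#' @export
threshold_from_sphere <- function(pet, s) {
  m <- sphere_mask(pet, s)
  if (sum(m$mask) == 0L) stop("threshold sphere selects no voxels")
  max(pet$data[m$mask])
}

#' Accumulate uptake over a volume of interest
#'
#' Sums voxel SUV over a mask, optionally applying an upper intensity
#' threshold: voxels with SUV strictly greater than `threshold` are excluded
#' from the cumulative SUV, the volume, the mean and the max (ties at the
#' threshold are retained, so the defining sphere's own maximum never
#' invalidates its region).
#'
#' @param pet a [scalar_volume()] in SUV units.
#' @param voi a [voi_mask()].
#' @param threshold upper SUV limit, or `NULL` for no thresholding.
#' @return list with `cumulative_suv` (SUV x cm^3), `volume_cm3`,
#'   `suv_mean`, `suv_max`, `excluded_voxel_count`, `n_voxels`.
#' @export
accumulate <- function(pet, voi, threshold = NULL) {
  if (!identical(dim(voi$mask), dim(pet$data)))
    stop("VOI mask is not congruent with the PET grid")
  vals <- pet$data[voi$mask]
  if (length(vals) == 0L) stop("VOI is empty")
  excluded <- 0L
  if (!is.null(threshold)) {
    keep <- vals <= threshold
    excluded <- sum(!keep)
    if (!any(keep)) stop("threshold removes entire region")
    vals <- vals[keep]
  }
  vv <- voxel_volume_mm3(pet) / 1000
  volume <- length(vals) * vv
  cumulative <- sum(vals) * vv
  list(cumulative_suv = cumulative, volume_cm3 = volume,
       suv_mean = cumulative / volume, suv_max = max(vals),
       excluded_voxel_count = excluded, n_voxels = length(vals))
}

new_region_result <- function(label, method, acc, bg, threshold = NULL,
                              tbr_mean = NA_real_, tbr_max = NA_real_,
                              ama_mean = NA_real_, ama_max = NA_real_,
                              extra = list()) {
  structure(c(list(
    label = label, method = method,
    cumulative_suv = acc$cumulative_suv, volume_cm3 = acc$volume_cm3,
    suv_mean = acc$suv_mean, suv_max = acc$suv_max,
    threshold = if (is.null(threshold)) NA_real_ else threshold,
    excluded_voxel_count = acc$excluded_voxel_count,
    background = bg$value,
    tbr_mean = tbr_mean, tbr_max = tbr_max,
    ama_mean = ama_mean, ama_max = ama_max), extra),
    class = "region_result")
}

#' @export
print.region_result <- function(x, ...) {
  cat(sprintf("<region_result> %s [%s]: volume %.3g cm^3, SUVmean %.4g, SUVmax %.4g\n",
              x$label, x$method, x$volume_cm3, x$suv_mean, x$suv_max))
  if (x$method == "ama")
    cat(sprintf("  AMA_mean %.4g, AMA_max %.4g (background %.4g%s)\n",
                x$ama_mean, x$ama_max, x$background,
                if (is.na(x$threshold)) "" else
                  sprintf(", threshold %.4g, %d voxels excluded",
                          x$threshold, x$excluded_voxel_count)))
  else
    cat(sprintf("  TBR_mean %.4g, TBR_max %.4g (background %.4g)\n",
                x$tbr_mean, x$tbr_max, x$background))
  invisible(x)
}

#' @export
as.data.frame.region_result <- function(x, ...) {
  data.frame(label = x$label, method = x$method,
             cumulative_suv = x$cumulative_suv, volume_cm3 = x$volume_cm3,
             suv_mean = x$suv_mean, suv_max = x$suv_max,
             threshold = x$threshold,
             excluded_voxel_count = x$excluded_voxel_count,
             background = x$background,
             tbr_mean = x$tbr_mean, tbr_max = x$tbr_max,
             ama_mean = x$ama_mean, ama_max = x$ama_max,
             stringsAsFactors = FALSE)
}

#' Aortic microcalcification activity of one region
#'
#' The cumulative SUV of the region's VOI is divided by the VOI volume and
#' by the mean background blood-pool activity to give AMA_mean; AMA_max is
#' the region's SUV_max divided by the background. If a threshold is given
#' it is applied as in [accumulate()] before either ratio is formed.
#'
#' @param pet a [scalar_volume()] in SUV units.
#' @param voi a [voi_mask()] (typically from [tube_mask()]).
#' @param bg a [background_activity()].
#' @param threshold optional upper SUV limit.
#' @param label region name for reporting.
#' @return a `region_result`.
#' @export
ama_region <- function(pet, voi, bg, threshold = NULL, label = "region") {
  if (!is.finite(bg$value) || bg$value <= 0)
    stop("background activity must be positive")
  acc <- accumulate(pet, voi, threshold)
  new_region_result(label, "ama", acc, bg, threshold,
                    ama_mean = acc$suv_mean / bg$value,
                    ama_max = acc$suv_max / bg$value)
}

#' Tissue-to-background ratio of one region
#'
#' Computes per-slab SUV_mean and SUV_max on each trans-axial slab mask
#' (minus an optional exclusion mask covering e.g. vertebral spill-over),
#' then aggregates: the region's TBR_mean is the unweighted mean of the
#' per-slab SUV_means divided by the background, and TBR_max is the maximum
#' per-slab SUV_max divided by the background. Slabs emptied by the
#' exclusion are dropped and counted.
#'
#' @param pet a [scalar_volume()] in SUV units.
#' @param slabs list of [voi_mask()] from [slice_disk_masks()].
#' @param bg a [background_activity()].
#' @param exclusion optional [voi_mask()] subtracted from every slab.
#' @param label region name for reporting.
#' @return a `region_result` with `n_slabs` and `n_slabs_dropped` fields.
#' @export
tbr_region <- function(pet, slabs, bg, exclusion = NULL, label = "region") {
  if (!is.finite(bg$value) || bg$value <= 0)
    stop("background activity must be positive")
  if (length(slabs) == 0L) stop("no slabs supplied")
  vv <- voxel_volume_mm3(pet) / 1000
  means <- maxes <- numeric(0)
  dropped <- 0L
  excluded_total <- 0L
  total_n <- 0L
  cum <- 0
  for (sl in slabs) {
    m <- if (is.null(exclusion)) sl else subtract_mask(sl, exclusion)
    excluded_total <- excluded_total + (sum(sl$mask) - sum(m$mask))
    vals <- pet$data[m$mask]
    if (length(vals) == 0L) { dropped <- dropped + 1L; next }
    means <- c(means, mean(vals))
    maxes <- c(maxes, max(vals))
    total_n <- total_n + length(vals)
    cum <- cum + sum(vals) * vv
  }
  if (length(means) == 0L) stop("all slabs empty after exclusion")
  acc <- list(cumulative_suv = cum, volume_cm3 = total_n * vv,
              suv_mean = mean(means), suv_max = max(maxes),
              excluded_voxel_count = excluded_total, n_voxels = total_n)
  new_region_result(label, "tbr", acc, bg, NULL,
                    tbr_mean = mean(means) / bg$value,
                    tbr_max = max(maxes) / bg$value,
                    extra = list(n_slabs = length(slabs),
                                 n_slabs_dropped = dropped))
}

#' Analyse a full study
#'
#' Orchestrates the whole measurement for one scan: background estimation
#' from the two blood-pool spheres, per-region VOI construction, optional
#' per-region threshold estimation, and accumulation, for each requested
#' method.
#'
#' For the AMA method each labeled centerline segment is swept into a tube
#' ([tube_mask()]), clipped to the region's z extent so consecutive regions
#' do not overlap. With `variable_radius = FALSE` the tube uses a fixed
#' radius equal to the region's maximum annotated radius (the uniform
#' cylinder that inevitably captures extra-aortic tissue where the vessel
#' narrows); with `variable_radius = TRUE` the per-point radii are used.
#'
#' For the TBR method the region is measured as a stack of trans-axial disk
#' ROIs of `slab_thickness_mm` thickness ([slice_disk_masks()]), the disk
#' centre and radius interpolated from the centerline at each slice; this
#' requires the centerline z coordinates to be strictly monotone over each
#' region. Optional per-region exclusion spheres remove vertebral
#' spill-over from the TBR masks.
#'
#' @param pet a [scalar_volume()] in SUV units.
#' @param centerline a labeled [centerline()].
#' @param spheres list with `blood` (list of two [sphere()]), optionally
#'   `threshold` (named list, one [sphere()] per region) and `exclusion`
#'   (named list of [sphere()] or lists of spheres per region).
#' @param method `"ama"`, `"tbr"`, or both.
#' @param threshold logical: apply the per-region upper-intensity threshold
#'   (AMA only)?
#' @param variable_radius logical: use per-point radii for the AMA tube?
#' @param slab_thickness_mm TBR slab thickness (mm).
#' @param regions region labels to measure; defaults to all labels on the
#'   centerline in order of appearance.
#' @param ct optional co-registered CT [scalar_volume()]; carried for
#'   provenance only, not used in any computation.
#' @return a data.frame with one row per region x method, with attributes
#'   `background` ([background_activity()]), `thresholds` (named list), and
#'   `options`.
#' @export
analyze_study <- function(pet, centerline, spheres,
                          method = c("ama", "tbr"),
                          threshold = FALSE, variable_radius = TRUE,
                          slab_thickness_mm = 3, regions = NULL,
                          ct = NULL) {
  method <- match.arg(method, c("ama", "tbr"), several.ok = TRUE)
  if (is.null(centerline$labels))
    stop("centerline has no region labels")
  if (is.null(regions)) regions <- rle(centerline$labels)$values
  missing_r <- setdiff(regions, unique(centerline$labels))
  if (length(missing_r))
    stop("missing region label(s) on centerline: ",
         paste(missing_r, collapse = ", "))
  if (length(spheres$blood) != 2L)
    stop("need exactly two blood-pool spheres")
  bg <- background_activity(pet, spheres$blood[[1]], spheres$blood[[2]])

  thresholds <- list()
  rows <- list()
  for (reg in regions) {
    sel <- which(centerline$labels == reg)
    if (length(sel) < 2L)
      stop("region '", reg, "' has fewer than 2 centerline points")
    pts <- centerline$points[sel, , drop = FALSE]
    radii <- centerline$radii[sel]
    sub <- centerline(pts, radii)
    zlo <- min(pts[, 3]); zhi <- max(pts[, 3])

    thr <- NULL
    if (threshold && "ama" %in% method) {
      if (is.null(spheres$threshold[[reg]]))
        stop("missing threshold sphere for region '", reg, "'")
      thr <- threshold_from_sphere(pet, spheres$threshold[[reg]])
      thresholds[[reg]] <- thr
    }

    if ("ama" %in% method) {
      tm <- if (variable_radius) tube_mask(pet, sub)
            else tube_mask(pet, sub, fixed_radius = max(radii))
      tm <- clip_mask_z(tm, pet, zlo, zhi)
      rows[[length(rows) + 1L]] <-
        ama_region(pet, tm, bg, threshold = thr, label = reg)
    }

    if ("tbr" %in% method) {
      zmono <- diff(pts[, 3])
      if (any(zmono <= 0) && any(zmono >= 0) &&
          !(all(zmono > 0) || all(zmono < 0)))
        stop("TBR slice ROIs require z-monotone centerline in region '",
             reg, "'")
      zs <- voxel_axis(pet, 3)
      kidx <- which(zs >= zlo - 1e-9 & zs <= zhi + 1e-9)
      if (length(kidx) == 0L) stop("region '", reg, "' covers no slices")
      ord <- order(pts[, 3])
      cx <- stats::approx(pts[ord, 3], pts[ord, 1], xout = zs[kidx],
                          rule = 2)$y
      cy <- stats::approx(pts[ord, 3], pts[ord, 2], xout = zs[kidx],
                          rule = 2)$y
      rr <- stats::approx(pts[ord, 3], radii[ord], xout = zs[kidx],
                          rule = 2)$y
      sr <- slice_region(min(kidx), max(kidx), cbind(cx, cy), rr)
      slabs <- slice_disk_masks(pet, sr, slab_thickness_mm)
      excl <- NULL
      if (!is.null(spheres$exclusion[[reg]])) {
        es <- spheres$exclusion[[reg]]
        if (inherits(es, "sphere")) es <- list(es)
        em <- sphere_mask(pet, es[[1]])
        if (length(es) > 1L) for (e in es[-1]) {
          em2 <- sphere_mask(pet, e)
          em$mask <- em$mask | em2$mask
        }
        excl <- em
      }
      rows[[length(rows) + 1L]] <-
        tbr_region(pet, slabs, bg, exclusion = excl, label = reg)
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  attr(df, "background") <- bg
  attr(df, "thresholds") <- thresholds
  attr(df, "options") <- list(threshold = threshold,
                              variable_radius = variable_radius,
                              slab_thickness_mm = slab_thickness_mm)
  df
}
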