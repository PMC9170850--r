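# Digital phantom: an abdominal aorta of varying diameter with a blood-pool
# lumen, a hotter wall/thrombus shell, and an adjacent high-uptake vertebral
# column, blurred by an isotropic Gaussian point-spread function so that
# vertebral activity spills over into the aneurysm exactly as it does in
# patient scans. Ground truth is recorded from the pre-blur image.

#' Phantom specification
#'
#' Defaults describe a desk-scale but anatomically plausible abdominal
#' aortic aneurysm study: a 128 x 128 x 200 mm field of view at 2 mm
#' isotropic PET resolution; blood-pool SUV 1 and wall/thrombus SUV 2
#' (typical sodium-fluoride TBR around 2); vertebral SUV 10 (intense
#' physiological bone uptake, five times the wall); a 10 mm aortic neck
#' radius bulging to 20 mm over a 50 mm (FWHM) aneurysm; the vertebral
#' column nearly abutting the aneurysm, as the aorta lies directly on the
#' spine; and a 4 mm Gaussian point-spread sigma, in the range of clinical
#' PET reconstructions.
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing numeric length-3 voxel spacing (mm).
#' @param blood_suv true blood-pool SUV (lumen).
#' @param wall_suv true aortic wall / thrombus SUV.
#' @param vertebra_suv true vertebral SUV.
#' @param neck_radius_mm aortic radius away from the aneurysm (mm).
#' @param aneurysm_max_radius_mm peak aneurysm radius (mm); must be >=
#'   `neck_radius_mm`.
#' @param aneurysm_center_z_mm z position of the bulge peak (mm).
#' @param aneurysm_extent_mm full width at half maximum of the bulge (mm).
#' @param wall_thickness_mm thickness of the wall shell (mm).
#' @param vertebra_offset_mm distance from the aortic axis to the vertebral
#'   column axis (mm).
#' @param vertebra_radius_mm radius of the vertebral column (mm).
#' @param blood_pool_offset_mm distance from the aortic axis (along -x) to
#'   the axis of the blood-pool cylinder that stands in for the cardiac
#'   blood pool; the background spheres are placed inside it, away from any
#'   structure whose uptake varies with the pathology under study.
#' @param blood_pool_radius_mm radius of the blood-pool cylinder (mm); must
#'   accommodate the 8-mm background spheres.
#' @param region_length_mm length of each of the thoracic, suprarenal and
#'   neck segments (mm); the aneurysm takes the remaining caudal extent.
#' @param psf_sigma_mm standard deviation of the isotropic Gaussian
#'   point-spread function (mm); 0 disables blurring.
#' @param noise_sd standard deviation of additive Gaussian voxel noise (SUV),
#'   applied after blurring; 0 disables noise.
#' @param seed integer random seed for the noise.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 100L), spacing = c(2, 2, 2),
                         blood_suv = 1, wall_suv = 2, vertebra_suv = 10,
                         neck_radius_mm = 10, aneurysm_max_radius_mm = 20,
                         aneurysm_center_z_mm = 60, aneurysm_extent_mm = 50,
                         wall_thickness_mm = 3,
                         vertebra_offset_mm = 35, vertebra_radius_mm = 12,
                         blood_pool_offset_mm = 41,
                         blood_pool_radius_mm = 14,
                         region_length_mm = 30,
                         psf_sigma_mm = 4, noise_sd = 0.05, seed = 1L) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               blood_suv = blood_suv, wall_suv = wall_suv,
               vertebra_suv = vertebra_suv,
               neck_radius_mm = neck_radius_mm,
               aneurysm_max_radius_mm = aneurysm_max_radius_mm,
               aneurysm_center_z_mm = aneurysm_center_z_mm,
               aneurysm_extent_mm = aneurysm_extent_mm,
               wall_thickness_mm = wall_thickness_mm,
               vertebra_offset_mm = vertebra_offset_mm,
               vertebra_radius_mm = vertebra_radius_mm,
               blood_pool_offset_mm = blood_pool_offset_mm,
               blood_pool_radius_mm = blood_pool_radius_mm,
               region_length_mm = region_length_mm,
               psf_sigma_mm = psf_sigma_mm, noise_sd = noise_sd,
               seed = as.integer(seed))
  suvs <- c(spec$blood_suv, spec$wall_suv, spec$vertebra_suv)
  if (any(!is.finite(suvs)) || any(suvs < 0))
    stop("SUV levels must be non-negative")
  if (spec$aneurysm_max_radius_mm < spec$neck_radius_mm)
    stop("aneurysm_max_radius_mm must be >= neck_radius_mm")
  if (spec$psf_sigma_mm < 0) stop("psf_sigma_mm must be >= 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  class(spec) <- "phantom_spec"
  spec
}

# Gaussian bulge radius profile r(z); extent is a FWHM, converted to a
# standard deviation via the usual factor 2.355
radius_profile <- function(spec, z) {
  sig <- spec$aneurysm_extent_mm / 2.355
  spec$neck_radius_mm +
    (spec$aneurysm_max_radius_mm - spec$neck_radius_mm) *
      exp(-(z - spec$aneurysm_center_z_mm)^2 / (2 * sig^2))
}

#' Isotropic Gaussian blur of a volume
#'
#' Separable convolution with a sampled, sum-normalised 1-D Gaussian kernel
#' (truncated at 4 sigma) along each axis; boundaries are zero-padded, so
#' total image sum is conserved up to truncation at the grid edge. This is
#' the point-spread model that produces partial-volume dilution and
#' spill-over in the phantom.
#'
#' @param vol a [scalar_volume()].
#' @param sigma_mm Gaussian standard deviation in mm; 0 returns the input.
#' @return a blurred [scalar_volume()].
#' @export
blur_volume <- function(vol, sigma_mm) {
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(vol)
  a <- vol$data
  for (axis in 1:3) {
    sp <- vol$spacing[axis]
    m <- max(1L, ceiling(4 * sigma_mm / sp))
    k <- stats::dnorm((-m:m) * sp, sd = sigma_mm)
    k <- k / sum(k)
    n <- dim(a)[axis]
    K <- matrix(0, n, n)
    for (off in -m:m) {
      d <- row(K) - col(K) == off
      K[d] <- k[off + m + 1L]
    }
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    ap <- K %*% matrix(ap, nrow = dp[1])
    dim(ap) <- dp
    a <- aperm(ap, order(perm))
  }
  scalar_volume(a, vol$spacing, vol$origin)
}

#' Generate a co-registered PET/CT phantom with ground truth
#'
#' Builds a straight vertical aortic centerline whose radius follows the
#' Gaussian bulge profile of the spec, paints the lumen at `blood_suv`, an
#' annular wall shell at `wall_suv` and a parallel vertebral cylinder at
#' `vertebra_suv` on a zero background, records ground truth from this
#' pre-blur image, then convolves the PET volume with the point-spread
#' Gaussian and adds voxel noise (deterministic given `seed`). The CT
#' volume encodes the same geometry with Hounsfield-like values and is
#' carried for landmarking only.
#'
#' The centerline is labeled caudally to cranially as aneurysm, neck,
#' suprarenal, thoracic; ground truth holds the per-region pre-blur
#' SUV_mean/SUV_max, the spill-free reference mean (the same aorta blurred
#' with the vertebra removed — the value an ideal spill-over correction
#' would recover), the true blood SUV, the radius profile, the region z
#' bounds and the true aortic voxel mask.
#'
#' @param spec a [phantom_spec()].
#' @return list with `pet`, `ct` ([scalar_volume()]), `centerline`
#'   ([centerline()]), and `truth` (list).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape; sp <- spec$spacing
  vol0 <- scalar_volume(array(0, dim = d), sp, c(0, 0, 0))
  xs <- voxel_axis(vol0, 1); ys <- voxel_axis(vol0, 2)
  zs <- voxel_axis(vol0, 3)
  x0 <- (max(xs) + min(xs)) / 2
  y0 <- (max(ys) + min(ys)) / 2
  yv <- y0 + spec$vertebra_offset_mm

  xb <- x0 - spec$blood_pool_offset_mm
  if (spec$vertebra_offset_mm <=
      spec$aneurysm_max_radius_mm + spec$vertebra_radius_mm)
    stop("vertebral column overlaps the aorta: increase vertebra_offset_mm")
  if (spec$blood_pool_offset_mm <=
      spec$aneurysm_max_radius_mm + spec$blood_pool_radius_mm)
    stop("blood pool overlaps the aorta: increase blood_pool_offset_mm")
  margin <- 2 * spec$psf_sigma_mm
  if (x0 + spec$aneurysm_max_radius_mm + margin > max(xs) ||
      y0 - spec$aneurysm_max_radius_mm - margin < min(ys) ||
      xb - spec$blood_pool_radius_mm - margin < min(xs) ||
      yv + spec$vertebra_radius_mm + margin > max(ys))
    stop("phantom geometry exceeds the grid (need a 2-sigma margin)")

  # centerline: one point per slice, away from the z boundaries
  zmargin <- max(10, margin)
  kline <- which(zs >= zmargin & zs <= max(zs) - zmargin + 1e-9)
  if (length(kline) < 8L) stop("grid too short for a labeled centerline")
  zpts <- zs[kline]
  L <- spec$region_length_mm
  ztop <- max(zpts)
  labels <- ifelse(zpts > ztop - L, "thoracic",
            ifelse(zpts > ztop - 2 * L, "suprarenal",
            ifelse(zpts > ztop - 3 * L, "neck", "aneurysm")))
  if (!all(c("thoracic", "suprarenal", "neck", "aneurysm") %in% labels))
    stop("grid too short to fit all four aortic regions")
  rpts <- radius_profile(spec, zpts)
  line <- centerline(cbind(x0, y0, zpts), rpts, labels)

  # pre-blur PET
  d2xy <- outer((xs - x0)^2, (ys - y0)^2, "+")
  pet <- array(0, dim = d)
  aorta <- array(FALSE, dim = d)
  rz <- rep(NA_real_, d[3])
  for (k in seq_len(d[3])) {
    if (!(k %in% kline)) next
    r <- radius_profile(spec, zs[k])
    rz[k] <- r
    rin <- max(r - spec$wall_thickness_mm, 0)
    sl <- pet[, , k]
    lum <- d2xy <= rin^2
    wal <- d2xy <= r^2 & !lum
    sl[lum] <- spec$blood_suv
    sl[wal] <- spec$wall_suv
    pet[, , k] <- sl
    aorta[, , k] <- d2xy <= r^2
  }
  # vertebral column and blood-pool cylinder span the same z range as the
  # centerline, keeping them clear of the grid's z faces so blur truncation
  # stays negligible
  vert2d <- outer((xs - x0)^2, (ys - yv)^2, "+") <= spec$vertebra_radius_mm^2
  vert <- array(FALSE, dim = d)
  for (k in kline) vert[, , k] <- vert2d
  pet[vert] <- spec$vertebra_suv
  bp2d <- outer((xs - xb)^2, (ys - y0)^2, "+") <= spec$blood_pool_radius_mm^2
  bpool <- array(FALSE, dim = d)
  for (k in kline) bpool[, , k] <- bp2d
  pet[bpool] <- spec$blood_suv

  # ground truth from the pre-blur image, plus the spill-free reference:
  # the same aorta blurred with the vertebral column removed. Thresholding
  # is a spill-over correction, so its accuracy is judged against what the
  # blurred measurement would read if the vertebra were not there, while
  # the pre-blur values anchor the exact identities on unblurred phantoms.
  aorta_only <- pet
  aorta_only[vert] <- 0
  spillfree <- if (spec$psf_sigma_mm > 0)
    blur_volume(scalar_volume(aorta_only, sp, c(0, 0, 0)),
                spec$psf_sigma_mm)$data
  else aorta_only
  region_names <- c("aneurysm", "neck", "suprarenal", "thoracic")
  regions <- lapply(region_names, function(reg) {
    zr <- range(zpts[labels == reg])
    keep <- aorta
    kz <- zs >= zr[1] - 1e-9 & zs <= zr[2] + 1e-9
    keep[, , !kz] <- FALSE
    vals <- pet[keep]
    list(label = reg, z_lo = zr[1], z_hi = zr[2],
         n_voxels = sum(keep), suv_mean = mean(vals), suv_max = max(vals),
         suv_mean_spillfree = mean(spillfree[keep]),
         ama_mean_true = mean(vals) / spec$blood_suv,
         ama_max_true = max(vals) / spec$blood_suv)
  })
  names(regions) <- region_names
  truth <- list(blood_suv = spec$blood_suv,
                regions = regions,
                radius_mm = data.frame(z = zpts, r = rpts),
                aorta_mask = aorta,
                axis_xy = c(x0, y0), vertebra_axis_y = yv,
                blood_axis_x = xb,
                spec = spec)

  # imaging chain: PSF blur then additive noise
  petv <- scalar_volume(pet, sp, c(0, 0, 0))
  petv <- blur_volume(petv, spec$psf_sigma_mm)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    petv$data <- petv$data +
      array(stats::rnorm(prod(d), sd = spec$noise_sd), dim = d)
  }

  # CT: soft tissue 40 HU, blood 45, wall 50, bone 700
  ct <- array(40, dim = d)
  ct[bpool] <- 45
  ct[aorta] <- 45
  wall_only <- aorta & pet > spec$blood_suv & !vert
  ct[wall_only] <- 50
  ct[vert] <- 700
  ctv <- scalar_volume(ct, sp, c(0, 0, 0))

  list(pet = petv, ct = ctv, centerline = line, truth = truth)
}

#' Blood-pool and threshold sphere placements for a phantom
#'
#' Derives the sphere configuration [analyze_study()] needs from the
#' phantom geometry: two 8-mm blood-pool spheres centred in the blood-pool
#' cylinder (the phantom's stand-in for the right and left atria), and one
#' threshold sphere per region centred mid-wall on the side facing away
#' from the vertebral column — the highest genuine aortic uptake clearly
#' distinct from the vertebra.
#'
#' @param ph result of [make_phantom()].
#' @param blood_radius_mm radius of the blood-pool spheres (mm); must fit
#'   inside the blood-pool cylinder.
#' @param threshold_radius_mm radius of the per-region threshold spheres.
#' @return list with `blood` (two [sphere()]) and `threshold` (named list).
#' @export
phantom_study_spheres <- function(ph, blood_radius_mm = 8,
                                  threshold_radius_mm = 4) {
  spec <- ph$truth$spec
  x0 <- ph$truth$axis_xy[1]; y0 <- ph$truth$axis_xy[2]
  xb <- ph$truth$blood_axis_x
  zmid <- mean(range(ph$truth$radius_mm$z))
  gap <- blood_radius_mm + 1.5  # centres apart so the spheres never touch
  blood <- list(
    sphere(c(xb, y0, zmid - gap), blood_radius_mm),
    sphere(c(xb, y0, zmid + gap), blood_radius_mm))

  thr <- lapply(ph$truth$regions, function(reg) {
    prof <- ph$truth$radius_mm
    inreg <- prof$z >= reg$z_lo & prof$z <= reg$z_hi
    zstar <- prof$z[inreg][which.max(prof$r[inreg])]
    rstar <- max(prof$r[inreg])
    sphere(c(x0, y0 - (rstar - spec$wall_thickness_mm / 2), zstar),
           threshold_radius_mm)
  })
  list(blood = blood, threshold = thr)
}

#' Simulated observer readings
#'
#' Produces a subjects x observers matrix of readings,
#' `reading[s, o] = truth[s] + N(0, observer_sd)` independently per cell —
#' the test substrate for intra- and inter-observer repeatability
#' statistics. Deterministic given `seed`.
#'
#' @param truth_values numeric vector of per-subject true measurements.
#' @param observer_sd standard deviation of observer error (>= 0).
#' @param n_observers number of observers (>= 2).
#' @param seed integer random seed.
#' @return numeric matrix (subjects x observers).
#' @export
make_observer_replicates <- function(truth_values, observer_sd,
                                     n_observers = 2L, seed = 1L) {
  truth_values <- as.numeric(truth_values)
  if (length(truth_values) == 0L) stop("truth_values is empty")
  if (observer_sd < 0) stop("observer_sd must be >= 0")
  if (n_observers < 2L) stop("need at least 2 observers")
  set.seed(as.integer(seed))
  n <- length(truth_values)
  err <- matrix(stats::rnorm(n * n_observers, sd = observer_sd),
                nrow = n, ncol = n_observers)
  matrix(truth_values, n, n_observers) + err
}
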