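#' Phantom specification
#'
#' Describes one synthetic heterogeneous lung-lesion phantom: the grid,
#' the irregular lesion geometry, the three-level intratumoral activity
#' partition, the kinetic parameter sets that give each tissue its value
#' at the acquisition time, respiratory-motion parameters, and the
#' image-degradation (PSF blur, Poisson noise, post-filter) settings.
#'
#' Background activity is normalized to the normal-lung value, so lung
#' voxels carry 1 and lesion voxels carry their kinetic lesion-to-lung
#' uptake ratio at `scan_time_min`.
#'
#' @param shape grid dimensions `(nz, ny, nx)`; default `c(48, 200, 200)`,
#'   the simulated scanner's 200 x 200 transaxial matrix.
#' @param spacing voxel spacing `(dz, dy, dx)` in cm; default
#'   `c(0.50, 0.41, 0.41)`.
#' @param volume_cm3 target static lesion volume in cm^3.
#' @param center lesion center in voxel coordinates `(z, y, x)`; default
#'   the grid center.
#' @param perturb_amp relative amplitude of the seeded radial boundary
#'   perturbation (0 = sphere; default 0.25).
#' @param perturb_smooth smoothing sigma of the perturbation field, voxels
#'   (default 3).
#' @param level_fractions fractions of lesion voxels assigned to the three
#'   activity levels, core (Level I) first; must sum to 1. Default equal
#'   thirds.
#' @param tissues named list of [kinetic_params()] with at least
#'   `level1..level3` and `lung`; default [fdg_tissue_params()].
#' @param input arterial input function; default [feng_input()].
#' @param scan_time_min acquisition time post injection, minutes
#'   (default 70).
#' @param motion_bins number of respiratory bins (default 10).
#' @param diaphragm_cm peak-to-peak cranio-caudal (diaphragm) motion in cm
#'   (default 1.5). Set 0 together with `ap_cm` to disable motion.
#' @param ap_cm peak-to-peak anterior-posterior motion in cm (default 0.5).
#' @param cycle_s breathing-cycle length in seconds (default 5; recorded
#'   for provenance, the averaged image depends only on the bin phases).
#' @param noise_scale expected Poisson counts per unit (background)
#'   activity per voxel (default 25).
#' @param psf_fwhm_mm effective reconstruction resolution of the
#'   image-domain degradation, mm FWHM (default 12). This is wider than a
#'   scanner's intrinsic PSF because it stands in for the whole
#'   projection/reconstruction chain (partial OSEM convergence, filtering),
#'   calibrated so that degraded lesion-to-background contrast lands near
#'   the 3-4.5 range typical of reconstructed thoracic FDG simulations.
#' @param postfilter_fwhm_mm Gaussian post-reconstruction filter, mm FWHM
#'   (default 2).
#' @param seed integer seed making the phantom reproducible.
#' @return An object of class `phantom_spec` (a validated list).
#' @export
phantom_spec <- function(shape = c(48, 200, 200),
                         spacing = c(0.50, 0.41, 0.41),
                         volume_cm3 = 20,
                         center = NULL,
                         perturb_amp = 0.25,
                         perturb_smooth = 3,
                         level_fractions = c(1, 1, 1) / 3,
                         tissues = fdg_tissue_params(),
                         input = feng_input(),
                         scan_time_min = 70,
                         motion_bins = 10,
                         diaphragm_cm = 1.5,
                         ap_cm = 0.5,
                         cycle_s = 5,
                         noise_scale = 25,
                         psf_fwhm_mm = 12,
                         postfilter_fwhm_mm = 2,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("'shape' must be three dimensions of at least 8 voxels")
  if (any(spacing <= 0)) stop("'spacing' must be positive (cm)")
  if (volume_cm3 <= 0) stop("'volume_cm3' must be positive")
  if (is.null(center)) center <- (shape + 1) / 2
  if (abs(sum(level_fractions) - 1) > 1e-8 || any(level_fractions < 0))
    stop("'level_fractions' must be non-negative and sum to 1")
  if (motion_bins < 1L) stop("'motion_bins' must be >= 1")
  if (diaphragm_cm < 0 || ap_cm < 0) stop("motion amplitudes must be >= 0")
  if (noise_scale <= 0) stop("'noise_scale' must be positive")
  req <- c("level1", "level2", "level3", "lung")
  if (!all(req %in% names(tissues)))
    stop("'tissues' must contain: ", paste(req, collapse = ", "))
  # lesion must fit: radius (with perturbation headroom) inside the grid
  r_cm <- (3 * volume_cm3 / (4 * pi))^(1 / 3) * (1 + perturb_amp)
  half_cm <- (shape - 1) / 2 * spacing
  if (any(r_cm >= half_cm))
    stop("lesion (radius ", round(r_cm, 2), " cm) does not fit in the grid")
  structure(list(
    shape = shape, spacing = as.numeric(spacing), volume_cm3 = volume_cm3,
    center = as.numeric(center), perturb_amp = perturb_amp,
    perturb_smooth = perturb_smooth,
    level_fractions = as.numeric(level_fractions), tissues = tissues,
    input = input, scan_time_min = scan_time_min,
    motion_bins = as.integer(motion_bins), diaphragm_cm = diaphragm_cm,
    ap_cm = ap_cm, cycle_s = cycle_s, noise_scale = noise_scale,
    psf_fwhm_mm = psf_fwhm_mm, postfilter_fwhm_mm = postfilter_fwhm_mm,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s grid, %.3g cm^3 lesion, seed %d\n",
              paste(x$shape, collapse = "x"), x$volume_cm3, x$seed))
  cat(sprintf("  motion: %d bins, %.2g cm diaphragm / %.2g cm AP; noise scale %g, PSF %g mm\n",
              x$motion_bins, x$diaphragm_cm, x$ap_cm, x$noise_scale,
              x$psf_fwhm_mm))
  invisible(x)
}

#' Build the noise-free phantom
#'
#' Creates one irregular lesion embedded in uniform lung background. The
#' lesion is a seeded random blob: a sphere of the requested volume whose
#' implicit surface is perturbed by a smoothed Gaussian random field, then
#' cleaned to a single filled component. Lesion voxels are partitioned
#' into three concentric activity levels (core = Level I, rim = Level III)
#' with voxel counts matching `level_fractions` to within one voxel;
#' activities are the kinetic lesion-to-lung uptake ratios at the scan
#' time, with background lung fixed at 1.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_case` with elements
#'   `activity` (noise-free [voxel_volume()]), `gt_static` /
#'   `gt_motion` (logical ground-truth masks; identical until
#'   [apply_motion()] is applied), `level_masks` (list of three logical
#'   masks partitioning `gt_static`), `labels` (integer tissue label
#'   volume: 1 lung, 2-4 Levels I-III), `pet_image` (`NULL` until
#'   [degrade()]), and `spec`.
#' @examples
#' spec <- phantom_spec(shape = c(24, 48, 48), volume_cm3 = 8, seed = 7)
#' case <- build_phantom(spec)
#' sum(case$gt_static) * voxel_size(case$activity)  # ~ 8 cm^3
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    mask <- .lesion_blob(spec)
    if (!any(mask)) stop("lesion generation produced an empty mask")
    lev <- .partition_levels(mask, spec$level_fractions)
    ratios <- uptake_ratios(spec$tissues[c("level1", "level2", "level3")],
                            spec$tissues$lung, spec$input,
                            spec$scan_time_min)
    act <- array(1, spec$shape)   # lung background normalized to 1
    lab <- array(1L, spec$shape)
    for (i in 1:3) {
      act[lev[[i]]] <- ratios[i]
      lab[lev[[i]]] <- i + 1L
    }
    structure(list(
      activity = voxel_volume(act, spec$spacing),
      gt_static = mask, gt_motion = mask,
      level_masks = lev, labels = lab,
      pet_image = NULL, spec = spec
    ), class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  vs <- voxel_size(x$activity)
  cat(sprintf("<phantom_case> %s grid; GT static %.2f cm^3, motion-union %.2f cm^3; %s\n",
              paste(dim(x$activity), collapse = "x"),
              sum(x$gt_static) * vs, sum(x$gt_motion) * vs,
              if (is.null(x$pet_image)) "noise-free" else "degraded PET present"))
  invisible(x)
}

# seeded irregular blob: implicit surface  r_sphere - dist + amp*r*N(x) > 0
.lesion_blob <- function(spec) {
  d <- spec$shape
  r <- (3 * spec$volume_cm3 / (4 * pi))^(1 / 3)
  cz <- (seq_len(d[1]) - spec$center[1]) * spec$spacing[1]
  cy <- (seq_len(d[2]) - spec$center[2]) * spec$spacing[2]
  cx <- (seq_len(d[3]) - spec$center[3]) * spec$spacing[3]
  dist <- sqrt(outer(outer(cz^2, cy^2, `+`), cx^2, `+`))
  f <- r - dist
  if (spec$perturb_amp > 0) {
    # restrict the noise field to a working box around the lesion
    half <- ceiling(r * (1 + spec$perturb_amp) / spec$spacing) + 4L
    rng <- lapply(1:3, function(ax)
      max(1L, round(spec$center[ax]) - half[ax]):min(d[ax], round(spec$center[ax]) + half[ax]))
    nb <- array(stats::rnorm(prod(lengths(rng))), lengths(rng))
    nb <- gauss_blur3(nb, rep(spec$perturb_smooth, 3))
    nb <- (nb - mean(nb)) / stats::sd(nb)
    noise <- array(0, d)
    noise[rng[[1]], rng[[2]], rng[[3]]] <- nb
    f <- f + spec$perturb_amp * r * noise
  }
  mask <- f > 0
  mask <- largest_component(mask)
  fill_holes(mask)
}

# concentric partition by erosion depth (deepest layers = Level I core);
# ties within a layer broken by continuous distance to the lesion centroid
.partition_levels <- function(mask, fractions) {
  n <- sum(mask)
  depth <- peel_depth(mask)
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  cdist <- sqrt(rowSums((idx - rep(ctr, each = nrow(idx)))^2))
  ord <- order(-depth[mask], cdist)   # innermost first
  counts <- diff(round(cumsum(c(0, fractions)) * n))
  lev <- lapply(1:3, function(i) array(FALSE, dim(mask)))
  flat <- which(mask)[ord]
  off <- 0L
  for (i in 1:3) {
    if (counts[i] > 0) lev[[i]][flat[(off + 1L):(off + counts[i])]] <- TRUE
    off <- off + counts[i]
  }
  lev
}

#' Apply respiratory-motion averaging
#'
#' Replaces the activity map by the mean over `motion_bins` rigidly
#' displaced copies of the lesion following a sinusoidal trajectory
#' (dominant axis cranio-caudal, secondary anterior-posterior), assuming
#' no uptake change over the breathing cycle. Displacements are taken at
#' bin midpoints and expressed relative to bin 3 — the mid-range
#' (intermediate) phase — so the static phantom already sits at the bin-3
#' reference position and `gt_static` is contained in the motion union.
#' Per-bin displacements are rounded to whole voxels, which conserves
#' total lesion activity exactly. `gt_motion` becomes the union of the
#' displaced static masks.
#'
#' @param case a `phantom_case` from [build_phantom()].
#' @param spec the same [phantom_spec()] (defaults to `case$spec`).
#' @return The modified `phantom_case`.
#' @export
apply_motion <- function(case, spec = case$spec) {
  stopifnot(inherits(case, "phantom_case"))
  shifts <- motion_shifts(spec)
  if (nrow(shifts) == 0L || all(shifts == 0L)) {
    case$gt_motion <- case$gt_static
    return(case)
  }
  bg <- array(1, spec$shape)
  lesion_vals <- array(0, spec$shape)
  lesion_vals[case$gt_static] <- case$activity[case$gt_static]
  acc <- array(0, spec$shape)
  un <- array(FALSE, spec$shape)
  for (b in seq_len(nrow(shifts))) {
    sh <- shifts[b, ]
    m <- shift3(case$gt_static, sh, fill = FALSE)
    v <- shift3(lesion_vals, sh, fill = 0)
    bin <- bg
    bin[m] <- v[m]
    acc <- acc + bin
    un <- un | m
  }
  case$activity <- as_volume_like(acc / nrow(shifts), case$activity)
  case$gt_motion <- un
  case
}

# per-bin whole-voxel displacements (z, y, x), relative to bin 3
motion_shifts <- function(spec) {
  nb <- spec$motion_bins
  ph <- (seq_len(nb) - 0.5) / nb
  # displacement 0..A over the cycle; bin-3 midpoint (phase 0.25) is A/2
  dz_cm <- spec$diaphragm_cm / 2 * (1 - cos(2 * pi * ph)) - spec$diaphragm_cm / 2
  dy_cm <- spec$ap_cm / 2 * (1 - cos(2 * pi * ph)) - spec$ap_cm / 2
  cbind(z = as.integer(round(dz_cm / spec$spacing[1])),
        y = as.integer(round(dy_cm / spec$spacing[2])),
        x = 0L)
}

#' Degrade a noise-free activity map into a PET-like image
#'
#' Image-domain degradation model standing in for the full
#' projection/reconstruction chain: Gaussian PSF blur (system
#' resolution), Poisson resampling at `noise_scale` expected counts per
#' unit activity, rescaling back to activity units, and a Gaussian
#' post-reconstruction filter.
#'
#' @param activity noise-free [voxel_volume()] (non-negative).
#' @param spec a [phantom_spec()] carrying `noise_scale`, `psf_fwhm_mm`
#'   and `postfilter_fwhm_mm`.
#' @param seed integer seed for the Poisson draw.
#' @return A degraded [voxel_volume()]; never negative.
#' @export
degrade <- function(activity, spec, seed = spec$seed) {
  stopifnot(inherits(activity, "voxel_volume"), inherits(spec, "phantom_spec"))
  if (min(activity) < 0) stop("'activity' must be non-negative")
  sp_mm <- vox_spacing(activity) * 10
  blur1 <- fwhm_to_sigma(spec$psf_fwhm_mm) / sp_mm
  blur2 <- fwhm_to_sigma(spec$postfilter_fwhm_mm) / sp_mm
  x <- gauss_blur3(unclass(activity), blur1)
  x[x < 0] <- 0
  noisy <- withr::with_seed(seed,
    array(stats::rpois(length(x), x * spec$noise_scale), dim(x)))
  x <- noisy / spec$noise_scale
  x <- gauss_blur3(x, blur2)
  x[x < 0] <- 0
  as_volume_like(x, activity)
}

#' Generate the two user-defined initial tumor masks
#'
#' Produces the two initial-mask conditions under which every
#' segmentation method is run: a regular rectangle area — the axis-aligned
#' bounding box of the ground truth expanded by `margin` voxels per axis
#' (clipped at the grid border) — and an irregular cropping area — the
#' ground truth dilated by a seeded, spatially varying radius and
#' hole-filled. Both strictly contain the ground truth.
#'
#' @param gt non-empty logical 3-D ground-truth mask.
#' @param seed integer seed for the irregular dilation field.
#' @param margin rectangle expansion, voxels per axis (default 3).
#' @param radius_range range of the spatially varying dilation radius in
#'   voxels (default `c(1, 4)`).
#' @param field_smooth smoothing sigma of the radius field, voxels
#'   (default 4).
#' @return List with logical masks `rectangle` and `irregular`.
#' @export
gen_masks <- function(gt, seed = 1L, margin = 3L, radius_range = c(1, 4),
                      field_smooth = 4) {
  if (!any(gt)) stop("'gt' mask is empty")
  d <- dim(gt)
  rng <- bbox_ranges(gt, margin = margin)
  rect <- array(FALSE, d)
  rect[rng[[1]], rng[[2]], rng[[3]]] <- TRUE

  rmax <- as.integer(ceiling(radius_range[2]))
  depth <- dilate_depth(gt, rmax)
  irr <- withr::with_seed(seed, {
    # smooth random field rescaled into [r_min, r_max], evaluated on a
    # working box around the dilated ground truth
    wrk <- bbox_ranges(gt, margin = rmax + 2L)
    nb <- array(stats::rnorm(prod(lengths(wrk))), lengths(wrk))
    nb <- gauss_blur3(nb, rep(field_smooth, 3))
    nb <- (nb - min(nb)) / max(max(nb) - min(nb), .Machine$double.eps)
    rad <- array(radius_range[1], d)
    rad[wrk[[1]], wrk[[2]], wrk[[3]]] <-
      radius_range[1] + nb * (radius_range[2] - radius_range[1])
    gt | (depth <= pmax(rad, 1))
  })
  irr <- fill_holes(irr)
  list(rectangle = rect, irregular = irr)
}
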