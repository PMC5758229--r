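#' PET/CT phantom grid parameters
#'
#' Geometry of the simulated scanner grids. The PET grid has `shape` voxels
#' at `spacing_mm`; the CT grid covers exactly the same physical extent at a
#' nominal `ct_spacing_mm` (the actual CT spacing is adjusted so a whole
#' number of CT voxels tiles the PET extent). The point-spread function of
#' the PET system is modelled as an isotropic Gaussian of full width at half
#' maximum `psf_fwhm_mm`; clinical PET resolution is 4-5 mm FWHM, default
#' 4.5. `psf_fwhm_mm = 0` disables blurring.
#'
#' Activity is rendered on a fine grid oversampled relative to the PET grid
#' before blurring and block-averaging down, so that sub-voxel sphere
#' boundaries and the PSF are represented faithfully. The per-axis
#' oversampling factor defaults to the factor (at most 4) that brings the
#' fine voxel near 0.8 mm; grids already finer than ~1.2 mm are rendered
#' natively. When `psf_fwhm_mm = 0` no oversampling is used, so an
#' unblurred voxel takes the activity at its centre exactly.
#'
#' @param shape integer length 3: PET grid size in voxels.
#' @param spacing_mm PET voxel spacing in mm (length 1 or 3); the 3.27 mm
#'   default matches the axial slice thickness of a whole-body PET protocol.
#' @param psf_fwhm_mm PET point-spread FWHM in mm (>= 0).
#' @param ct_spacing_mm nominal CT voxel spacing in mm (thin-slice chest CT,
#'   default 1.25).
#' @param oversample optional integer override of the per-axis oversampling
#'   factor (length 1 or 3).
#' @return object of class `grid_params`.
#' @export
grid_params <- function(shape = c(24L, 24L, 24L), spacing_mm = 3.27,
                        psf_fwhm_mm = 4.5, ct_spacing_mm = 1.25,
                        oversample = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("'shape' must be 3 integers >= 4")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(spacing_mm <= 0)) stop("spacings must be positive")
  if (!is.numeric(psf_fwhm_mm) || psf_fwhm_mm < 0)
    stop("'psf_fwhm_mm' must be >= 0")
  if (ct_spacing_mm <= 0) stop("'ct_spacing_mm' must be positive")
  if (is.null(oversample)) {
    oversample <- if (psf_fwhm_mm == 0) rep(1L, 3L) else
      pmax(1L, pmin(4L, as.integer(round(spacing_mm / 0.82))))
  } else {
    oversample <- as.integer(oversample)
    if (length(oversample) == 1L) oversample <- rep(oversample, 3L)
    if (any(oversample < 1L)) stop("'oversample' must be >= 1")
  }
  extent <- shape * spacing_mm
  ct_shape <- pmax(4L, as.integer(round(extent / ct_spacing_mm)))
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 psf_fwhm_mm = psf_fwhm_mm,
                 ct_shape = ct_shape, ct_spacing_mm = extent / ct_shape,
                 oversample = oversample),
            class = "grid_params")
}

#' @export
print.grid_params <- function(x, ...) {
  cat(sprintf("<grid_params> PET %s @ %s mm, CT %s @ %s mm, PSF %.2f mm FWHM\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              paste(x$ct_shape, collapse = "x"),
              paste(signif(x$ct_spacing_mm, 4), collapse = "x"),
              x$psf_fwhm_mm))
  invisible(x)
}

#' Synthetic lung-lesion description
#'
#' Ground-truth parameters of one simulated lung nodule. Lesions are
#' spheres; a part-solid nodule carries a concentric dense core occupying
#' `solid_fraction` of the lesion volume (ground-glass shell around it).
#' Tracer activity (pre-blur SUV) is uniform across the lesion; the density
#' type drives the CT appearance and the realistic coupling between type
#' and uptake is imposed by the cohort generator.
#'
#' @param nodule_type `"nonsolid"`, `"part_solid"` or `"solid"`.
#' @param long_diameter_mm sphere diameter in mm (> 0).
#' @param lesion_activity pre-blur lesion SUV (> background).
#' @param background_activity lung background SUV (>= 0).
#' @param solid_fraction volume fraction of the dense core; forced to 1 for
#'   solid and 0 for nonsolid nodules; default 0.3 for part-solid.
#' @param center_mm lesion centre in world mm, or `NULL` to centre in the
#'   grid at generation time.
#' @param hu_ground_glass,hu_solid,hu_lung_bg CT attenuation (HU) of the
#'   ground-glass component, the dense component and background lung.
#' @return object of class `lesion_spec`.
#' @export
lesion_spec <- function(nodule_type = c("solid", "part_solid", "nonsolid"),
                        long_diameter_mm, lesion_activity,
                        background_activity = 0.5, solid_fraction = NULL,
                        center_mm = NULL, hu_ground_glass = -600,
                        hu_solid = 30, hu_lung_bg = -850) {
  nodule_type <- match.arg(nodule_type)
  if (!is.numeric(long_diameter_mm) || long_diameter_mm <= 0)
    stop("'long_diameter_mm' must be positive")
  if (background_activity < 0) stop("'background_activity' must be >= 0")
  if (lesion_activity <= background_activity)
    stop("'lesion_activity' must exceed 'background_activity'")
  solid_fraction <- switch(nodule_type,
    solid = 1,
    nonsolid = 0,
    part_solid = if (is.null(solid_fraction)) 0.3 else solid_fraction)
  if (solid_fraction < 0 || solid_fraction > 1)
    stop("'solid_fraction' must be in [0, 1]")
  if (!is.null(center_mm) && length(center_mm) != 3L)
    stop("'center_mm' must have length 3")
  structure(list(nodule_type = nodule_type,
                 long_diameter_mm = as.numeric(long_diameter_mm),
                 lesion_activity = as.numeric(lesion_activity),
                 background_activity = as.numeric(background_activity),
                 solid_fraction = solid_fraction,
                 center_mm = if (is.null(center_mm)) NULL else as.numeric(center_mm),
                 hu_ground_glass = hu_ground_glass, hu_solid = hu_solid,
                 hu_lung_bg = hu_lung_bg),
            class = "lesion_spec")
}

# --- rendering internals ----------------------------------------------------

# Gaussian blur of a 3-D array via FFT with the analytic transfer function
# exp(-2 pi^2 sigma^2 |k|^2). Circular convolution: callers must keep
# structures away from the boundary by at least the PSF width. Exactly
# preserves the array total (the DC coefficient is multiplied by 1).
gaussian_blur_fft <- function(a, spacing, fwhm) {
  if (fwhm == 0) return(a)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(a)
  freq <- function(n, s) {
    k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * s)
    k^2
  }
  kx2 <- freq(d[1], spacing[1])
  ky2 <- freq(d[2], spacing[2])
  kz2 <- freq(d[3], spacing[3])
  k2 <- array(kx2, d) + rep(ky2, each = d[1]) + rep(kz2, each = d[1] * d[2])
  H <- exp(-2 * pi^2 * sigma^2 * k2)
  Re(stats::fft(stats::fft(a) * H, inverse = TRUE)) / length(a)
}

# Block-average one axis of a 3-D array by integer factor f.
downsample_axis <- function(a, f, axis) {
  if (f == 1L) return(a)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(a, perm)
  d <- dim(a)
  m <- matrix(a, nrow = f)
  v <- colMeans(m)
  a <- array(v, c(d[1] / f, d[2], d[3]))
  aperm(a, order(perm))
}

# Block-average a fine array down by per-axis factors f (length 3).
block_mean <- function(a, f) {
  for (axis in 1:3) a <- downsample_axis(a, f[axis], axis)
  a
}

# Render a set of spheres (uniform activity inside each) plus uniform
# background on the oversampled grid, blur, and downsample to the PET grid.
render_pet <- function(grid, centers, radii, activities, background) {
  f <- grid$oversample
  fine_shape <- grid$shape * f
  fine_spacing <- grid$spacing_mm / f
  a <- array(background, fine_shape)
  for (i in seq_along(radii)) {
    d2 <- dist2_from_point(fine_shape, fine_spacing, centers[[i]])
    a[d2 <= radii[i]^2] <- activities[i]
  }
  a <- gaussian_blur_fft(a, fine_spacing, grid$psf_fwhm_mm)
  pet <- block_mean(a, f)
  image_volume(pet, grid$spacing_mm, "SUV")
}

# --- lesion phantom ---------------------------------------------------------

#' Generate one synthetic PET/CT lesion case with known ground truth
#'
#' Renders the lesion's activity on an oversampled grid, convolves with the
#' Gaussian PSF, block-averages to the PET grid and adds seeded Gaussian
#' noise. The CT volume is rendered on the fine CT grid (ground-glass shell
#' and dense core as specified) and the ground-truth mask is the analytic
#' sphere support sampled at CT voxel centres; the true volume is exact
#' voxel-count arithmetic on that mask.
#'
#' @param spec a [lesion_spec()].
#' @param grid a [grid_params()].
#' @param noise_sd standard deviation of additive Gaussian SUV noise on the
#'   PET grid (0 = noiseless).
#' @param seed integer seed controlling the noise draw.
#' @return object of class `phantom_case`: list with `spec` (centre filled
#'   in), `pet`, `ct`, `truth_mask` (logical, CT grid), `truth_volume_mm3`,
#'   `suv_max` (post-blur, pre-noise maximum on the PET grid), `seed`.
#' @export
generate_lesion_phantom <- function(spec, grid, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(spec, "lesion_spec"), inherits(grid, "grid_params"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  extent <- grid$shape * grid$spacing_mm
  center <- if (is.null(spec$center_mm)) extent / 2 else spec$center_mm
  R <- spec$long_diameter_mm / 2
  margin <- R + grid$psf_fwhm_mm
  if (any(center - margin < 0) || any(center + margin > extent))
    stop("lesion (plus PSF margin) does not fit inside the grid")
  spec$center_mm <- center

  pet <- render_pet(grid, list(center), R, spec$lesion_activity,
                    spec$background_activity)
  suv_max <- max(pet$data)
  if (noise_sd > 0) {
    noise <- with_local_seed(seed,
      array(stats::rnorm(length(pet$data), 0, noise_sd), dim(pet$data)))
    pet$data <- pet$data + noise
  }

  ct_vol <- image_volume(array(spec$hu_lung_bg, grid$ct_shape),
                         grid$ct_spacing_mm, "HU")
  d2 <- dist2_from_point(grid$ct_shape, grid$ct_spacing_mm, center)
  truth_mask <- d2 <= R^2
  shell_hu <- switch(spec$nodule_type, solid = spec$hu_solid,
                     spec$hu_ground_glass)
  ct_vol$data[truth_mask] <- shell_hu
  if (spec$nodule_type == "part_solid" && spec$solid_fraction > 0) {
    core_r <- R * spec$solid_fraction^(1 / 3)
    ct_vol$data[d2 <= core_r^2] <- spec$hu_solid
  }

  structure(list(spec = spec, pet = pet, ct = ct_vol,
                 truth_mask = truth_mask,
                 truth_volume_mm3 = sum(truth_mask) * voxel_volume_mm3(ct_vol),
                 suv_max = suv_max, seed = as.integer(seed)),
            class = "phantom_case")
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s, d = %.1f mm, activity %.2f on bg %.2f, truth %.0f mm^3\n",
              x$spec$nodule_type, x$spec$long_diameter_mm,
              x$spec$lesion_activity, x$spec$background_activity,
              x$truth_volume_mm3))
  invisible(x)
}

#' Default lesion parameter ranges per nodule density type
#'
#' Uniform sampling ranges used by [generate_cohort()]. Diameters span
#' 8-35 mm for every type (clinical cohorts show no strong size/type
#' coupling); pre-blur activities are chosen so that nonsolid nodules fall
#' mostly at SUVmax <= 2 and solid nodules mostly above it, reproducing the
#' strong type-uptake association seen clinically in early lung
#' adenocarcinoma.
#'
#' @return named list with one element per type, each holding
#'   `diameter_mm` and `activity` ranges, plus a shared `background` range.
#' @export
default_cohort_ranges <- function() {
  list(nonsolid   = list(diameter_mm = c(8, 35), activity = c(1.2, 2.4)),
       part_solid = list(diameter_mm = c(8, 35), activity = c(1.5, 4.5)),
       solid      = list(diameter_mm = c(8, 35), activity = c(2.5, 8.0)),
       background = c(0.4, 0.6))
}

#' Default grid for cohort cases
#'
#' Elongated along x so the lesion sits in one "lung" and the mid-sagittal
#' mirror of its position falls in clean background for contralateral
#' background sampling.
#' @param psf_fwhm_mm PET PSF FWHM in mm.
#' @return a [grid_params()].
#' @export
default_cohort_grid <- function(psf_fwhm_mm = 4.5) {
  grid_params(shape = c(40L, 24L, 24L), spacing_mm = 3.27,
              psf_fwhm_mm = psf_fwhm_mm, ct_spacing_mm = 1.25)
}

#' Generate a synthetic lesion cohort
#'
#' Draws per-case diameters, activities and backgrounds from per-type
#' ranges and renders each case with [generate_lesion_phantom()]. Lesion
#' centres are fixed at a quarter of the x extent (off the mirror plane)
#' with a small seeded jitter in y/z. Fully deterministic given `seed`.
#'
#' @param counts named integer vector/list: cases per nodule type, e.g.
#'   `c(nonsolid = 16, part_solid = 30, solid = 87)`.
#' @param ranges parameter ranges as in [default_cohort_ranges()].
#' @param grid a [grid_params()]; default [default_cohort_grid()].
#' @param noise_sd additive Gaussian SUV noise (default 0.05).
#' @param seed integer master seed.
#' @return list of `phantom_case`, each with a `case_id` element.
#' @export
generate_cohort <- function(counts, ranges = default_cohort_ranges(),
                            grid = default_cohort_grid(), noise_sd = 0.05,
                            seed = 1L) {
  counts <- unlist(counts)
  if (length(counts) == 0 || sum(counts) == 0) return(list())
  if (any(counts < 0)) stop("counts must be nonnegative")
  bad <- setdiff(names(counts), c("nonsolid", "part_solid", "solid"))
  if (length(bad)) stop("unknown nodule type(s): ", paste(bad, collapse = ", "))
  types <- rep(names(counts), counts)
  n <- length(types)
  extent <- grid$shape * grid$spacing_mm

  draws <- with_local_seed(seed, {
    diam <- act <- bg <- numeric(n)
    for (i in seq_len(n)) {
      rg <- ranges[[types[i]]]
      diam[i] <- stats::runif(1, rg$diameter_mm[1], rg$diameter_mm[2])
      act[i] <- stats::runif(1, rg$activity[1], rg$activity[2])
      bg[i] <- stats::runif(1, ranges$background[1], ranges$background[2])
      bg[i] <- min(bg[i], act[i] - 0.1)  # keep lesion hotter than background
    }
    jit <- matrix(stats::runif(2 * n, -2, 2), ncol = 2)
    case_seed <- sample.int(.Machine$integer.max, n)
    list(diam = diam, act = act, bg = bg, jit = jit, case_seed = case_seed)
  })

  cases <- vector("list", n)
  for (i in seq_len(n)) {
    center <- c(0.25 * extent[1],
                extent[2] / 2 + draws$jit[i, 1],
                extent[3] / 2 + draws$jit[i, 2])
    sp <- lesion_spec(types[i], draws$diam[i], draws$act[i], draws$bg[i],
                      center_mm = center)
    cases[[i]] <- generate_lesion_phantom(sp, grid, noise_sd,
                                          draws$case_seed[i])
    cases[[i]]$case_id <- sprintf("%s_%03d", types[i], i)
  }
  cases
}

#' Generate a hot-sphere calibration phantom
#'
#' Spheres of the given diameters at uniform activity `contrast` in a
#' uniform background of activity 1.0, blurred by the grid PSF; noiseless.
#' Used to measure recovery coefficients at known sphere-to-background
#' activity ratio. Three 15 mm background reference ROIs are placed near
#' grid corners, away from every hot sphere.
#'
#' @param diameters sphere diameters in mm (default the six standard image
#'   quality sphere sizes 10-37 mm).
#' @param contrast sphere-to-background activity ratio (default 8, a
#'   high-contrast phantom).
#' @param grid a [grid_params()]; default a 64x64x20 grid at 3.27 mm.
#' @return object of class `calibration_phantom`: list with
#'   `sphere_diameters_mm`, `contrast_ratio`, `pet`, `true_centers_mm`
#'   (list), `bg_roi_centers_mm` (list), `bg_roi_radius_mm`, `grid`.
#' @export
generate_calibration_phantom <- function(diameters = c(10, 13, 17, 22, 28, 37),
                                         contrast = 8,
                                         grid = grid_params(
                                           shape = c(64L, 64L, 20L),
                                           spacing_mm = 3.27,
                                           psf_fwhm_mm = 4.5)) {
  if (contrast <= 1) stop("'contrast' must exceed 1")
  if (any(diameters <= 0)) stop("diameters must be positive")
  nd <- length(diameters)
  extent <- grid$shape * grid$spacing_mm
  fx <- c(0.22, 0.5, 0.78)
  fy <- c(0.3, 0.7)
  pos <- expand.grid(x = fx * extent[1], y = fy * extent[2])
  if (nd > nrow(pos)) stop("too many spheres for the sphere layout")
  centers <- lapply(seq_len(nd),
                    function(i) c(pos$x[i], pos$y[i], extent[3] / 2))
  radii <- diameters / 2
  for (i in seq_len(nd)) {
    m <- radii[i] + grid$psf_fwhm_mm
    if (any(centers[[i]] - m < 0) || any(centers[[i]] + m > extent))
      stop("sphere ", i, " does not fit inside the grid")
    if (i > 1) for (j in 1:(i - 1)) {
      gap <- sqrt(sum((centers[[i]] - centers[[j]])^2)) - radii[i] - radii[j]
      if (gap <= 0) stop("spheres ", j, " and ", i, " overlap")
    }
  }
  pet <- render_pet(grid, centers, radii, rep(contrast, nd), background = 1)

  bg_r <- 7.5
  bg_centers <- list(c(0.08, 0.08, 0.5) * extent,
                     c(0.92, 0.08, 0.5) * extent,
                     c(0.08, 0.92, 0.5) * extent)
  min_clear <- 2 * grid$psf_fwhm_mm
  for (b in bg_centers) for (i in seq_len(nd)) {
    gap <- sqrt(sum((b - centers[[i]])^2)) - radii[i] - bg_r
    if (gap < min_clear)
      stop("background ROI too close to sphere ", i,
           "; enlarge the grid or reduce sphere sizes")
  }
  structure(list(sphere_diameters_mm = as.numeric(diameters),
                 contrast_ratio = contrast, pet = pet,
                 true_centers_mm = centers,
                 bg_roi_centers_mm = bg_centers, bg_roi_radius_mm = bg_r,
                 grid = grid),
            class = "calibration_phantom")
}

#' @export
print.calibration_phantom <- function(x, ...) {
  cat(sprintf("<calibration_phantom> %d spheres (%s mm), contrast %.1f:1, PSF %.2f mm\n",
              length(x$sphere_diameters_mm),
              paste(x$sphere_diameters_mm, collapse = ", "),
              x$contrast_ratio, x$grid$psf_fwhm_mm))
  invisible(x)
}
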