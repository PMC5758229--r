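#' Bounding-box volume of interest
#'
#' Axis-aligned box in world millimetres placed around a lesion. At
#' segmentation time the box is snapped outward to whole voxels of the
#' target grid (half-open voxel convention).
#'
#' @param min_corner_mm,max_corner_mm length-3 corners, `min < max` per axis.
#' @return object of class `bbox_voi`.
#' @export
bounding_box_voi <- function(min_corner_mm, max_corner_mm) {
  if (length(min_corner_mm) != 3L || length(max_corner_mm) != 3L)
    stop("corners must have length 3")
  if (any(min_corner_mm >= max_corner_mm))
    stop("'min_corner_mm' must be strictly below 'max_corner_mm' on every axis")
  structure(list(min_corner_mm = as.numeric(min_corner_mm),
                 max_corner_mm = as.numeric(max_corner_mm)),
            class = "bbox_voi")
}

#' Default VOI around a phantom lesion
#' @param case a `phantom_case`.
#' @param margin_mm box margin beyond the lesion radius (default 8 mm).
#' @return a [bounding_box_voi()] clipped to the grid.
#' @export
lesion_voi <- function(case, margin_mm = 8) {
  r <- case$spec$long_diameter_mm / 2 + margin_mm
  ext <- extent_mm(case$pet)
  bounding_box_voi(pmax(case$spec$center_mm - r, 0),
                   pmin(case$spec$center_mm + r, ext))
}

# Snap a VOI outward to whole voxel indices on a volume's grid.
# Returns list(lo, hi) of inclusive 1-based voxel index bounds.
voi_to_index <- function(voi, vol) {
  stopifnot(inherits(voi, "bbox_voi"), inherits(vol, "image_volume"))
  d <- dim(vol$data)
  s <- vol$spacing_mm
  lo <- pmax(1L, pmin(d, as.integer(floor(voi$min_corner_mm / s)) + 1L))
  hi <- pmax(1L, pmin(d, as.integer(ceiling(voi$max_corner_mm / s))))
  if (any(voi$max_corner_mm <= 0) || any(voi$min_corner_mm >= d * s))
    stop("VOI does not intersect the image grid")
  if (any(hi < lo)) stop("VOI does not intersect the image grid")
  list(lo = lo, hi = hi)
}

# Crop the array of a volume to index bounds.
crop_to <- function(vol, ix) {
  vol$data[ix$lo[1]:ix$hi[1], ix$lo[2]:ix$hi[2], ix$lo[3]:ix$hi[3],
           drop = FALSE]
}

# Paste a cropped logical array back into a full-size FALSE array.
uncrop_mask <- function(sub, dims, ix) {
  full <- array(FALSE, dims)
  full[ix$lo[1]:ix$hi[1], ix$lo[2]:ix$hi[2], ix$lo[3]:ix$hi[3]] <- sub
  full
}

# Shared core of the fixed-threshold segmenters: voxels >= threshold inside
# the VOI, restricted to the 26-connected component containing the SUVmax
# voxel. Threshold comparisons are inclusive (>=).
segment_fixed_threshold <- function(pet, voi, threshold_suv, method,
                                    iterations = NA_integer_,
                                    converged = TRUE) {
  ix <- voi_to_index(voi, pet)
  sub <- crop_to(pet, ix)
  suv_max <- max(sub)
  if (suv_max <= 0) stop("VOI contains no voxel with SUV > 0")
  seed <- which.max(sub)
  sub_mask <- connected_component(sub >= threshold_suv, seed)
  mask <- uncrop_mask(sub_mask, dim(pet$data), ix)
  n <- sum(sub_mask)
  structure(list(method = method, mask = mask,
                 threshold_suv = threshold_suv,
                 mtv_mm3 = n * voxel_volume_mm3(pet),
                 suv_mean = if (n > 0) mean(sub[sub_mask]) else 0,
                 suv_max = suv_max,
                 iterations = iterations, converged = converged,
                 voi = voi),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: T = %.3f SUV, MTV = %.0f mm^3, SUVmean = %.3f (SUVmax %.3f)\n",
              x$method, x$threshold_suv, x$mtv_mm3, x$suv_mean, x$suv_max))
  if (!is.na(x$iterations))
    cat(sprintf("  %d iterations, converged = %s\n", x$iterations, x$converged))
  invisible(x)
}

#' Fixed 42% SUVmax threshold segmentation (T42%)
#'
#' Delineates all voxels with SUV at or above 42% of the maximum SUV inside
#' the VOI, keeping the 26-connected component that contains the SUVmax
#' voxel.
#'
#' @param pet an SUV `image_volume`.
#' @param voi a [bounding_box_voi()].
#' @return a `segmentation_result` (`method = "T42"`): binary mask on the
#'   PET grid, absolute threshold, MTV in cubic mm (exact voxel count times
#'   voxel volume), SUVmean inside the mask, SUVmax in the VOI.
#' @export
segment_t42 <- function(pet, voi) {
  ix <- voi_to_index(voi, pet)
  suv_max <- max(crop_to(pet, ix))
  if (suv_max <= 0) stop("VOI contains no voxel with SUV > 0")
  segment_fixed_threshold(pet, voi, 0.42 * suv_max, "T42")
}

#' 42% SUVmax threshold with recovery-coefficient correction (T42%xRC)
#'
#' As [segment_t42()] but the threshold fraction is scaled by the
#' recovery coefficient for the lesion's (CT-measured) long diameter:
#' `T = 0.42 * RC(d) * SUVmax`. Because `RC <= 1`, the threshold is lower
#' for small lesions, compensating partial-volume signal loss. For
#' diameters above 30 mm `RC = 1` and the result is identical to T42%.
#'
#' @inheritParams segment_t42
#' @param rc_table an [build_rc_table()] result.
#' @param long_diameter_mm lesion long diameter in mm (> 0), normally taken
#'   from the CT reference measurement.
#' @return a `segmentation_result` (`method = "T42RC"`).
#' @export
segment_t42_rc <- function(pet, voi, rc_table, long_diameter_mm) {
  if (long_diameter_mm <= 0) stop("'long_diameter_mm' must be positive")
  rc <- lookup_rc(rc_table, long_diameter_mm)
  ix <- voi_to_index(voi, pet)
  suv_max <- max(crop_to(pet, ix))
  if (suv_max <= 0) stop("VOI contains no voxel with SUV > 0")
  segment_fixed_threshold(pet, voi, 0.42 * rc * suv_max, "T42RC")
}

#' Configuration for the adaptive iterative segmentation
#'
#' @param weight weight of SUVmax against region SUVmean in the adaptive
#'   reference level, in `[0, 1]` (default 0.5).
#' @param frac threshold fraction applied to the reference level
#'   (default 0.42, matching the fixed-threshold convention).
#' @param tol convergence tolerance on the absolute threshold in SUV;
#'   `NULL` (default) resolves to 1% of the VOI SUVmax at run time.
#' @param max_iter iteration cap (default 100).
#' @return object of class `aia_config`.
#' @export
aia_config <- function(weight = 0.5, frac = 0.42, tol = NULL, max_iter = 100L) {
  if (weight < 0 || weight > 1) stop("'weight' must be in [0, 1]")
  if (frac <= 0 || frac > 1) stop("'frac' must be in (0, 1]")
  if (!is.null(tol) && tol <= 0) stop("'tol' must be positive")
  if (max_iter < 1) stop("'max_iter' must be >= 1")
  structure(list(weight = weight, frac = frac, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "aia_config")
}

#' Adaptive iterative threshold segmentation (AT-AIA)
#'
#' Iteratively adapts the threshold to the lesion's own uptake
#' distribution. Starting from the fixed 42% threshold, each iteration
#' forms the connected region at or above the current threshold, blends the
#' VOI SUVmax with the region SUVmean using `weight`, and re-thresholds at
#' `frac` of that blended reference level:
#'
#' `T_{k+1} = frac * ( w * SUVmax + (1 - w) * SUVmean(R_k) )`
#'
#' With a homogeneous region the reference level equals SUVmax and the
#' method coincides with T42%; heterogeneous or blurred lesions pull the
#' reference level down toward the region mean, adapting the absolute
#' threshold. Iteration stops when the region repeats exactly (exact fixed
#' point), when the threshold moves less than `tol`, or when a threshold
#' cycle / the iteration cap is hit (then `converged = FALSE` and the last
#' state is returned).
#'
#' @inheritParams segment_t42
#' @param cfg an [aia_config()].
#' @return a `segmentation_result` (`method = "AIA"`) with `iterations`
#'   and `converged` filled in.
#' @export
segment_aia <- function(pet, voi, cfg = aia_config()) {
  stopifnot(inherits(cfg, "aia_config"))
  ix <- voi_to_index(voi, pet)
  sub <- crop_to(pet, ix)
  suv_max <- max(sub)
  if (suv_max <= 0) stop("VOI contains no voxel with SUV > 0")
  seed <- which.max(sub)
  tol <- if (is.null(cfg$tol)) 0.01 * suv_max else cfg$tol
  w <- cfg$weight

  region_for <- function(thr) connected_component(sub >= thr, seed)
  next_thr <- function(region)
    cfg$frac * (w * suv_max + (1 - w) * mean(sub[region]))

  thr <- cfg$frac * suv_max
  history <- thr
  region <- region_for(thr)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    thr_new <- next_thr(region)
    region_new <- region_for(thr_new)
    if (identical(region_new, region)) {
      # exact fixed point: the region reproduces its own threshold
      thr <- thr_new; region <- region_new; converged <- TRUE; break
    }
    if (abs(thr_new - thr) < tol) {
      thr <- thr_new; region <- region_new; converged <- TRUE; break
    }
    if (any(abs(thr_new - history) < 1e-12)) {
      # threshold cycle: return last state, flag non-convergence
      thr <- thr_new; region <- region_new; break
    }
    if (iter >= cfg$max_iter) {
      thr <- thr_new; region <- region_new; break
    }
    history <- c(history, thr_new)
    thr <- thr_new
    region <- region_new
  }

  mask <- uncrop_mask(region, dim(pet$data), ix)
  n <- sum(region)
  structure(list(method = "AIA", mask = mask, threshold_suv = thr,
                 mtv_mm3 = n * voxel_volume_mm3(pet),
                 suv_mean = if (n > 0) mean(sub[region]) else 0,
                 suv_max = suv_max, iterations = iter,
                 converged = converged, voi = voi),
            class = "segmentation_result")
}

#' Estimate background SUV from the contralateral lung
#'
#' Mirrors the lesion centre across the mid-sagittal plane of the grid
#' (the plane normal to `mirror_axis` through the grid centre) and averages
#' the SUV in a spherical ROI at the mirrored position — the "copy the ROI
#' to the same location in the contralateral lung" procedure.
#'
#' @param pet an SUV `image_volume`.
#' @param lesion_center_mm lesion centre in world mm.
#' @param roi_radius_mm background ROI radius (default 7.5 mm).
#' @param mirror_axis axis index of the left-right direction (default 1).
#' @param lesion_voi optional [bounding_box_voi()] of the lesion; if the
#'   mirrored ROI intersects it an error is raised (invalid background).
#' @return object of class `background_estimate`: list with `bg_mean`,
#'   `roi_center_mm`, `roi_radius_mm`.
#' @export
measure_background <- function(pet, lesion_center_mm, roi_radius_mm = 7.5,
                               mirror_axis = 1L, lesion_voi = NULL) {
  ext <- extent_mm(pet)
  center <- as.numeric(lesion_center_mm)
  center[mirror_axis] <- ext[mirror_axis] - center[mirror_axis]
  if (any(center - roi_radius_mm < 0) || any(center + roi_radius_mm > ext))
    stop("mirrored background ROI falls outside the image grid")
  if (!is.null(lesion_voi)) {
    overlaps <- all(center + roi_radius_mm > lesion_voi$min_corner_mm) &&
      all(center - roi_radius_mm < lesion_voi$max_corner_mm)
    if (overlaps)
      stop("mirrored background ROI overlaps the lesion VOI; background is invalid")
  }
  roi <- sphere_mask(pet, center, roi_radius_mm)
  if (!any(roi)) stop("background ROI contains no voxels")
  structure(list(bg_mean = mean(pet$data[roi]), roi_center_mm = center,
                 roi_radius_mm = roi_radius_mm),
            class = "background_estimate")
}

#' Background-adaptive 40% threshold segmentation (AT40%)
#'
#' Adapts the threshold to the contrast between the lesion and the mean
#' background SUV: `T = BG + 0.40 * (SUVmax - BG)`. This is the only
#' method of the four that uses background information, which makes it
#' robust when lesion uptake is low and barely above lung background.
#'
#' @inheritParams segment_t42
#' @param bg a [measure_background()] result (or any list with `bg_mean`).
#' @return a `segmentation_result` (`method = "AT40"`).
#' @export
segment_at40 <- function(pet, voi, bg) {
  bg_mean <- if (is.list(bg)) bg$bg_mean else bg
  if (!is.finite(bg_mean) || bg_mean < 0) stop("invalid background mean")
  ix <- voi_to_index(voi, pet)
  suv_max <- max(crop_to(pet, ix))
  if (suv_max <= 0) stop("VOI contains no voxel with SUV > 0")
  if (bg_mean >= suv_max)
    stop("background mean is not below SUVmax; lesion indistinct from background")
  segment_fixed_threshold(pet, voi, bg_mean + 0.40 * (suv_max - bg_mean),
                          "AT40")
}

#' Total lesion glycolysis
#'
#' `TLG = MTV x SUVmean`, in SUV-weighted cubic millimetres.
#' @param result a `segmentation_result`.
#' @return scalar TLG.
#' @export
tlg <- function(result) {
  stopifnot(inherits(result, "segmentation_result"))
  result$mtv_mm3 * result$suv_mean
}
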