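#' Measure a recovery coefficient from a hot-sphere phantom
#'
#' Applies the threshold-isocontour technique to one sphere of a
#' calibration phantom: the hot ROI is the connected set of voxels at or
#' above `isocontour_fraction` of the sphere's local maximum, the
#' background is the pooled mean over the phantom's background reference
#' ROIs, and the recovery coefficient is the measured hot-to-background
#' ratio divided by the true activity ratio,
#' `RC = (C_hot / C_bg) / (a_hot / a_bg)`.
#'
#' @param phantom a [generate_calibration_phantom()] result.
#' @param diameter_mm diameter of the sphere to measure (must match one of
#'   the phantom's spheres).
#' @param isocontour_fraction isocontour level as a fraction of the sphere
#'   maximum, in (0, 1). The 0.7 default keeps the isocontour at or above
#'   the level of the true sphere boundary (which sits at
#'   `(1 + (c-1)/2)/c` of the maximum for contrast `c`, 0.56 at 8:1), so
#'   the hot ROI does not swallow the blurred outside-the-sphere skirt and
#'   the recovery coefficient approaches 1 for spheres much larger than
#'   the PSF.
#' @param bg_roi_centers_mm optional override of the background ROI centres
#'   (list of length-3 vectors); each ROI must stay clear of every sphere.
#' @return object of class `rc_measurement`: list with `diameter_mm`,
#'   `c_hot`, `c_bg`, `true_ratio`, `rc`.
#' @export
measure_recovery <- function(phantom, diameter_mm, isocontour_fraction = 0.7,
                             bg_roi_centers_mm = NULL) {
  stopifnot(inherits(phantom, "calibration_phantom"))
  if (isocontour_fraction <= 0 || isocontour_fraction >= 1)
    stop("'isocontour_fraction' must be in (0, 1)")
  i <- which(abs(phantom$sphere_diameters_mm - diameter_mm) < 1e-6)
  if (length(i) != 1L)
    stop("no sphere with diameter ", diameter_mm, " mm in the phantom")
  pet <- phantom$pet
  center <- phantom$true_centers_mm[[i]]
  r <- diameter_mm / 2
  fwhm <- phantom$grid$psf_fwhm_mm

  # local search region around this sphere only, so the isocontour cannot
  # leak into a neighbouring sphere
  local <- sphere_mask(pet, center, r + max(2 * fwhm, 2 * max(pet$spacing_mm)))
  vals <- pet$data
  vals[!local] <- -Inf
  peak <- max(vals)
  thr <- isocontour_fraction * peak
  seed <- which.max(vals)
  roi <- connected_component(vals >= thr, seed)
  if (!any(roi)) stop("empty isocontour ROI")
  c_hot <- mean(pet$data[roi])

  if (is.null(bg_roi_centers_mm)) bg_roi_centers_mm <- phantom$bg_roi_centers_mm
  if (length(bg_roi_centers_mm) < 1L) stop("at least one background ROI needed")
  radii <- phantom$sphere_diameters_mm / 2
  bg_vox <- logical(length(pet$data))
  for (b in bg_roi_centers_mm) {
    for (j in seq_along(radii)) {
      gap <- sqrt(sum((b - phantom$true_centers_mm[[j]])^2)) -
        radii[j] - phantom$bg_roi_radius_mm
      if (gap < 2 * fwhm)
        stop("background ROI overlaps or abuts sphere ", j,
             "; background estimate would be contaminated")
    }
    bg_vox <- bg_vox | sphere_mask(pet, b, phantom$bg_roi_radius_mm)
  }
  c_bg <- mean(pet$data[bg_vox])
  if (!is.finite(c_bg) || c_bg <= 0) stop("background mean is not positive")

  structure(list(diameter_mm = as.numeric(diameter_mm), c_hot = c_hot,
                 c_bg = c_bg, true_ratio = phantom$contrast_ratio,
                 rc = (c_hot / c_bg) / phantom$contrast_ratio),
            class = "rc_measurement")
}

#' Build a diameter-indexed recovery-coefficient table
#'
#' @param measurements list of `rc_measurement` objects (or a data frame
#'   with columns `diameter_mm` and `rc`) at two or more distinct diameters.
#' @return object of class `rc_table`: a data frame of `diameter_mm`
#'   (strictly increasing) and `rc`.
#' @export
build_rc_table <- function(measurements) {
  if (is.data.frame(measurements)) {
    df <- measurements[, c("diameter_mm", "rc")]
  } else {
    df <- data.frame(
      diameter_mm = vapply(measurements, function(m) m$diameter_mm, 0),
      rc = vapply(measurements, function(m) m$rc, 0))
  }
  if (nrow(df) < 2L) stop("need at least 2 measurements")
  if (anyDuplicated(df$diameter_mm)) stop("duplicate diameters in RC table")
  df <- df[order(df$diameter_mm), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$rc <= 0)) stop("recovery coefficients must be positive")
  class(df) <- c("rc_table", "data.frame")
  df
}

#' Look up a recovery coefficient by lesion diameter
#'
#' Linear interpolation between tabulated diameters, clamped to the end
#' values outside the tabulated range and capped at 1. Lesions larger than
#' 30 mm are considered free of partial-volume loss: `RC = 1` exactly for
#' any diameter above 30 mm, regardless of the table.
#'
#' @param table an [build_rc_table()] result.
#' @param diameter_mm positive diameter(s) in mm (vectorised).
#' @return numeric recovery coefficient(s) in (0, 1].
#' @export
lookup_rc <- function(table, diameter_mm) {
  stopifnot(inherits(table, "rc_table"))
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0))
    stop("'diameter_mm' must be positive")
  rc <- stats::approx(table$diameter_mm, table$rc, xout = diameter_mm,
                      rule = 2)$y
  rc <- pmin(rc, 1)
  rc[diameter_mm > 30] <- 1
  rc
}

#' Write / read an RC table as CSV
#'
#' Plain two-column CSV (`diameter_mm,rc`).
#' @param table an `rc_table`.
#' @param path file path.
#' @return `write_rc_table` returns `path` invisibly; `read_rc_table`
#'   returns an `rc_table`.
#' @export
write_rc_table <- function(table, path) {
  stopifnot(inherits(table, "rc_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rc_table
#' @export
read_rc_table <- function(path) {
  build_rc_table(utils::read.csv(path))
}

#' Calibrate an RC table from a phantom in one call
#'
#' Measures every sphere of the phantom with [measure_recovery()] and
#' assembles the table.
#' @param phantom a `calibration_phantom`.
#' @param isocontour_fraction passed to [measure_recovery()].
#' @return an `rc_table`.
#' @export
calibrate_rc_table <- function(phantom, isocontour_fraction = 0.7) {
  ms <- lapply(phantom$sphere_diameters_mm, function(d)
    measure_recovery(phantom, d, isocontour_fraction))
  build_rc_table(ms)
}
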