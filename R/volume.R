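#' 3-D scalar image volume
#'
#' Lightweight container for a 3-D scalar grid (SUV, Hounsfield units, or a
#' binary mask) with anisotropic voxel spacing in millimetres. Voxel `i`
#' along an axis with spacing `s` covers the half-open interval
#' `[(i-1)*s, i*s)`, so its centre sits at `(i - 0.5) * s` and the grid
#' covers `[0, n*s]` in world (mm) coordinates.
#'
#' @param data numeric 3-D array.
#' @param spacing_mm positive numeric of length 1 or 3, voxel spacing in mm.
#' @param modality one of `"SUV"`, `"HU"`, `"mask"`.
#' @return An object of class `image_volume`: a list with elements `data`,
#'   `spacing_mm` (length 3) and `modality`.
#' @export
image_volume <- function(data, spacing_mm, modality = c("SUV", "HU", "mask")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3-D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive finite values")
  structure(list(data = data, spacing_mm = spacing_mm, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$modality, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Physical extent of a volume in mm
#' @param vol an `image_volume`.
#' @return numeric length 3, the world-space size of the grid per axis.
#' @export
extent_mm <- function(vol) dim(vol$data) * vol$spacing_mm

#' Voxel volume in cubic millimetres
#' @param vol an `image_volume`.
#' @return scalar, the product of the three spacings.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing_mm)

#' Voxel centre coordinates along one axis
#' @param n number of voxels.
#' @param spacing spacing in mm.
#' @return numeric vector of world coordinates of the voxel centres.
#' @keywords internal
axis_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# Squared distance of every voxel centre from a point, as a 3-D array.
# Built from per-axis vectors to avoid materialising coordinate grids.
dist2_from_point <- function(dims, spacing, point_mm) {
  dx2 <- (axis_centers(dims[1], spacing[1]) - point_mm[1])^2
  dy2 <- (axis_centers(dims[2], spacing[2]) - point_mm[2])^2
  dz2 <- (axis_centers(dims[3], spacing[3]) - point_mm[3])^2
  a <- array(dx2, dims)
  a <- a + rep(dy2, each = dims[1])
  a + rep(dz2, each = dims[1] * dims[2])
}

#' Logical mask of voxels whose centres fall inside a sphere
#' @param vol an `image_volume` (only geometry is used).
#' @param center_mm sphere centre, length 3, mm.
#' @param radius_mm sphere radius, mm.
#' @return logical array matching `dim(vol$data)`.
#' @export
sphere_mask <- function(vol, center_mm, radius_mm) {
  d2 <- dist2_from_point(dim(vol$data), vol$spacing_mm, center_mm)
  d2 <= radius_mm^2
}

# Shift a logical array by one voxel along an axis, padding with FALSE.
shift1 <- function(a, by, axis) {
  d <- dim(a)
  out <- array(FALSE, d)
  n <- d[axis]
  if (n <= 1L) return(out)
  src <- if (by > 0) 1:(n - 1) else 2:n
  dst <- if (by > 0) 2:n else 1:(n - 1)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ix_src <- ix; ix_src[[axis]] <- src
  ix_dst <- ix; ix_dst[[axis]] <- dst
  out[ix_dst[[1]], ix_dst[[2]], ix_dst[[3]]] <-
    a[ix_src[[1]], ix_src[[2]], ix_src[[3]]]
  out
}

# One 26-connected (3x3x3 box) binary dilation, as three separable passes.
dilate26 <- function(a) {
  for (axis in 1:3) a <- a | shift1(a, 1L, axis) | shift1(a, -1L, axis)
  a
}

#' Connected component of a binary mask containing a seed voxel
#'
#' Grows the 26-connected component containing `seed` by repeated
#' mask-restricted dilation (geodesic reconstruction).
#'
#' @param mask logical 3-D array.
#' @param seed linear index (or length-3 voxel index) of the seed voxel;
#'   must be `TRUE` in `mask`.
#' @return logical array of the same shape: the component containing `seed`.
#' @export
connected_component <- function(mask, seed) {
  if (!is.logical(mask)) mask <- mask > 0
  if (length(seed) == 3L) {
    seed <- seed[1] + (seed[2] - 1L) * dim(mask)[1] +
      (seed[3] - 1L) * dim(mask)[1] * dim(mask)[2]
  }
  if (!mask[seed]) stop("seed voxel is not inside the mask")
  region <- array(FALSE, dim(mask))
  region[seed] <- TRUE
  n_prev <- 1L
  repeat {
    region <- dilate26(region) & mask
    n <- sum(region)
    if (n == n_prev) break
    n_prev <- n
  }
  region
}

#' Largest 26-connected component of a binary mask
#' @param mask logical 3-D array with at least one `TRUE` voxel.
#' @return logical array: the component with the most voxels (ties broken by
#'   the first seed encountered in array order).
#' @export
largest_component <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stop("mask is empty")
  remaining <- mask
  best <- NULL
  best_n <- -1L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- connected_component(remaining, seed)
    n <- sum(comp)
    if (n > best_n) {
      best <- comp
      best_n <- n
    }
    remaining <- remaining & !comp
  }
  best
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
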