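# Independent oracles used across the test files. These deliberately avoid
# the package's own rendering / segmentation code paths.

# Closed-form radial profile of a uniform sphere (radius R, amplitude 1,
# background 0) convolved with an isotropic Gaussian of standard deviation
# sigma, evaluated at distance r from the centre.
blurred_sphere_profile <- function(r, R, sigma) {
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  out <- 0.5 * (erf((R - r) / (sigma * sqrt(2))) +
                  erf((R + r) / (sigma * sqrt(2)))) -
    sigma / (r * sqrt(2 * pi)) *
      (exp(-(R - r)^2 / (2 * sigma^2)) - exp(-(R + r)^2 / (2 * sigma^2)))
  center <- erf(R / (sigma * sqrt(2))) -
    R * sqrt(2 / pi) / sigma * exp(-R^2 / (2 * sigma^2))
  ifelse(r < 1e-9, center, out)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Queue-based breadth-first flood fill: the 26-connected component of
# `mask` containing linear index `seed`. Plain-loop reference
# implementation, independent of the package's dilation-based one.
bfs_component <- function(mask, seed) {
  d <- dim(mask)
  visited <- array(FALSE, d)
  if (!mask[seed]) stop("seed not in mask")
  queue <- integer(length(mask))
  queue[1] <- seed
  head <- 1L; tail <- 1L
  visited[seed] <- TRUE
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    k <- (v - 1L) %/% (d[1] * d[2])
    rem <- (v - 1L) %% (d[1] * d[2])
    j <- rem %/% d[1]
    i <- rem %% d[1]
    for (o in seq_len(nrow(offs))) {
      ni <- i + offs[o, 1]; nj <- j + offs[o, 2]; nk <- k + offs[o, 3]
      if (ni < 0 || nj < 0 || nk < 0 ||
          ni >= d[1] || nj >= d[2] || nk >= d[3]) next
      nv <- 1L + ni + nj * d[1] + nk * d[1] * d[2]
      if (mask[nv] && !visited[nv]) {
        visited[nv] <- TRUE
        tail <- tail + 1L
        queue[tail] <- nv
      }
    }
  }
  visited
}

# Exhaustive fixed-threshold segmentation oracle: per-voxel scan inside the
# VOI index bounds plus BFS connected component around the SUVmax voxel.
oracle_fixed_threshold_mask <- function(pet_data, lo, hi, threshold) {
  sub <- pet_data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  above <- array(FALSE, dim(sub))
  for (v in seq_along(sub)) above[v] <- sub[v] >= threshold
  comp <- bfs_component(above, which.max(sub))
  full <- array(FALSE, dim(pet_data))
  full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- comp
  full
}

# Brute-force fixed points of the adaptive iterative map over the finite
# set of candidate thresholds (the distinct voxel values in the VOI): a
# region R(t) is a fixed point when the threshold it generates selects R(t)
# again.
oracle_aia_fixed_points <- function(sub, weight = 0.5, frac = 0.42) {
  suv_max <- max(sub)
  seed <- which.max(sub)
  cands <- sort(unique(as.vector(sub)))
  fixed <- list()
  for (t in cands) {
    region <- bfs_component(sub >= t, seed)
    t_new <- frac * (weight * suv_max + (1 - weight) * mean(sub[region]))
    region_new <- bfs_component(sub >= t_new, seed)
    if (identical(region_new, region))
      fixed[[length(fixed) + 1]] <- list(threshold = t_new, region = region)
  }
  fixed
}

# Small deterministic random SUV volume with a warm blob on background, so
# thresholds produce nontrivial connected structure.
random_suv_volume <- function(seed, dims = c(32L, 32L, 32L), spacing = 2) {
  set.seed(seed)
  a <- array(runif(prod(dims), 0.2, 1), dims)
  ctr <- runif(3, 0.35, 0.65) * dims * spacing
  d2 <- array(0, dims)
  for (ax in 1:3) {
    x <- ((seq_len(dims[ax]) - 0.5) * spacing - ctr[ax])^2
    d2 <- d2 + array(rep(x, each = prod(dims[seq_len(ax - 1)])), dims)
  }
  a <- a + 4 * exp(-d2 / (2 * 8^2))
  image_volume(a, spacing, "SUV")
}
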