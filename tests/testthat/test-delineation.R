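# A small noiseless blurred solid lesion reused across tests.
blurred_case <- generate_lesion_phantom(
  lesion_spec("solid", 22, 5, 0.5, center_mm = c(32.7, 39.24, 39.24)),
  default_cohort_grid(), noise_sd = 0, seed = 2)
blurred_voi <- lesion_voi(blurred_case)

test_that("T42 on a uniform lesion delineates exactly the lesion voxels", {
  g <- grid_params(c(16, 16, 16), 3.27, psf_fwhm_mm = 0)
  case <- generate_lesion_phantom(lesion_spec("solid", 20, 10, 0), g, 0, 1)
  res <- segment_t42(case$pet, lesion_voi(case))
  expect_equal(res$threshold_suv, 4.2)
  expect_identical(res$mask, case$pet$data == 10)
  expect_equal(res$suv_mean, 10)
  expect_equal(res$mtv_mm3, sum(case$pet$data == 10) * 3.27^3)
  expect_equal(tlg(res), res$mtv_mm3 * 10)
})

test_that("fixed-threshold masks match the exhaustive per-voxel + BFS oracle", {
  tab <- build_rc_table(data.frame(diameter_mm = c(10, 30), rc = c(0.6, 0.95)))
  for (seed in 1:6) {
    pet <- random_suv_volume(seed)
    ext <- extent_mm(pet)
    voi <- bounding_box_voi(0.15 * ext, 0.85 * ext)
    ix <- petmtv:::voi_to_index(voi, pet)
    sub <- pet$data[ix$lo[1]:ix$hi[1], ix$lo[2]:ix$hi[2], ix$lo[3]:ix$hi[3]]
    suv_max <- max(sub)

    r1 <- segment_t42(pet, voi)
    expect_identical(r1$mask,
                     oracle_fixed_threshold_mask(pet$data, ix$lo, ix$hi,
                                                 0.42 * suv_max))
    d <- 15 + seed
    r2 <- segment_t42_rc(pet, voi, tab, d)
    expect_identical(r2$mask,
                     oracle_fixed_threshold_mask(pet$data, ix$lo, ix$hi,
                                                 0.42 * lookup_rc(tab, d) * suv_max))
    bg <- 0.3
    r3 <- segment_at40(pet, voi, list(bg_mean = bg))
    expect_identical(r3$mask,
                     oracle_fixed_threshold_mask(pet$data, ix$lo, ix$hi,
                                                 bg + 0.4 * (suv_max - bg)))
  }
})

test_that("lower thresholds give supersets and never smaller volumes", {
  tab <- build_rc_table(data.frame(diameter_mm = c(10, 30), rc = c(0.5, 0.9)))
  r_t42 <- segment_t42(blurred_case$pet, blurred_voi)
  r_rc <- segment_t42_rc(blurred_case$pet, blurred_voi, tab, 22)
  expect_lt(r_rc$threshold_suv, r_t42$threshold_suv)
  expect_true(all(r_rc$mask[r_t42$mask]))     # containment chain
  expect_gte(r_rc$mtv_mm3, r_t42$mtv_mm3)
  # monotonicity across a threshold sweep
  ix <- petmtv:::voi_to_index(blurred_voi, blurred_case$pet)
  vols <- vapply(seq(0.8, 4, by = 0.4), function(t) {
    petmtv:::segment_fixed_threshold(blurred_case$pet, blurred_voi, t, "T42")$mtv_mm3
  }, 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("T42xRC is bit-identical to T42 above the 30 mm RC cut", {
  tab <- build_rc_table(data.frame(diameter_mm = c(10, 30), rc = c(0.5, 0.9)))
  r_t42 <- segment_t42(blurred_case$pet, blurred_voi)
  r_rc <- segment_t42_rc(blurred_case$pet, blurred_voi, tab, 35)
  expect_identical(r_rc$mask, r_t42$mask)
  expect_identical(r_rc$threshold_suv, r_t42$threshold_suv)
})

test_that("masked voxels always sit at or above the reported threshold", {
  res <- list(segment_t42(blurred_case$pet, blurred_voi),
              segment_aia(blurred_case$pet, blurred_voi),
              segment_at40(blurred_case$pet, blurred_voi,
                           list(bg_mean = 0.5)))
  for (r in res) {
    expect_true(all(blurred_case$pet$data[r$mask] >= r$threshold_suv))
    expect_equal(r$mtv_mm3, sum(r$mask) * prod(blurred_case$pet$spacing_mm))
    expect_equal(r$suv_mean, mean(blurred_case$pet$data[r$mask]))
  }
})

test_that("adaptive iteration reaches a fixed point on a uniform lesion", {
  g <- grid_params(c(16, 16, 16), 3.27, psf_fwhm_mm = 0)
  case <- generate_lesion_phantom(lesion_spec("solid", 20, 10, 0), g, 0, 1)
  res <- segment_aia(case$pet, lesion_voi(case))
  expect_true(res$converged)
  expect_lte(res$iterations, 3)
  # homogeneous region: blended reference equals SUVmax, threshold 42% of it
  expect_equal(res$threshold_suv, 4.2, tolerance = 1e-9)
  expect_identical(res$mask, case$pet$data == 10)
})

test_that("adaptive iteration equals the brute-force fixed-point search", {
  # two-level lesion: hot core inside a warm rim
  pet <- image_volume(array(0, c(20, 20, 20)), 2, "SUV")
  ctr <- c(20, 20, 20)
  rim <- sphere_mask(pet, ctr, 14)
  core <- sphere_mask(pet, ctr, 7)
  pet$data[rim] <- 4
  pet$data[core] <- 10
  voi <- bounding_box_voi(c(2, 2, 2), c(38, 38, 38))
  res <- segment_aia(pet, voi)
  expect_true(res$converged)

  ix <- petmtv:::voi_to_index(voi, pet)
  sub <- pet$data[ix$lo[1]:ix$hi[1], ix$lo[2]:ix$hi[2], ix$lo[3]:ix$hi[3]]
  fixed <- oracle_aia_fixed_points(sub)
  expect_gte(length(fixed), 1)
  match_any <- any(vapply(fixed, function(fp) {
    full <- array(FALSE, dim(pet$data))
    full[ix$lo[1]:ix$hi[1], ix$lo[2]:ix$hi[2], ix$lo[3]:ix$hi[3]] <- fp$region
    isTRUE(all.equal(fp$threshold, res$threshold_suv)) &&
      identical(full, res$mask)
  }, TRUE))
  expect_true(match_any)
})

test_that("adaptive iteration converges quickly on blurred noisy phantoms", {
  g <- grid_params(c(16, 16, 16), 3.27, psf_fwhm_mm = 4.5)
  set.seed(7)
  params <- data.frame(d = runif(25, 9, 26), act = runif(25, 1.5, 8))
  for (i in seq_len(25)) {
    case <- generate_lesion_phantom(
      lesion_spec("solid", params$d[i], params$act[i], 0.5), g,
      noise_sd = 0.05, seed = 1000 + i)
    res <- segment_aia(case$pet, lesion_voi(case, margin_mm = 6))
    expect_true(res$converged)
    expect_lt(res$iterations, 50)
    # fixed-point residual of the returned state
    resid <- abs(res$threshold_suv -
                   0.42 * (0.5 * res$suv_max + 0.5 * res$suv_mean))
    expect_lt(resid, 0.01 * res$suv_max)
  }
})

test_that("background is read from the mirrored contralateral position", {
  pet <- blurred_case$pet
  bg <- measure_background(pet, blurred_case$spec$center_mm,
                           lesion_voi = blurred_voi)
  ext <- extent_mm(pet)
  expect_equal(bg$roi_center_mm[1],
               ext[1] - blurred_case$spec$center_mm[1])
  expect_equal(bg$bg_mean, 0.5, tolerance = 0.01)
  # smoothness under small ROI jitter on a noiseless phantom
  bg_j <- measure_background(pet, blurred_case$spec$center_mm + c(2, -2, 1),
                             lesion_voi = blurred_voi)
  expect_lt(abs(bg_j$bg_mean - bg$bg_mean) / bg$bg_mean, 0.01)
  # mirrored ROI intersecting the lesion VOI is an invalid background
  center_mid <- ext / 2 + c(1, 0, 0)
  expect_error(measure_background(pet, center_mid,
                                  lesion_voi = bounding_box_voi(ext / 2 - 20,
                                                                ext / 2 + 20)),
               "overlaps")
  expect_error(measure_background(pet, c(1, 1, 1)), "outside")
})

test_that("AT40 threshold interpolates between background and SUVmax", {
  pet <- image_volume(array(0.5, c(10, 10, 10)), 3, "SUV")
  pet$data[5, 5, 5] <- 5
  voi <- bounding_box_voi(c(1, 1, 1), c(29, 29, 29))
  r <- segment_at40(pet, voi, list(bg_mean = 1))
  expect_equal(r$threshold_suv, 1 + 0.4 * (5 - 1))
  r0 <- segment_at40(pet, voi, list(bg_mean = 0))
  expect_equal(r0$threshold_suv, 2)
  expect_error(segment_at40(pet, voi, list(bg_mean = 6)), "indistinct")
})

test_that("degenerate VOIs are rejected", {
  pet <- image_volume(array(0, c(8, 8, 8)), 3, "SUV")
  expect_error(bounding_box_voi(c(5, 5, 5), c(5, 9, 9)), "strictly below")
  voi_out <- bounding_box_voi(c(40, 40, 40), c(50, 50, 50))
  expect_error(segment_t42(pet, voi_out), "intersect")
  voi_in <- bounding_box_voi(c(1, 1, 1), c(10, 10, 10))
  expect_error(segment_t42(pet, voi_in), "SUV > 0")
})
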