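test_that("unblurred solid sphere reproduces its analytic activity and volume", {
  g <- grid_params(shape = c(24, 24, 24), spacing_mm = 3.27, psf_fwhm_mm = 0)
  case <- generate_lesion_phantom(lesion_spec("solid", 30, 10, 0.5), g,
                                  noise_sd = 0, seed = 1)
  expect_identical(case$suv_max, 10)
  analytic <- 4 / 3 * pi * 15^3
  # truth volume is exact voxel arithmetic; digitization error only
  expect_equal(sum(case$truth_mask) * prod(case$ct$spacing_mm),
               case$truth_volume_mm3)
  expect_lt(abs(case$truth_volume_mm3 - analytic) / analytic, 0.03)
})

test_that("PSF blur reduces peak SUV of small lesions and matches the closed form", {
  # 1 mm grid so a voxel mean approximates the continuum profile value
  g <- grid_params(shape = c(48, 48, 48), spacing_mm = 1, psf_fwhm_mm = 4.5)
  case <- generate_lesion_phantom(lesion_spec("solid", 10, 10, 0.5), g,
                                  noise_sd = 0, seed = 1)
  expect_lt(case$suv_max, 10)
  sigma <- fwhm_to_sigma(4.5)
  expected_center <- 0.5 + 9.5 * blurred_sphere_profile(0, 5, sigma)
  expect_lt(abs(case$suv_max - expected_center) / expected_center, 0.02)
})

test_that("phantom generation is deterministic given the seed", {
  g <- grid_params(shape = c(16, 16, 16), spacing_mm = 3.27, psf_fwhm_mm = 4.5)
  sp <- lesion_spec("part_solid", 14, 3, 0.5)
  a <- generate_lesion_phantom(sp, g, noise_sd = 0.1, seed = 99)
  b <- generate_lesion_phantom(sp, g, noise_sd = 0.1, seed = 99)
  expect_identical(a$pet$data, b$pet$data)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$truth_mask, b$truth_mask)
  c2 <- generate_lesion_phantom(sp, g, noise_sd = 0.1, seed = 100)
  expect_false(identical(a$pet$data, c2$pet$data))
})

test_that("blur conserves total activity", {
  g0 <- grid_params(shape = c(24, 24, 24), spacing_mm = 3.27, psf_fwhm_mm = 0,
                    oversample = 4)
  g1 <- grid_params(shape = c(24, 24, 24), spacing_mm = 3.27, psf_fwhm_mm = 4.5)
  sp <- lesion_spec("solid", 16, 8, 0.5)
  tot0 <- sum(generate_lesion_phantom(sp, g0, 0, 1)$pet$data)
  tot1 <- sum(generate_lesion_phantom(sp, g1, 0, 1)$pet$data)
  expect_lt(abs(tot1 - tot0) / tot0, 0.001)
})

test_that("post-blur peak is non-decreasing in sphere diameter", {
  g <- grid_params(shape = c(24, 24, 24), spacing_mm = 3.27, psf_fwhm_mm = 4.5)
  peaks <- vapply(c(8, 12, 18, 26, 34), function(d) {
    generate_lesion_phantom(lesion_spec("solid", d, 6, 0.5), g, 0, 1)$suv_max
  }, 0)
  expect_true(all(diff(peaks) >= 0))
})

test_that("oversized or invalid lesions are rejected", {
  g <- grid_params(shape = c(16, 16, 16), spacing_mm = 3.27, psf_fwhm_mm = 4.5)
  expect_error(generate_lesion_phantom(lesion_spec("solid", 60, 5, 0.5), g),
               "does not fit")
  expect_error(lesion_spec("solid", -5, 5, 0.5), "positive")
  expect_error(lesion_spec("solid", 10, 0.4, 0.5), "exceed")
})

test_that("cohort generation honours counts, seed and the type-uptake link", {
  counts <- c(nonsolid = 6, part_solid = 8, solid = 20)
  cohort <- generate_cohort(counts, noise_sd = 0.05, seed = 11)
  types <- vapply(cohort, function(c) c$spec$nodule_type, "")
  expect_identical(as.integer(table(types)[names(counts)]),
                   as.integer(counts))
  cohort2 <- generate_cohort(counts, noise_sd = 0.05, seed = 11)
  expect_identical(cohort[[5]]$pet$data, cohort2[[5]]$pet$data)
  expect_length(generate_cohort(c(solid = 0)), 0)

  # type rank vs measured SUVmax association on a full-size cohort
  big <- generate_cohort(c(nonsolid = 16, part_solid = 30, solid = 87),
                         noise_sd = 0.05, seed = 1)
  rank <- match(vapply(big, function(c) c$spec$nodule_type, ""),
                c("nonsolid", "part_solid", "solid"))
  suv <- vapply(big, function(c) c$suv_max, 0)
  expect_gt(cor(rank, suv, method = "spearman"), 0.5)
})

test_that("part-solid lesions carry a dense core of the stated volume fraction", {
  g <- grid_params(shape = c(24, 24, 24), spacing_mm = 3.27, psf_fwhm_mm = 0)
  case <- generate_lesion_phantom(lesion_spec("part_solid", 24, 3, 0.5), g, 0, 1)
  f <- mean(case$ct$data[case$truth_mask] >= -300)
  expect_gt(f, 0.2)
  expect_lt(f, 0.4)
  ns <- generate_lesion_phantom(lesion_spec("nonsolid", 24, 1.5, 0.5), g, 0, 1)
  expect_true(all(ns$ct$data[ns$truth_mask] == -600))
})

test_that("calibration phantom renders spheres at the stated contrast", {
  ph0 <- generate_calibration_phantom(
    grid = grid_params(c(64, 64, 20), 3.27, psf_fwhm_mm = 0))
  expect_equal(max(ph0$pet$data), 8)
  # background mean ~1 far from the spheres
  corner <- ph0$pet$data[1:4, 1:4, 1:4]
  expect_equal(mean(corner), 1, tolerance = 1e-9)
  ph <- generate_calibration_phantom()
  peak_of <- function(p, d) {
    i <- which(p$sphere_diameters_mm == d)
    max(p$pet$data[sphere_mask(p$pet, p$true_centers_mm[[i]], d / 2 + 9)])
  }
  expect_lt(peak_of(ph, 10), peak_of(ph, 37))
  tall <- grid_params(c(64, 64, 40), 3.27, psf_fwhm_mm = 4.5)
  expect_error(generate_calibration_phantom(c(59, 59), grid = tall), "overlap")
  expect_error(generate_calibration_phantom(c(70, 10)), "fit")
})

test_that("phantom cases round-trip through NIfTI with spacing intact", {
  g <- grid_params(shape = c(12, 12, 12), spacing_mm = c(3, 3, 4),
                   psf_fwhm_mm = 0)
  case <- generate_lesion_phantom(lesion_spec("solid", 12, 5, 0.5), g, 0, 3)
  dir <- withr::local_tempdir()
  write_phantom_case(case, dir, "t")
  pet2 <- read_volume_nifti(file.path(dir, "t_pet.nii.gz"), "SUV")
  expect_equal(pet2$spacing_mm, c(3, 3, 4))
  expect_equal(pet2$data, case$pet$data, tolerance = 1e-6)
  mask2 <- read_volume_nifti(file.path(dir, "t_truth.nii.gz"), "mask")
  expect_identical(sum(mask2$data), sum(case$truth_mask))
})
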