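test_that("FWHM/sigma conversion matches the closed form", {
  expect_equal(fwhm_to_sigma(2), 0.84932, tolerance = 1e-4)
  expect_equal(fwhm_to_sigma(2.355), 1, tolerance = 1e-3)
})

test_that("Gaussian smoothing preserves constants, mass and shifts", {
  # constant interior stays constant
  v <- wmh_volume(array(10, dim = c(20, 20, 12)))
  sm <- smooth_gaussian(v, 2)
  expect_equal(max(abs(sm$data[6:15, 6:15, 5:8] - 10)), 0, tolerance = 1e-4)

  # a unit impulse keeps its mass and spreads out
  imp <- array(0, dim = c(21, 21, 13)); imp[11, 11, 7] <- 1
  smi <- smooth_gaussian(wmh_volume(imp), 2)
  expect_equal(sum(smi$data), 1, tolerance = 1e-3)
  expect_lt(max(smi$data), 1)
  expect_equal(which.max(smi$data),
               which.max(imp))

  # discrete shift-invariance: shifting by whole voxels commutes
  set.seed(4)
  arr <- array(0, dim = c(16, 16, 10))
  arr[5:12, 5:12, 4:7] <- rnorm(8 * 8 * 4, 100, 10)
  smoothed <- smooth_gaussian(wmh_volume(arr), 2)$data
  shifted <- array(0, dim = c(16, 16, 10))
  shifted[7:14, 5:12, 4:7] <- arr[5:12, 5:12, 4:7]
  smoothed_shifted <- smooth_gaussian(wmh_volume(shifted), 2)$data
  expect_equal(smoothed_shifted[7:14, 5:12, 4:7],
               smoothed[5:12, 5:12, 4:7], tolerance = 1e-10)

  # anisotropic spacing: sigma in voxels scales with spacing
  vz <- wmh_volume(array(10, dim = c(20, 20, 12)),
                   diag(c(1, 1, 5, 1)))
  expect_equal(max(abs(smooth_gaussian(vz, 2)$data[6:15, 6:15, 5:8] - 10)),
               0, tolerance = 1e-4)
  expect_error(smooth_gaussian(v, -1), "positive")
})

test_that("brain mask is the thresholded sum of tissue maps", {
  d <- c(10, 10, 6)
  ball <- array(0, dim = d); ball[3:8, 3:8, 2:5] <- 1
  # binary partition of the ball into three tissues
  gm <- wm <- csf <- array(0, dim = d)
  gm[3:4, 3:8, 2:5] <- 1
  wm[5:6, 3:8, 2:5] <- 1
  csf[7:8, 3:8, 2:5] <- 1
  tis <- tissue_maps(wmh_volume(gm), wmh_volume(wm), wmh_volume(csf))
  expect_identical(build_brain_mask(tis)$data, ball)

  # all-zero tissues warn and give an empty mask
  zero <- wmh_volume(array(0, dim = d))
  expect_warning(m0 <- build_brain_mask(tissue_maps(zero, zero, zero)),
                 "empty")
  expect_equal(sum(m0$data), 0)

  # probabilistic boundary voxel below threshold is excluded
  gm2 <- array(0, dim = d); gm2[5, 5, 3] <- 0.15
  wm2 <- array(0, dim = d); wm2[5, 5, 3] <- 0.15
  csf2 <- array(0, dim = d); csf2[5, 5, 3] <- 0.1
  csf2[6, 5, 3] <- 1
  tis2 <- tissue_maps(wmh_volume(gm2), wmh_volume(wm2), wmh_volume(csf2))
  m2 <- build_brain_mask(tis2, threshold = 0.5)
  expect_equal(m2$data[5, 5, 3], 0)  # sum 0.4 < 0.5
  expect_equal(m2$data[6, 5, 3], 1)

  # out-of-range values are clipped with a warning
  bad <- wmh_volume(array(1.2, dim = d))
  expect_warning(tissue_maps(bad, zero, zero), "clipping")
})

test_that("registration recovers a known translation on a phantom", {
  shift <- diag(4); shift[1:3, 4] <- c(4, -3, 2)
  ph <- generate_phantom(small_spec(true_flair_to_t1 = shift))
  tr <- suppressWarnings(
    register_affine(ph$flair, ph$t1,
                    preprocess_config(registration_dof = "rigid6")))
  expect_lt(max(abs(tr$matrix[1:3, 4] - c(4, -3, 2))), 0.5)
  expect_lt(max(abs(tr$matrix[1:3, 1:3] - diag(3))), 0.02)
  expect_lte(attr(tr, "cost"), attr(tr, "initial_cost"))
})

test_that("self-registration stays at identity", {
  ph <- generate_phantom(small_spec())
  tr <- suppressWarnings(register_affine(ph$t1, ph$t1, preprocess_config()))
  expect_lt(max(abs(tr$matrix[1:3, 4])), 0.1)        # < 0.1 mm
  expect_lt(max(abs(tr$matrix[1:3, 1:3] - diag(3))), 0.005)  # < 0.5% scale
})

test_that("registration rejects degenerate images", {
  flat <- wmh_volume(array(1, dim = c(8, 8, 4)))
  ph <- generate_phantom(small_spec())
  expect_error(register_affine(flat, ph$t1, preprocess_config()),
               "degenerate")
  expect_error(register_affine(ph$t1, flat, preprocess_config()),
               "degenerate")
})

test_that("preprocess pipeline output lives on the template grid", {
  ph <- generate_phantom(small_spec())
  pre <- suppressWarnings(
    preprocess_pipeline(ph$flair, ph$t1, ph$tissues, ph$template,
                        ph$exclusion_mask))
  expect_identical(grid_shape(pre$flair), grid_shape(ph$template))
  expect_equal(pre$flair$affine, ph$template$affine, tolerance = 1e-9)
  expect_identical(grid_shape(pre$mask), grid_shape(ph$template))

  # identity-geometry phantom: recovered transforms are near identity ...
  expect_lt(max(abs(pre$flair_to_t1$matrix - diag(4))), 0.5)
  expect_lt(max(abs(pre$t1_to_template$matrix - diag(4))), 0.5)

  # ... and the excluded block is removed from the output entirely
  excl <- ph$exclusion_mask$data == 1
  expect_equal(max(abs(pre$flair$data[excl])), 0)
  # and the pipeline segmentation agrees with plain mask-then-smooth
  keep <- apply_mask(ph$brain_mask, mask_complement(ph$exclusion_mask))
  direct <- threshold_segment(
    smooth_gaussian(apply_mask(ph$flair, keep), 2), keep, k = 1.5)
  piped <- threshold_segment(pre$flair, pre$mask, k = 1.5)
  expect_gt(dice(piped$lesion_map, direct$lesion_map), 0.9)

  # ground-truth lesion centroid lands within 1 voxel of its true place
  seg_idx <- which(piped$lesion_map$data == 1, arr.ind = TRUE)
  true_idx <- which(ph$ground_truth$data == 1, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(seg_idx) - colMeans(true_idx))), 1)
})

test_that("preprocess config validates its parameters", {
  expect_error(preprocess_config(fwhm_mm = 0), "positive")
  expect_error(preprocess_config(brain_mask_threshold = 0), "0, 1")
  expect_error(preprocess_config(registration_dof = "rigid7"))
})
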