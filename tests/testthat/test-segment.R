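test_that("brain intensity statistics match hand arithmetic", {
  vals <- c(2, 4, 4, 4, 5, 5, 7, 9)
  v <- wmh_volume(array(c(vals, rep(0, 42)), dim = c(10, 5, 1)))
  m <- mask_with_n_ones(8, dim = c(10, 5, 1))
  st <- brain_intensity_stats(v, m)
  expect_equal(st$mean, 5.0)
  expect_equal(st$sd, 2.1381, tolerance = 1e-4)
  expect_equal(st$n_voxels, 8L)

  # without a mask, strictly positive voxels are used: same result here
  st2 <- brain_intensity_stats(v)
  expect_equal(st2$mean, st$mean)
  expect_equal(st2$sd, st$sd)
  expect_equal(st2$n_voxels, st$n_voxels)

  # constant intensity: sd 0
  vc <- wmh_volume(array(c(rep(3, 10), rep(0, 40)), dim = c(10, 5, 1)))
  stc <- brain_intensity_stats(vc)
  expect_equal(stc$mean, 3)
  expect_equal(stc$sd, 0)

  # population-SD option
  stn <- brain_intensity_stats(v, m, sd_denominator = "n")
  expect_equal(stn$sd, st$sd * sqrt(7 / 8), tolerance = 1e-12)

  # fewer than 2 voxels errors
  v1 <- wmh_volume(array(c(5, rep(0, 7)), dim = c(2, 2, 2)))
  expect_error(brain_intensity_stats(v1), "degenerate")
})

test_that("intensity statistics are invariant under voxel permutation", {
  set.seed(5)
  vals <- rnorm(200, 100, 15)
  perm <- sample(200)
  v1 <- wmh_volume(array(vals, dim = c(10, 10, 2)))
  v2 <- wmh_volume(array(vals[perm], dim = c(10, 10, 2)))
  s1 <- brain_intensity_stats(v1)
  s2 <- brain_intensity_stats(v2)
  expect_equal(s1$mean, s2$mean)
  expect_equal(s1$sd, s2$sd)
})

test_that("threshold segmentation honours the mean + k*SD rule", {
  ph <- generate_phantom(small_spec())
  keep <- apply_mask(ph$brain_mask, mask_complement(ph$exclusion_mask))
  seg <- threshold_segment(ph$flair, keep, k = 1.5)

  # arithmetic identities hold exactly
  expect_identical(seg$threshold, seg$stats$mean + 1.5 * seg$stats$sd)
  expect_identical(seg$n_lesion_voxels, as.integer(sum(seg$lesion_map$data)))
  expect_equal(seg$volume_cm3,
               seg$n_lesion_voxels * voxel_volume_mm3(ph$flair) / 1000)

  # the lesion map is exactly the voxelwise comparison with the threshold
  expected <- keep$data == 1 & ph$flair$data >= seg$threshold
  expect_identical(seg$lesion_map$data == 1, expected)

  # ground-truth lesion voxels well above threshold are all captured;
  # pure-WM voxels well below it are not
  margin <- 3 * ph$spec$noise_sd
  deep_lesion <- ph$ground_truth$data == 1 &
    ph$flair$data >= seg$threshold + margin
  expect_true(all(seg$lesion_map$data[deep_lesion] == 1))

  # unreachable threshold -> empty map, zero volume
  seg_hi <- threshold_segment(ph$flair, keep, k = 1000)
  expect_equal(seg_hi$n_lesion_voxels, 0L)
  expect_equal(seg_hi$volume_cm3, 0)
  expect_equal(lesion_volume_cm3(seg_hi$lesion_map), 0)
})

test_that("thresholding is monotone in k", {
  ph <- generate_phantom(small_spec())
  keep <- apply_mask(ph$brain_mask, mask_complement(ph$exclusion_mask))
  n <- vapply(c(1.0, 1.5, 2.0), function(k)
    threshold_segment(ph$flair, keep, k = k)$n_lesion_voxels, 0L)
  expect_true(all(diff(n) <= 0))
})

test_that("edit masks merge with removal precedence", {
  ph <- generate_phantom(small_spec(noise_sd = 0))
  keep <- apply_mask(ph$brain_mask, mask_complement(ph$exclusion_mask))
  seg <- threshold_segment(ph$flair, keep, k = 1.5)
  d <- grid_shape(ph$flair)
  aff <- ph$flair$affine

  # no edits: unchanged
  same <- apply_edits(seg)
  expect_identical(same$lesion_map$data, seg$lesion_map$data)
  expect_identical(same$threshold, seg$threshold)

  # disjoint additions increase the count by exactly their size
  add <- array(0, dim = d)
  free <- which(seg$lesion_map$data == 0)[1:50]
  add[free] <- 1
  grown <- apply_edits(seg, additions = wmh_mask(add, aff))
  expect_equal(grown$n_lesion_voxels, seg$n_lesion_voxels + 50L)
  expect_equal(grown$edits$added, 50L)
  expect_identical(grown$threshold, seg$threshold)  # provenance carried

  # a voxel in both additions and removals is absent from the result
  both <- array(0, dim = d)
  both[free[1]] <- 1
  out <- apply_edits(seg, additions = wmh_mask(both, aff),
                     removals = wmh_mask(both, aff))
  expect_equal(out$lesion_map$data[free[1]], 0)

  # removals delete in-map voxels and are counted
  rem <- array(0, dim = d)
  inmap <- which(seg$lesion_map$data == 1)[1:20]
  rem[inmap] <- 1
  shrunk <- apply_edits(seg, removals = wmh_mask(rem, aff))
  expect_equal(shrunk$n_lesion_voxels, seg$n_lesion_voxels - 20L)
  expect_equal(shrunk$edits$removed, 20L)

  # volume identity still holds after edits
  expect_equal(shrunk$volume_cm3,
               shrunk$n_lesion_voxels * voxel_volume_mm3(ph$flair) / 1000)

  # grid mismatch errors
  expect_error(apply_edits(seg, additions = wmh_mask(array(0, c(2, 2, 2)))),
               "mismatch")
})

test_that("lesion volume converts voxel counts to cm^3", {
  d <- c(10, 10, 10)
  m <- wmh_mask(array(1, dim = d))        # 1000 voxels at 1 mm iso
  expect_equal(lesion_volume_cm3(m), 1.0)
  empty <- wmh_mask(array(0, dim = d))
  expect_equal(lesion_volume_cm3(empty), 0.0)
  # 3490 voxels at 1 mm iso -> 3.49 cm^3 (a realistic per-subject load)
  m2 <- mask_with_n_ones(3490, dim = c(20, 20, 10))
  expect_equal(lesion_volume_cm3(m2), 3.49)
})

test_that("segmentation report serialises every field", {
  ph <- generate_phantom(small_spec())
  keep <- apply_mask(ph$brain_mask, mask_complement(ph$exclusion_mask))
  seg <- threshold_segment(ph$flair, keep, k = 1.5)
  js <- jsonlite::fromJSON(segmentation_report_json(seg))
  expect_equal(js$threshold, seg$threshold)
  expect_equal(js$n_lesion_voxels, seg$n_lesion_voxels)
  expect_equal(js$volume_cm3, seg$volume_cm3)
  expect_equal(js$k, 1.5)
})
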