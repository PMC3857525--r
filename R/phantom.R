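#' Specification of a synthetic brain phantom
#'
#' Describes a concentric-ellipsoid brain (CSF ventricles inside a WM core
#' inside a GM shell), an optional inferior "cerebellum/brainstem" block, and
#' ellipsoidal hyperintense lesions stamped into the WM, on a regular voxel
#' grid. Anatomy scales with the grid so that smaller phantoms remain valid;
#' lesions are given explicitly in world mm so their ground-truth voxel
#' counts are exactly constructible.
#'
#' @param grid_shape Integer triple, default `c(96, 96, 60)`.
#' @param spacing_mm Voxel spacing per axis in mm, default 1 mm isotropic.
#' @param tissue_means Named FLAIR intensities (arbitrary units) for `csf`,
#'   `gm`, `wm`, `lesion`; defaults 30, 90, 100, 160.
#' @param t1_means Named T1 intensities for `csf`, `gm`, `wm`; defaults
#'   30, 70, 110 (lesions take the WM value on T1).
#' @param noise_sd SD of the independent Gaussian noise added to FLAIR and
#'   T1 inside the brain; default 5 (5% of the WM mean).
#' @param lesions List of lesions, each `list(center_mm =, radii_mm =,
#'   intensity =)` (`intensity` optional, defaulting to
#'   `tissue_means["lesion"]`). `NULL` selects a default set of three
#'   lesions: two confluent periventricular caps and one deep WM lesion, ~6.3 cm^3
#'   in total on the default grid.
#' @param include_cerebellum_block Add the inferior block flagged by the
#'   exclusion mask; default `TRUE`.
#' @param true_flair_to_t1 A [affine_transform] giving the true FLAIR-world
#'   to T1-world mapping; the FLAIR is synthesised already displaced by its
#'   inverse, so registration should recover this transform. Identity by
#'   default.
#' @param seed Integer seed making the phantom deterministic.
#' @return An object of class `wmh_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 60L),
                         spacing_mm = c(1, 1, 1),
                         tissue_means = c(csf = 30, gm = 90, wm = 100,
                                          lesion = 160),
                         t1_means = c(csf = 30, gm = 70, wm = 110),
                         noise_sd = 5,
                         lesions = NULL,
                         include_cerebellum_block = TRUE,
                         true_flair_to_t1 = affine_transform(),
                         seed = 42L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            length(spacing_mm) == 3L, all(spacing_mm > 0),
            noise_sd >= 0)
  if (tissue_means[["lesion"]] <= tissue_means[["wm"]])
    stop("lesion intensity must exceed the WM mean (hyperintense by ",
         "construction)", call. = FALSE)
  extent <- grid_shape * spacing_mm
  if (is.null(lesions)) {
    # two confluent periventricular caps (anterior and posterior horns) and
    # one small deep WM lesion -- the typical moderate-to-high-load pattern
    # of the cohorts this method targets; ~6.3 cm^3 total on the default
    # grid (~5% of the phantom brain)
    les_frac <- list(
      list(center = c(0.5, 0.7083, 0.60),
           radii = c(0.1354, 0.0729, 0.1333)),
      list(center = c(0.5, 0.2917, 0.60),
           radii = c(0.1354, 0.0729, 0.1333)),
      list(center = c(0.7083, 0.5625, 0.6167),
           radii = c(0.0417, 0.0417, 0.0667)))
    lesions <- lapply(les_frac, function(l)
      list(center_mm = l$center * extent, radii_mm = l$radii * extent,
           intensity = NULL))
  }
  if (!inherits(true_flair_to_t1, "wmh_affine"))
    true_flair_to_t1 <- affine_transform(true_flair_to_t1)
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 tissue_means = tissue_means, t1_means = t1_means,
                 noise_sd = noise_sd, lesions = lesions,
                 include_cerebellum_block = include_cerebellum_block,
                 true_flair_to_t1 = true_flair_to_t1,
                 seed = as.integer(seed)),
            class = "wmh_phantom_spec")
}

# brain geometry in fractions of the field of view; the outermost shell of
# the cerebrum is sulcal CSF so that the brain mask (GM+WM+CSF) has the
# realistic ~15% CSF fraction that shapes the FLAIR intensity histogram
.phantom_geometry <- list(
  cerebrum = list(center = c(0.5, 0.5, 0.60),
                  semi = c(0.375, 0.4167, 0.3667)),
  gm_scale = 0.96,   # outside this (up to 1): sulcal CSF rim
  wm_scale = 0.78,   # inside this: WM core
  ventricles = list(
    list(center = c(0.4063, 0.5, 0.60), semi = c(0.0625, 0.146, 0.1)),
    list(center = c(0.5938, 0.5, 0.60), semi = c(0.0625, 0.146, 0.1))),
  cerebellum = list(center = c(0.5, 0.4167, 0.1333),
                    semi = c(0.1875, 0.1458, 0.1333)))

#' Generate a synthetic brain phantom
#'
#' Builds the full input set of the pipeline from a [phantom_spec()]:
#' FLAIR and T1 volumes (Gaussian noise inside the brain), noise-free
#' ground-truth tissue maps, brain mask, cerebellum/brainstem exclusion
#' mask, a template (the noise-free T1), and the ground-truth lesion mask.
#' Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `wmh_phantom`: `flair`, `t1`, `tissues`,
#'   `brain_mask`, `exclusion_mask`, `template`, `ground_truth`, `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "wmh_phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing_mm
  affine <- diag(c(sp, 1))
  extent <- d * sp

  X <- slice_index(d, 1) * sp[1]
  Y <- slice_index(d, 2) * sp[2]
  Z <- slice_index(d, 3) * sp[3]
  inside <- function(center, semi) {
    ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
      ((Z - center[3]) / semi[3])^2 <= 1
  }
  g <- .phantom_geometry
  cerebrum <- inside(g$cerebrum$center * extent, g$cerebrum$semi * extent)
  gm_outer <- inside(g$cerebrum$center * extent,
                     g$cerebrum$semi * extent * g$gm_scale)
  wm_core <- inside(g$cerebrum$center * extent,
                    g$cerebrum$semi * extent * g$wm_scale)
  vent <- Reduce(`|`, lapply(g$ventricles, function(v)
    inside(v$center * extent, v$semi * extent)))
  vent <- vent & cerebrum
  wm <- wm_core & !vent
  gm <- gm_outer & !wm_core
  csf_rim <- cerebrum & !gm_outer
  vent <- vent | csf_rim
  cereb <- if (spec$include_cerebellum_block)
    inside(g$cerebellum$center * extent, g$cerebellum$semi * extent) &
      !cerebrum
  else
    array(FALSE, dim = d)

  lesion <- array(FALSE, dim = d)
  for (i in seq_along(spec$lesions)) {
    l <- spec$lesions[[i]]
    li <- inside(l$center_mm, l$radii_mm)
    if (any(li & !wm))
      stop("lesion ", i, " extends outside the WM compartment (",
           sum(li & !wm), " voxels)", call. = FALSE)
    lesion <- lesion | li
  }

  tm <- spec$tissue_means
  flair_clean <- array(0, dim = d)
  flair_clean[gm | cereb] <- tm[["gm"]]
  flair_clean[wm] <- tm[["wm"]]
  flair_clean[vent] <- tm[["csf"]]
  for (l in spec$lesions) {
    li <- inside(l$center_mm, l$radii_mm)
    flair_clean[li] <- if (is.null(l$intensity)) tm[["lesion"]] else
      l$intensity
  }
  t1m <- spec$t1_means
  t1_clean <- array(0, dim = d)
  t1_clean[gm | cereb] <- t1m[["gm"]]
  t1_clean[wm] <- t1m[["wm"]]
  t1_clean[vent] <- t1m[["csf"]]

  # smooth anatomy-locked intensity texture (~6% peak to peak): real tissue
  # intensity varies with position, and because this modulation travels
  # with the anatomy it is what makes rotations identifiable to
  # intensity-based registration, unlike the iid scanner noise added below
  tex <- 1 + 0.02 * (sin(2 * pi * X / 17 + 0.7) +
                     sin(2 * pi * Y / 15 + 1.3) +
                     sin(2 * pi * Z / 13 + 2.1))
  flair_clean <- flair_clean * tex
  t1_clean <- t1_clean * tex

  brain <- cerebrum | cereb

  # displace the FLAIR by the inverse of the true transform so that
  # registering it back to the T1 recovers the transform
  Tm <- spec$true_flair_to_t1$matrix
  if (max(abs(Tm - diag(4))) > 0) {
    ideal <- wmh_volume(flair_clean, affine)
    target <- wmh_volume(array(0, dim = d), affine)
    flair_clean <- resample(ideal, affine_transform(solve(Tm)), target,
                            "trilinear")$data
    flair_support <- flair_clean > 0
  } else {
    flair_support <- brain
  }

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  flair <- flair_clean
  flair[flair_support] <- flair[flair_support] +
    stats::rnorm(sum(flair_support), 0, spec$noise_sd)
  t1 <- t1_clean
  t1[brain] <- t1[brain] + stats::rnorm(sum(brain), 0, spec$noise_sd)

  as_arr <- function(m) array(as.double(m), dim = d)
  tissues <- tissue_maps(gm = wmh_volume(as_arr(gm | cereb), affine),
                         wm = wmh_volume(as_arr(wm), affine),
                         csf = wmh_volume(as_arr(vent), affine))
  structure(list(
    flair = wmh_volume(flair, affine),
    t1 = wmh_volume(t1, affine),
    tissues = tissues,
    brain_mask = wmh_mask(as_arr(brain), affine),
    exclusion_mask = wmh_mask(as_arr(cereb), affine),
    template = wmh_volume(t1_clean, affine),
    ground_truth = wmh_mask(as_arr(lesion), affine),
    spec = spec), class = "wmh_phantom")
}

#' @export
print.wmh_phantom <- function(x, ...) {
  cat("<wmh_phantom>\n")
  cat(sprintf("  grid %s, voxel %.3g mm^3, noise SD %.3g\n",
              paste(grid_shape(x$flair), collapse = " x "),
              voxel_volume_mm3(x$flair), x$spec$noise_sd))
  cat(sprintf("  brain %d voxels, lesions %d voxels (%.3g cm^3)\n",
              as.integer(sum(x$brain_mask$data)),
              as.integer(sum(x$ground_truth$data)),
              lesion_volume_cm3(x$ground_truth)))
  invisible(x)
}

#' Score a segmentation against phantom ground truth
#'
#' @param seg A [wmh_mask] on the phantom's grid (e.g. a lesion map).
#' @param bundle A `wmh_phantom` from [generate_phantom()].
#' @return List with `dsc`, `volume_error_cm3` (segmented minus true),
#'   `false_positive_voxels`, `false_negative_voxels`.
#' @export
score_against_truth <- function(seg, bundle) {
  stopifnot(inherits(seg, "wmh_mask"), inherits(bundle, "wmh_phantom"))
  truth <- bundle$ground_truth
  check_same_grid(seg, truth)
  list(dsc = dice(seg, truth),
       volume_error_cm3 = lesion_volume_cm3(seg) - lesion_volume_cm3(truth),
       false_positive_voxels = as.integer(sum(seg$data == 1 &
                                                truth$data == 0)),
       false_negative_voxels = as.integer(sum(seg$data == 0 &
                                                truth$data == 1)))
}

#' Write a phantom bundle to disk as NIfTI files
#'
#' Writes every image of the bundle plus a JSON manifest of ground-truth
#' counts.
#'
#' @param bundle A `wmh_phantom`.
#' @param dir Output directory (created if missing).
#' @return Named vector of file paths, invisibly.
#' @export
write_phantom <- function(bundle, dir) {
  stopifnot(inherits(bundle, "wmh_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(flair = "flair.nii.gz", t1 = "t1.nii.gz",
             brain_mask = "brain_mask.nii.gz",
             exclusion_mask = "exclusion_mask.nii.gz",
             template = "template.nii.gz",
             ground_truth = "ground_truth.nii.gz")
  out <- character(0)
  for (nm in names(paths)) {
    p <- file.path(dir, paths[[nm]])
    write_volume(bundle[[nm]], p)
    out[nm] <- p
  }
  for (nm in c("gm", "wm", "csf")) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_volume(bundle$tissues[[nm]], p)
    out[nm] <- p
  }
  manifest <- list(
    seed = bundle$spec$seed,
    noise_sd = bundle$spec$noise_sd,
    n_brain_voxels = as.integer(sum(bundle$brain_mask$data)),
    n_lesion_voxels = as.integer(sum(bundle$ground_truth$data)),
    true_volume_cm3 = lesion_volume_cm3(bundle$ground_truth))
  mp <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA), mp)
  out["manifest"] <- mp
  invisible(out)
}
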