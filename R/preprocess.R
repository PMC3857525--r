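#' Tissue probability maps in T1 space
#'
#' Bundles grey-matter, white-matter and CSF maps (probability or binary) on
#' a common grid. Values are clipped into [0, 1] with a warning if clipping
#' was needed.
#'
#' @param gm,wm,csf [wmh_volume]s sharing grid and affine.
#' @return An object of class `wmh_tissues`.
#' @export
tissue_maps <- function(gm, wm, csf) {
  stopifnot(inherits(gm, "wmh_volume"), inherits(wm, "wmh_volume"),
            inherits(csf, "wmh_volume"))
  check_same_grid(gm, wm)
  check_same_grid(gm, csf)
  clip01 <- function(v, label) {
    if (any(v$data < 0 | v$data > 1)) {
      warning(label, " map contains values outside [0,1]; clipping",
              call. = FALSE)
      v$data <- pmin(pmax(v$data, 0), 1)
    }
    v
  }
  structure(list(gm = clip01(gm, "GM"), wm = clip01(wm, "WM"),
                 csf = clip01(csf, "CSF")),
            class = "wmh_tissues")
}

#' Preprocessing configuration
#'
#' Parameters of the preprocessing stage. Defaults follow the reference
#' procedure: 2 mm FWHM smoothing, full affine (12 dof) registration with a
#' correlation-ratio cost, nearest-neighbour resampling for the FLAIR-to-T1
#' coregistration and trilinear for the normalisation to the template grid.
#'
#' @param fwhm_mm Gaussian smoothing kernel FWHM in mm (> 0).
#' @param brain_mask_threshold Threshold on the summed tissue maps, in
#'   (0, 1].
#' @param registration_dof `"affine12"` or `"rigid6"`.
#' @param cost Registration similarity, `"correlation_ratio"` or
#'   `"least_squares"`.
#' @param coreg_interpolation Interpolation for resampling the FLAIR onto
#'   the T1 grid.
#' @param normalization_interpolation Interpolation for resampling onto the
#'   template grid.
#' @param mask_normalized_smoothing If `TRUE`, divide the smoothed image by
#'   the smoothed brain mask inside the brain, compensating the intensity
#'   draw-down near the brain edge that zero-padded smoothing causes.
#' @return An object of class `wmh_config`.
#' @export
preprocess_config <- function(fwhm_mm = 2.0,
                              brain_mask_threshold = 0.5,
                              registration_dof = c("affine12", "rigid6"),
                              cost = c("correlation_ratio", "least_squares"),
                              coreg_interpolation = c("nearest", "trilinear"),
                              normalization_interpolation = c("trilinear",
                                                              "nearest"),
                              mask_normalized_smoothing = FALSE) {
  if (!is.numeric(fwhm_mm) || fwhm_mm <= 0)
    stop("fwhm_mm must be positive", call. = FALSE)
  if (brain_mask_threshold <= 0 || brain_mask_threshold > 1)
    stop("brain_mask_threshold must be in (0, 1]", call. = FALSE)
  structure(list(fwhm_mm = fwhm_mm,
                 brain_mask_threshold = brain_mask_threshold,
                 registration_dof = match.arg(registration_dof),
                 cost = match.arg(cost),
                 coreg_interpolation = match.arg(coreg_interpolation),
                 normalization_interpolation =
                   match.arg(normalization_interpolation),
                 mask_normalized_smoothing =
                   isTRUE(mask_normalized_smoothing)),
            class = "wmh_config")
}

#' Build a whole-brain binary mask from tissue maps
#'
#' Sums the GM, WM and CSF maps and binarises the sum at `threshold`: the
#' standard construction of a brain mask from a unified tissue segmentation.
#'
#' @param tissues A [tissue_maps] object.
#' @param threshold Cut-off on `gm + wm + csf`; voxels at or above it enter
#'   the mask. Default 0.5 (majority probability).
#' @return A [wmh_mask] on the tissue grid.
#' @export
build_brain_mask <- function(tissues, threshold = 0.5) {
  stopifnot(inherits(tissues, "wmh_tissues"))
  s <- tissues$gm$data + tissues$wm$data + tissues$csf$data
  m <- array(as.double(s >= threshold), dim = dim(s))
  if (!any(m == 1))
    warning("brain mask is empty: no voxel reached the threshold",
            call. = FALSE)
  wmh_mask(m, tissues$gm$affine)
}

#' Preprocess a FLAIR image for WMH thresholding
#'
#' Runs the full preprocessing stage: (a) affine coregistration of the FLAIR
#' to the T1; (b) brain-mask construction from the tissue maps and
#' skull-stripping of both images; (c) affine registration of the
#' skull-stripped T1 to the template and application of the composed
#' FLAIR-to-template transform; (d) removal of the excluded region
#' (cerebellum and brainstem); (e) Gaussian smoothing. The output FLAIR and
#' the brain-minus-exclusion mask both live on the template grid.
#'
#' @param flair,t1 [wmh_volume]s in native space.
#' @param tissues A [tissue_maps] object on the T1 grid.
#' @param template A [wmh_volume] defining the standard grid.
#' @param exclusion_mask A [wmh_mask] on the template grid (1 = excluded).
#' @param config A [preprocess_config()].
#' @param verbose Log each stage and its elapsed time to stderr.
#' @return A list of class `wmh_preprocessed`: `flair` (processed volume),
#'   `mask` (brain-minus-exclusion [wmh_mask]), `flair_to_t1` and
#'   `t1_to_template` ([affine_transform]s), and `config`.
#' @export
preprocess_pipeline <- function(flair, t1, tissues, template, exclusion_mask,
                                config = preprocess_config(),
                                verbose = FALSE) {
  stopifnot(inherits(flair, "wmh_volume"), inherits(t1, "wmh_volume"),
            inherits(template, "wmh_volume"),
            inherits(exclusion_mask, "wmh_mask"))
  check_same_grid(template, exclusion_mask)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    if (verbose)
      message(sprintf("[preprocess] %-28s %6.2f s", name,
                      proc.time()[["elapsed"]] - t0))
    out
  }

  fl2t1 <- stage("coregister FLAIR -> T1",
                 register_affine(flair, t1, config))

  brain <- stage("build brain mask",
                 build_brain_mask(tissues, config$brain_mask_threshold))
  # carry the brain mask back into native FLAIR space so the FLAIR is
  # interpolated only once, by the composed transform
  brain_flair <- resample(brain, affine_transform(solve(fl2t1$matrix)),
                          flair, config$coreg_interpolation)
  if (!inherits(brain_flair, "wmh_mask")) brain_flair <- as_mask(brain_flair)
  flair_brain <- apply_mask(flair, brain_flair)
  t1_brain <- apply_mask(t1, brain)

  t12tpl <- stage("register T1 -> template",
                  register_affine(t1_brain, template, config))
  composed <- affine_transform(t12tpl$matrix %*% fl2t1$matrix)
  flair_tpl <- stage("resample FLAIR onto template grid",
                     resample(flair_brain, composed, template,
                              config$normalization_interpolation))
  mask_tpl <- stage("resample brain mask",
                    resample(brain, t12tpl, template, "nearest"))

  keep <- apply_mask(mask_tpl, mask_complement(exclusion_mask))
  flair_kept <- apply_mask(flair_tpl, keep)

  flair_sm <- stage("smooth", smooth_gaussian(flair_kept, config$fwhm_mm))
  if (config$mask_normalized_smoothing) {
    mk <- smooth_gaussian(wmh_volume(keep$data, keep$affine), config$fwhm_mm)
    inside <- keep$data == 1 & mk$data > 1e-6
    flair_sm$data[inside] <- flair_sm$data[inside] / mk$data[inside]
  }
  # the excluded region stays removed: re-zero the smoothing leakage there
  flair_sm$data[exclusion_mask$data == 1] <- 0

  structure(list(flair = flair_sm, mask = keep,
                 flair_to_t1 = fl2t1, t1_to_template = t12tpl,
                 config = config),
            class = "wmh_preprocessed")
}

#' @export
print.wmh_preprocessed <- function(x, ...) {
  cat("<wmh_preprocessed>\n")
  cat(sprintf("  template grid: %s, voxel %.3g mm^3\n",
              paste(grid_shape(x$flair), collapse = " x "),
              voxel_volume_mm3(x$flair)))
  cat(sprintf("  brain-minus-exclusion mask: %d voxels\n",
              as.integer(sum(x$mask$data))))
  invisible(x)
}
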