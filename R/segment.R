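#' Global intensity statistics of the brain
#'
#' Mean and sample SD of the image intensities that represent brain tissue.
#' With a mask, the statistics run over the in-mask voxels; without one, over
#' the strictly positive voxels, since exact zeros are the background
#' introduced by skull-stripping and would corrupt the moments.
#'
#' @param vol A [wmh_volume].
#' @param mask Optional [wmh_mask] on the same grid.
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return A list of class `wmh_stats`: `mean`, `sd`, `n_voxels`.
#' @export
brain_intensity_stats <- function(vol, mask = NULL,
                                  sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(vol, "wmh_volume"))
  sd_denominator <- match.arg(sd_denominator)
  if (is.null(mask)) {
    v <- vol$data[vol$data > 0]
  } else {
    stopifnot(inherits(mask, "wmh_mask"))
    check_same_grid(vol, mask)
    v <- vol$data[mask$data == 1]
  }
  n <- length(v)
  if (n < 2L)
    stop("degenerate input: fewer than 2 voxels enter the intensity ",
         "statistics", call. = FALSE)
  s <- stats::sd(v)
  if (sd_denominator == "n") s <- s * sqrt((n - 1) / n)
  structure(list(mean = mean(v), sd = s, n_voxels = n), class = "wmh_stats")
}

#' Segment hyperintensities by global thresholding
#'
#' Computes the brain intensity mean and SD via [brain_intensity_stats()] and
#' labels as lesion every in-mask voxel with intensity at or above
#' `mean + k * sd`. `k = 1.5` is the default operating point. A voxel exactly
#' at the threshold is lesion (keep-at-threshold rule).
#'
#' @param vol A preprocessed [wmh_volume] (or the `flair` of a
#'   [preprocess_pipeline()] result).
#' @param mask Optional [wmh_mask] restricting both the statistics and the
#'   lesion map; without it, strictly positive voxels are used.
#' @param k Threshold multiplier on the SD.
#' @param sd_denominator Passed to [brain_intensity_stats()].
#' @return An object of class `wmh_segmentation`: `lesion_map` ([wmh_mask]),
#'   `stats`, `k`, `threshold`, `n_lesion_voxels`, `volume_cm3`, `edits`.
#' @examples
#' v <- wmh_volume(array(c(rep(100, 995), rep(160, 5)), dim = c(10, 10, 10)))
#' threshold_segment(v, k = 1.5)
#' @export
threshold_segment <- function(vol, mask = NULL, k = 1.5,
                              sd_denominator = c("n-1", "n")) {
  stopifnot(inherits(vol, "wmh_volume"), is.numeric(k), length(k) == 1L)
  st <- brain_intensity_stats(vol, mask, sd_denominator)
  thr <- st$mean + k * st$sd
  inmask <- if (is.null(mask)) vol$data > 0 else mask$data == 1
  lesion <- array(as.double(inmask & vol$data >= thr), dim = dim(vol$data))
  lesion_map <- wmh_mask(lesion, vol$affine)
  new_segmentation(lesion_map, st, k, thr,
                   edits = list(added = 0L, removed = 0L))
}

new_segmentation <- function(lesion_map, stats, k, threshold, edits) {
  n <- as.integer(sum(lesion_map$data))
  structure(list(lesion_map = lesion_map, stats = stats, k = k,
                 threshold = threshold, n_lesion_voxels = n,
                 volume_cm3 = n * voxel_volume_mm3(lesion_map) / 1000,
                 edits = edits),
            class = "wmh_segmentation")
}

#' Merge manual edit masks into a segmentation
#'
#' Deterministic stand-in for interactive correction of false positives and
#' negatives: voxels in `additions` are re-included, voxels in `removals`
#' are deleted, and removals win where the two overlap. Counts and volume
#' are recomputed; the threshold provenance is carried over unchanged.
#'
#' @param seg A `wmh_segmentation` from [threshold_segment()].
#' @param additions,removals Optional [wmh_mask]s on the lesion map's grid.
#' @return A new `wmh_segmentation` with updated lesion map and `edits`
#'   provenance (voxels added / removed).
#' @export
apply_edits <- function(seg, additions = NULL, removals = NULL) {
  stopifnot(inherits(seg, "wmh_segmentation"))
  old <- seg$lesion_map
  new <- old$data
  if (!is.null(additions)) {
    stopifnot(inherits(additions, "wmh_mask"))
    check_same_grid(old, additions)
    new <- pmax(new, additions$data)
  }
  if (!is.null(removals)) {
    stopifnot(inherits(removals, "wmh_mask"))
    check_same_grid(old, removals)
    new <- new * (1 - removals$data)
  }
  added <- as.integer(sum(new == 1 & old$data == 0))
  removed <- as.integer(sum(new == 0 & old$data == 1))
  new_segmentation(wmh_mask(array(new, dim = dim(new)), old$affine),
                   seg$stats, seg$k, seg$threshold,
                   edits = list(added = added, removed = removed))
}

#' Lesion volume in cubic centimetres
#'
#' Number of 1-voxels times the voxel volume in mm^3, divided by 1000.
#'
#' @param mask A [wmh_mask] (e.g. a lesion map).
#' @return Non-negative scalar, cm^3.
#' @export
lesion_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "wmh_mask"))
  sum(mask$data) * voxel_volume_mm3(mask) / 1000
}

#' @export
print.wmh_segmentation <- function(x, ...) {
  cat("<wmh_segmentation>\n")
  cat(sprintf("  brain voxels: %d, intensity %.4g +/- %.4g\n",
              x$stats$n_voxels, x$stats$mean, x$stats$sd))
  cat(sprintf("  threshold: mean + %.3g * SD = %.6g\n", x$k, x$threshold))
  cat(sprintf("  lesion: %d voxels = %.4g cm^3\n",
              x$n_lesion_voxels, x$volume_cm3))
  if (x$edits$added > 0 || x$edits$removed > 0)
    cat(sprintf("  edits: +%d / -%d voxels\n",
                x$edits$added, x$edits$removed))
  invisible(x)
}

#' @export
summary.wmh_segmentation <- function(object, ...) {
  out <- c(mean = object$stats$mean, sd = object$stats$sd,
           n_brain_voxels = object$stats$n_voxels, k = object$k,
           threshold = object$threshold,
           n_lesion_voxels = object$n_lesion_voxels,
           volume_cm3 = object$volume_cm3)
  class(out) <- "summary.wmh_segmentation"
  out
}

#' @export
print.summary.wmh_segmentation <- function(x, ...) {
  print(unclass(x))
  invisible(x)
}

#' Serialise a segmentation report to JSON
#'
#' @param seg A `wmh_segmentation`.
#' @param path Optional output file; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
segmentation_report_json <- function(seg, path = NULL) {
  stopifnot(inherits(seg, "wmh_segmentation"))
  rec <- list(mean = seg$stats$mean, sd = seg$stats$sd,
              n_brain_voxels = seg$stats$n_voxels, k = seg$k,
              threshold = seg$threshold,
              n_lesion_voxels = seg$n_lesion_voxels,
              volume_cm3 = seg$volume_cm3,
              voxels_added = seg$edits$added,
              voxels_removed = seg$edits$removed)
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
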