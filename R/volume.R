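#' @useDynLib wmhseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Volumetric image with a voxel-to-world affine
#'
#' A `wmh_volume` couples a 3-D array of intensities with a 4x4 affine matrix
#' mapping 0-based voxel indices `(i, j, k, 1)` to world coordinates in
#' millimetres (RAS convention, as in the NIfTI-1 standard).
#'
#' @param data Numeric 3-D array of intensities. Must be finite.
#' @param affine 4x4 numeric matrix; the upper-left 3x3 block must have
#'   nonzero determinant. Defaults to 1 mm isotropic spacing at the origin.
#' @return An object of class `wmh_volume` with elements `data` and `affine`.
#' @examples
#' v <- wmh_volume(array(0, dim = c(4, 4, 4)))
#' voxel_volume_mm3(v)
#' @export
wmh_volume <- function(data, affine = diag(4)) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3-D array, got ", length(dim(data)),
         " dimensions", call. = FALSE)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data)))
    stop("volume data must be finite numeric values", call. = FALSE)
  affine <- validate_affine(affine)
  storage.mode(data) <- "double"
  structure(list(data = data, affine = unname(affine)),
            class = "wmh_volume")
}

#' Binary mask on a voxel grid
#'
#' A `wmh_mask` is a [wmh_volume] whose voxels are exactly 0 or 1. It carries
#' brain masks, exclusion masks, lesion maps and manual edit masks.
#'
#' @param data Numeric 3-D array containing only the values 0 and 1.
#' @param affine 4x4 voxel-to-world affine matrix.
#' @return An object of class `c("wmh_mask", "wmh_volume")`.
#' @export
wmh_mask <- function(data, affine = diag(4)) {
  v <- wmh_volume(data, affine)
  if (!all(v$data == 0 | v$data == 1))
    stop("mask voxels must be exactly 0 or 1", call. = FALSE)
  class(v) <- c("wmh_mask", "wmh_volume")
  v
}

#' Binarize a volume into a mask
#'
#' @param vol A [wmh_volume].
#' @param threshold Voxels with values `>= threshold` become 1. Default 0.5.
#' @return A [wmh_mask] on the same grid.
#' @export
as_mask <- function(vol, threshold = 0.5) {
  stopifnot(inherits(vol, "wmh_volume"))
  wmh_mask(array(as.double(vol$data >= threshold), dim = dim(vol$data)),
           vol$affine)
}

validate_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  storage.mode(affine) <- "double"
  if (anyNA(affine) || any(!is.finite(affine)))
    stop("affine contains non-finite entries", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("affine upper-left 3x3 block is singular", call. = FALSE)
  affine
}

#' @export
print.wmh_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, voxel volume %.4g mm^3\n",
              class(x)[1], d[1], d[2], d[3], voxel_volume_mm3(x)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Grid dimensions of a volume
#' @param vol A [wmh_volume].
#' @return Integer vector `(nx, ny, nz)`.
#' @export
grid_shape <- function(vol) dim(vol$data)

#' Voxel spacing along each axis
#' @param vol A [wmh_volume].
#' @return Numeric length-3 vector of spacings in mm (column norms of the
#'   affine's 3x3 block).
#' @export
spacing_mm <- function(vol) sqrt(colSums(vol$affine[1:3, 1:3]^2))

#' Voxel volume in cubic millimetres
#'
#' The absolute determinant of the upper-left 3x3 block of the affine, i.e.
#' the volume of one voxel in world space.
#'
#' @param vol A [wmh_volume].
#' @return Positive scalar, mm^3.
#' @export
voxel_volume_mm3 <- function(vol) {
  stopifnot(inherits(vol, "wmh_volume"))
  abs(det(vol$affine[1:3, 1:3]))
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii` or `.nii.gz` file into a [wmh_volume]. Data are cast to
#' double; the affine is taken from the header, preferring the sform when its
#' code is positive and falling back to the qform, then to a spacing-only
#' diagonal affine. Trailing singleton dimensions (e.g. a 4-D file whose last
#' dimension is 1) are squeezed.
#'
#' @param path Path to a NIfTI-1 file.
#' @param as_mask If `TRUE`, return a [wmh_mask] (values are checked).
#' @return A [wmh_volume] (or [wmh_mask]).
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) > 3L && any(d[-(1:3)] != 1L))
    stop("expected a 3-D image, got dimensions (",
         paste(d, collapse = ", "), ") in ", path, call. = FALSE)
  if (length(d) < 3L)
    stop("expected a 3-D image, got ", length(d), "-D image in ", path,
         call. = FALSE)
  arr <- array(as.double(arr), dim = d[1:3])  # drop niftiImage attributes
  hdr <- RNifti::niftiHeader(img)
  if (hdr$sform_code > 0 || hdr$qform_code > 0) {
    affine <- unclass(RNifti::xform(img))  # sform preferred when coded
    attributes(affine) <- list(dim = c(4L, 4L))
  } else {
    affine <- diag(c(RNifti::pixdim(img)[1:3], 1))
  }
  storage.mode(arr) <- "double"
  if (as_mask) wmh_mask(arr, affine) else wmh_volume(arr, affine)
}

#' Write a volume as NIfTI-1
#'
#' Stores the affine as both sform and qform (codes 2). A `.nii.gz` suffix
#' produces gzip-compressed output. Data are written as float32 for
#' intensity volumes and uint8 for masks.
#'
#' @param vol A [wmh_volume] or [wmh_mask].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "wmh_volume"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  dtype <- if (inherits(vol, "wmh_mask")) "uint8" else "float"
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- spacing_mm(vol)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Affine world-to-world transform
#'
#' Wraps a 4x4 matrix mapping world-mm coordinates of a moving image to
#' world-mm coordinates of a fixed image, as produced by [register_affine()]
#' and consumed by [resample()].
#'
#' @param matrix Invertible 4x4 numeric matrix (last row `0 0 0 1`).
#' @return An object of class `wmh_affine`.
#' @export
affine_transform <- function(matrix = diag(4)) {
  matrix <- validate_affine(matrix)
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-6)
    stop("last row of an affine transform must be 0 0 0 1", call. = FALSE)
  structure(list(matrix = unname(matrix)), class = "wmh_affine")
}

#' @export
print.wmh_affine <- function(x, ...) {
  cat("<wmh_affine> world-mm to world-mm\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' Read / write a transform as a 4-line text matrix
#'
#' FLIRT-style convention: four whitespace-separated rows of four numbers.
#'
#' @param path File path.
#' @return `read_affine` returns a [affine_transform]; `write_affine`
#'   returns `path` invisibly.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  affine_transform(m)
}

#' @rdname read_affine
#' @param transform A [affine_transform].
#' @export
write_affine <- function(transform, path) {
  stopifnot(inherits(transform, "wmh_affine"))
  utils::write.table(format(transform$matrix, digits = 17), path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample a volume onto a target grid under an affine transform
#'
#' Each voxel of the target grid is mapped to world space, pulled back
#' through the inverse of `transform` into the moving image's world space,
#' and sampled there. Out-of-field voxels are 0. Nearest-neighbour
#' interpolation of a mask yields a mask.
#'
#' @param moving A [wmh_volume] to resample.
#' @param transform A [affine_transform] mapping moving-world to fixed-world
#'   mm; identity by default.
#' @param target A [wmh_volume] defining the output grid and affine.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return A [wmh_volume] (or [wmh_mask] when `moving` is a mask and
#'   interpolation is nearest) on the target grid.
#' @export
resample <- function(moving, transform = affine_transform(), target,
                     interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(moving, "wmh_volume"), inherits(target, "wmh_volume"))
  if (!inherits(transform, "wmh_affine"))
    transform <- affine_transform(transform)
  interpolation <- match.arg(interpolation)
  # target voxel -> target world -> moving world -> moving voxel
  M <- solve(moving$affine) %*% solve(transform$matrix) %*% target$affine
  mode <- if (interpolation == "nearest") 0L else 1L
  out <- .affine_sample_cpp(as.double(moving$data), dim(moving$data),
                            M, dim(target$data), mode)
  arr <- array(out, dim = dim(target$data))
  if (inherits(moving, "wmh_mask") && interpolation == "nearest")
    wmh_mask(arr, target$affine)
  else
    wmh_volume(arr, target$affine)
}

#' Multiply a volume by a binary mask
#'
#' Voxelwise product; voxels outside the mask become exactly 0. The grids
#' must agree (affine entries within 1e-4).
#'
#' @param vol A [wmh_volume].
#' @param mask A [wmh_mask] on the same grid.
#' @return A masked [wmh_volume] (a [wmh_mask] if `vol` is one).
#' @export
apply_mask <- function(vol, mask) {
  stopifnot(inherits(vol, "wmh_volume"), inherits(mask, "wmh_mask"))
  check_same_grid(vol, mask)
  out <- vol
  out$data <- vol$data * mask$data
  out
}

#' Logical complement of a mask
#' @param mask A [wmh_mask].
#' @return A [wmh_mask] with 0 and 1 exchanged.
#' @export
mask_complement <- function(mask) {
  stopifnot(inherits(mask, "wmh_mask"))
  wmh_mask(1 - mask$data, mask$affine)
}

check_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: (", paste(dim(a$data), collapse = "x"), ") vs (",
         paste(dim(b$data), collapse = "x"), ")", call. = FALSE)
  if (max(abs(a$affine - b$affine)) > tol)
    stop("affine mismatch between volumes (max difference ",
         format(max(abs(a$affine - b$affine))), ")", call. = FALSE)
  invisible(TRUE)
}
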