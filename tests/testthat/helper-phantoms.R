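# Small phantoms shared across test files. Generated once per test run.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(64, 64, 40), ...)
}

# a tiny volume with known values for arithmetic checks
tiny_volume <- function(values, dim = c(4, 4, 2), affine = diag(4)) {
  wmh_volume(array(values, dim = dim), affine)
}

tiny_mask <- function(values, dim = c(4, 4, 2), affine = diag(4)) {
  wmh_mask(array(values, dim = dim), affine)
}

# mask with `n` ones placed at the start of the array
mask_with_n_ones <- function(n, dim = c(10, 10, 5), affine = diag(4)) {
  v <- numeric(prod(dim))
  v[seq_len(n)] <- 1
  wmh_mask(array(v, dim = dim), affine)
}

random_mask <- function(dim = c(8, 8, 4), p = 0.3) {
  wmh_mask(array(as.double(stats::runif(prod(dim)) < p), dim = dim))
}

# zero-padded whole-voxel shift of a 3-D array along one axis
shift_arr <- function(a, axis, by) {
  d <- dim(a)
  out <- array(0, dim = d)
  src <- lapply(d, seq_len)
  dst <- lapply(d, seq_len)
  n <- d[axis]
  if (by > 0) {
    src[[axis]] <- seq_len(n - by)
    dst[[axis]] <- seq_len(n - by) + by
  } else if (by < 0) {
    src[[axis]] <- seq_len(n + by) - by
    dst[[axis]] <- seq_len(n + by)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
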