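#' Intensity-based affine registration
#'
#' Estimates the world-to-world affine transform aligning a moving image to a
#' fixed image, in the spirit of FSL FLIRT: a correlation-ratio similarity
#' between the moving intensities and the binned fixed intensities, optimised
#' coarse-to-fine (downsampling factors 4, 2, 1) with a derivative-free
#' simplex at each level, starting from the alignment of the two images'
#' intensity centres of mass. Rotations and scalings are parameterised about
#' the fixed image's centre of mass.
#'
#' @param moving,fixed [wmh_volume]s with non-constant intensities inside
#'   their nonzero support.
#' @param config A [preprocess_config()]; the fields `registration_dof`
#'   (`"rigid6"` or `"affine12"`) and `cost` (`"correlation_ratio"` or
#'   `"least_squares"`) are used here.
#' @return A [affine_transform] mapping moving-world mm to fixed-world mm,
#'   with attributes `cost` (achieved), `initial_cost` and `converged`.
#' @export
register_affine <- function(moving, fixed, config = preprocess_config()) {
  stopifnot(inherits(moving, "wmh_volume"), inherits(fixed, "wmh_volume"))
  check_nonconstant(moving, "moving")
  check_nonconstant(fixed, "fixed")
  dof <- match.arg(config$registration_dof, c("affine12", "rigid6"))
  cost_name <- match.arg(config$cost, c("correlation_ratio", "least_squares"))
  npar <- if (dof == "rigid6") 6L else 12L

  center <- center_of_mass(fixed)
  par <- numeric(npar)
  par[1:3] <- center - center_of_mass(moving)  # gross offset from CoM

  # parameter scales: mm for translations, degrees for rotations,
  # log-scale / shear units ~0.05
  pscale <- c(rep(1, 3), rep(1, 3), rep(0.05, 6))[seq_len(npar)]

  par0 <- par  # centre-of-mass starting transform
  initial_cost <- NA_real_
  final_cost <- NA_real_
  last_fun <- NULL
  converged <- TRUE
  for (factor in c(4L, 2L, 1L)) {
    fx <- downsample_volume(fixed, factor)
    mv <- downsample_volume(moving, factor)
    fpos <- fx$data > 0
    if (sum(fpos) < 50) next
    # bins over the whole fixed grid, with the zero background as its own
    # bin: support mismatch in either direction (brain sampling background
    # or background sampling brain) then raises within-bin variance, so the
    # cost cannot be lowered by shrinking or growing the moving image
    fvals <- as.vector(fx$data)
    bins <- integer(length(fvals))
    bins[!fpos] <- 1L
    bins[fpos] <- bin_intensities(fvals[fpos], nbins = 32L) + 1L
    fun <- function(p) {
      Tm <- params_to_matrix(p, center)
      M <- solve(mv$affine) %*% solve(Tm) %*% fx$affine
      res <- .affine_sample_cpp(as.double(mv$data), dim(mv$data), M,
                                dim(fx$data), 1L)
      if (sum(res[fpos] > 0) < 50) return(1e6)
      if (cost_name == "correlation_ratio")
        correlation_ratio_cost(as.vector(res), bins)
      else
        mean((res - fvals)^2) / stats::var(fvals)
    }
    last_fun <- fun

    # estimate the rigid part first at the coarser levels, then (for
    # affine12) open up all 12 parameters; the full-resolution level only
    # polishes, so it gets a smaller iteration budget
    if (npar == 12L && factor > 1L) {
      fun6 <- function(p6) fun(c(p6, par[7:12]))
      opt6 <- stats::optim(par[1:6], fun6, method = "Nelder-Mead",
                           control = list(maxit = 300L,
                                          parscale = pscale[1:6],
                                          reltol = 1e-8))
      if (opt6$value <= fun6(par[1:6])) par[1:6] <- opt6$par
    }
    cost_before <- fun(par)
    if (factor > 1L) {
      for (s in 1:2) {
        opt <- stats::optim(par, fun, method = "Nelder-Mead",
                            control = list(maxit = 400L, parscale = pscale,
                                           reltol = 1e-8))
        if (opt$value <= fun(par)) par <- opt$par
      }
    } else {
      # full-resolution polish: restart the simplex (it re-expands from the
      # collapsed one) until the cost stops moving, up to three rounds
      prev <- cost_before
      for (round in 1:3) {
        opt <- stats::optim(par, fun, method = "Nelder-Mead",
                            control = list(maxit = 300L, parscale = pscale,
                                           reltol = 1e-10))
        if (opt$value <= prev) par <- opt$par
        if (prev - opt$value < 1e-6 * max(prev, 1e-12)) break
        prev <- opt$value
      }
      if (opt$convergence != 0L &&
          is.finite(cost_before) && cost_before > 0 &&
          (cost_before - opt$value) / cost_before > 0.01) {
        converged <- FALSE
        warning("registration simplex reached its iteration limit; ",
                "returning best transform found", call. = FALSE)
      }
    }
    final_cost <- opt$value
  }
  # the starting and achieved costs are compared on the finest level used;
  # the optimised transform can never be worse than the starting one
  initial_cost <- last_fun(par0)
  final_cost <- last_fun(par)
  if (final_cost > initial_cost) {
    par <- par0
    final_cost <- initial_cost
  }
  out <- affine_transform(params_to_matrix(par, center))
  attr(out, "cost") <- final_cost
  attr(out, "initial_cost") <- initial_cost
  attr(out, "converged") <- converged
  attr(out, "parameters") <- par
  out
}

check_nonconstant <- function(vol, label) {
  v <- vol$data[vol$data > 0]
  if (length(v) < 2L || stats::var(v) == 0)
    stop("degenerate input: ", label,
         " image has no intensity variance inside its nonzero support",
         call. = FALSE)
  invisible(TRUE)
}

# Intensity-weighted centre of mass in world mm.
center_of_mass <- function(vol) {
  w <- vol$data
  w[w < 0] <- 0
  tot <- sum(w)
  if (tot == 0) stop("cannot compute centre of mass of an empty image",
                     call. = FALSE)
  d <- dim(w)
  ci <- c(sum(slice_index(d, 1) * w), sum(slice_index(d, 2) * w),
          sum(slice_index(d, 3) * w)) / tot
  as.vector(vol$affine %*% c(ci, 1))[1:3]
}

# array of 0-based index values along one axis, matching dim d
slice_index <- function(d, axis) {
  idx <- seq_len(d[axis]) - 1
  perm <- c(axis, setdiff(1:3, axis))
  aperm(array(idx, dim = d[perm]), order(perm))
}

# Rigid/affine parameter vector to a 4x4 world transform.
# par = (tx,ty,tz, rx,ry,rz in degrees[, log-sx,sy,sz, shear-xy,xz,yz])
# Rotation/scale/shear act about `center` (world mm).
params_to_matrix <- function(par, center = c(0, 0, 0)) {
  t <- par[1:3]
  r <- par[4:6] * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  A3 <- Rz %*% Ry %*% Rx
  if (length(par) >= 12L) {
    S <- diag(exp(par[7:9]))
    Sh <- diag(3)
    Sh[1, 2] <- par[10]; Sh[1, 3] <- par[11]; Sh[2, 3] <- par[12]
    A3 <- A3 %*% S %*% Sh
  }
  M <- diag(4)
  M[1:3, 1:3] <- A3
  M[1:3, 4] <- t + center - A3 %*% center
  M
}

# Smooth-and-subsample pyramid level; factor 1 returns the volume unchanged.
downsample_volume <- function(vol, factor) {
  if (factor == 1L) return(vol)
  sp <- spacing_mm(vol)
  sm <- smooth_gaussian(vol, fwhm_mm = 2.355 * (factor / 2) * min(sp))
  d <- dim(sm$data)
  ix <- seq(1, d[1], by = factor)
  iy <- seq(1, d[2], by = factor)
  iz <- seq(1, d[3], by = factor)
  arr <- sm$data[ix, iy, iz, drop = FALSE]
  aff <- vol$affine %*% diag(c(factor, factor, factor, 1))
  wmh_volume(arr, aff)
}

bin_intensities <- function(x, nbins = 32L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1L, length(x)))
  b <- as.integer(floor((x - rng[1]) / diff(rng) * nbins)) + 1L
  b[b > nbins] <- nbins
  b
}

# 1 - eta^2: fraction of moving-intensity variance not explained by the
# fixed-intensity bin. 0 = moving perfectly predicted by fixed.
correlation_ratio_cost <- function(m, bins) {
  tot_var <- stats::var(m)
  if (!is.finite(tot_var) || tot_var == 0) return(1e6)
  n_k <- tabulate(bins)
  s_k <- as.vector(rowsum(m, bins, reorder = TRUE))
  ss_k <- as.vector(rowsum(m^2, bins, reorder = TRUE))
  keep <- n_k > 0
  within <- sum(ss_k - s_k^2 / n_k[keep])
  within / ((length(m) - 1) * tot_var)
}
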