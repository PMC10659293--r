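#' Per-shell noise model
#'
#' Radial noise variance profile with a record of how it was obtained.
#'
#' @param sigma2 numeric vector of per-shell noise variances (strictly
#'   positive) on the parent grid's shells.
#' @param shells the \code{\link{build_shells}} object of the parent grid.
#' @param method \code{"sphere_complement"}, \code{"slab"} or
#'   \code{"known"}.
#' @param region_spec list of geometric parameters used (e.g. sphere
#'   radius in Angstrom, or slab axis and index range).
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(sigma2, shells,
                        method = c("known", "sphere_complement", "slab"),
                        region_spec = list()) {
  method <- match.arg(method)
  if (length(sigma2) != shells$n_shells) {
    stop("sigma2 length does not match number of shells")
  }
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop("noise variance must be strictly positive at every shell; ",
         "zero noise makes whitening undefined")
  }
  structure(
    list(sigma2 = as.numeric(sigma2), shells = shells,
         frequencies = shells$frequencies, method = method,
         region_spec = region_spec),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat("noise_model (", x$method, "): ", length(x$sigma2), " shells, sigma2 in [",
      format(min(x$sigma2)), ", ", format(max(x$sigma2)), "]\n", sep = "")
  invisible(x)
}

## Guard tiny estimated variances before division.
floor_sigma2 <- function(sigma2) {
  floor_val <- 1e-12 * max(sigma2)
  if (any(sigma2 < floor_val)) {
    warning("noise variance floored at 1e-12 of the profile maximum on ",
            sum(sigma2 < floor_val), " shell(s)")
    sigma2 <- pmax(sigma2, floor_val)
  }
  sigma2
}

#' Estimate noise from the region outside a centered sphere
#'
#' Zeroes all voxels inside a centered sphere assumed to enclose the
#' structure, computes the spherically averaged power spectrum of the
#' masked grid, and rescales it by the inverse of the fraction of voxels
#' kept, compensating the power removed with the masked region.
#'
#' @param g a \code{\link{real_grid}}.
#' @param radius sphere radius in Angstrom; at least 5 percent of the
#'   voxels must lie outside the sphere.
#' @return a \code{\link{noise_model}} with method
#'   \code{"sphere_complement"}.
#' @export
estimate_noise_sphere_complement <- function(g, radius) {
  stopifnot_real_grid(g)
  if (!is.numeric(radius) || radius <= 0) stop("'radius' must be positive (Angstrom)")
  shape <- g$shape
  d <- grid_ndim(g)
  dist2 <- array(0, dim = shape)
  for (a in seq_len(d)) {
    coord2 <- ((0:(shape[a] - 1L)) - floor(shape[a] / 2))^2
    before <- if (a == 1L) 1 else prod(shape[seq_len(a - 1L)])
    dist2 <- dist2 + array(rep(coord2, each = before), dim = shape)
  }
  outside <- g$voxel_size * sqrt(dist2) > radius
  frac_outside <- mean(outside)
  if (frac_outside < 0.05) {
    stop("sphere of radius ", format(radius), " A leaves only ",
         format(100 * frac_outside, digits = 3),
         "% of voxels outside; need at least 5% for a noise estimate")
  }
  masked <- g$values
  masked[!outside] <- 0
  shells <- build_shells(shape, g$voxel_size)
  ps <- radial_power_spectrum(real_grid(masked, g$voxel_size), shells)
  sigma2 <- floor_sigma2(ps$values / frac_outside)
  noise_model(sigma2, shells, method = "sphere_complement",
              region_spec = list(radius_angstrom = radius,
                                 fraction_outside = frac_outside))
}

#' Estimate noise from a signal-free slab
#'
#' Extracts the slab \code{lo..hi} (1-based, inclusive) along one axis,
#' computes its radially averaged power spectrum on shells rebuilt for the
#' slab's shape (singleton axes are dropped), and transfers it onto the
#' parent grid's shell frequencies by piecewise-linear interpolation in
#' physical frequency (constant extrapolation at the ends).
#'
#' @param g a \code{\link{real_grid}}.
#' @param axis axis along which the slab is taken.
#' @param lo,hi first and last slab plane (1-based, \code{lo <= hi}).
#' @return a \code{\link{noise_model}} with method \code{"slab"}.
#' @export
estimate_noise_slab <- function(g, axis, lo, hi) {
  stopifnot_real_grid(g)
  axis <- as.integer(axis)
  d <- grid_ndim(g)
  if (axis < 1L || axis > d) stop("'axis' must be between 1 and ", d)
  n <- g$shape[axis]
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (is.na(lo) || is.na(hi) || lo < 1L || hi > n || lo > hi) {
    stop("slab range [", lo, ", ", hi, "] is empty or outside 1..", n)
  }
  slab <- take_axis(g$values, axis, lo:hi)
  keep <- dim(slab) > 1L
  if (!any(keep)) stop("slab reduces to a single voxel")
  dim(slab) <- dim(slab)[keep]
  slab_grid <- real_grid(slab, g$voxel_size)
  slab_shells <- build_shells(slab_grid$shape, g$voxel_size)
  ps <- radial_power_spectrum(slab_grid, slab_shells)
  parent_shells <- build_shells(g$shape, g$voxel_size)
  ## the DC shell reflects the slab's mean offset, not its noise spectral
  ## density; exclude it from the transfer
  keep_sh <- seq_along(ps$values) > 1L
  sigma2 <- stats::approx(x = slab_shells$frequencies[keep_sh],
                          y = ps$values[keep_sh],
                          xout = parent_shells$frequencies, rule = 2)$y
  sigma2 <- floor_sigma2(sigma2)
  noise_model(sigma2, parent_shells, method = "slab",
              region_spec = list(axis = axis, lo = lo, hi = hi))
}

#' Exact noise model from known per-shell variances
#'
#' Convenience wrapper used with synthetic data, where the generative
#' noise spectrum is known exactly.
#'
#' @param sigma2 per-shell noise variances on the parent shells; a zero
#'   shell-0 entry (mean-free noise) is replaced by the nearest positive
#'   shell value.
#' @param shells parent \code{\link{build_shells}}.
#' @return a \code{\link{noise_model}} with method \code{"known"}.
#' @export
known_noise_model <- function(sigma2, shells) {
  if (length(sigma2) >= 2L && sigma2[1L] <= 0) sigma2[1L] <- sigma2[2L]
  noise_model(sigma2, shells, method = "known")
}

## Per-index variance lookup: shell label clamped to the profile range so
## corner coefficients outside the Nyquist ball use the outermost shell.
sigma2_per_index <- function(nm, shape) {
  labels <- as.integer(round(sqrt(radial_index_sq(shape))))
  labels <- pmin(labels, length(nm$sigma2) - 1L)
  arr <- nm$sigma2[labels + 1L]
  dim(arr) <- shape
  arr
}

#' Whiten a measurement
#'
#' Divides every Fourier coefficient at shell r by \code{sqrt(sigma2(r))}.
#' The transform is radial, hence Hermitian-symmetric, and the output is
#' real.  After whitening, noise drawn from the model has unit variance
#' per coefficient (flat radial power spectrum near 1) in the unitary
#' convention, and the per-shell SSNR is unchanged.  Corner coefficients
#' beyond the inscribed Nyquist ball are scaled with the outermost shell's
#' variance.
#'
#' @param g a \code{\link{real_grid}}.
#' @param nm a \code{\link{noise_model}} on \code{g}'s shells.
#' @return the whitened \code{\link{real_grid}}.
#' @export
whiten <- function(g, nm) {
  stopifnot_real_grid(g)
  if (!inherits(nm, "noise_model")) stop("expected a 'noise_model'")
  check_shells_match(g, nm$shells)
  w <- 1 / sqrt(sigma2_per_index(nm, g$shape))
  real_grid(Re(uifft(ufft(g$values) * w)), g$voxel_size)
}

#' Undo a whitening transform
#'
#' Multiplies coefficients back by \code{sqrt(sigma2(r))}; exact inverse
#' of \code{\link{whiten}} with the same model.
#'
#' @param g a whitened \code{\link{real_grid}}.
#' @param nm the \code{\link{noise_model}} used for whitening.
#' @return the un-whitened \code{\link{real_grid}}.
#' @export
unwhiten <- function(g, nm) {
  stopifnot_real_grid(g)
  if (!inherits(nm, "noise_model")) stop("expected a 'noise_model'")
  check_shells_match(g, nm$shells)
  w <- sqrt(sigma2_per_index(nm, g$shape))
  real_grid(Re(uifft(ufft(g$values) * w)), g$voxel_size)
}

#' Direct SSNR estimate from the power spectrum and a noise model
#'
#' If the noise variance is known, the per-shell SSNR can be estimated
#' without any correlation: the noise variance is subtracted from the
#' measured power spectrum and the difference is divided by the noise
#' variance, clamping negative excess power at zero.
#'
#' @param power a \code{\link{radial_profile}} of kind \code{"power"}
#'   (the measurement's spherically averaged power spectrum).
#' @param nm a \code{\link{noise_model}} on the same shells.
#' @return a \code{\link{radial_profile}} of kind \code{"ssnr"}.
#' @export
ssnr_direct <- function(power, nm) {
  if (!inherits(power, "radial_profile") || power$kind != "power") {
    stop("'power' must be a radial_profile of kind 'power'")
  }
  if (!inherits(nm, "noise_model")) stop("expected a 'noise_model'")
  if (length(power$values) != length(nm$sigma2)) {
    stop("power spectrum and noise model are on different shells")
  }
  v <- pmax(power$values - nm$sigma2, 0) / nm$sigma2
  radial_profile(v, power$shells, kind = "ssnr")
}
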