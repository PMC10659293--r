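## Fourier-domain resampling: zero-padding upsampling and hard low-pass.

## Pad one axis of a (full, unitary-scaled) coefficient array from n to 2n.
## Coefficients with signed frequency |k| < n/2 are copied; the Nyquist
## plane (signed -n/2) is split in half between signed -n/2 and +n/2 of the
## padded axis, preserving Hermitian symmetry and making interpolation of
## band-limited input exact.  Everything else is zero.
pad_axis_double <- function(X, axis) {
  dims <- dim(X)
  n <- dims[axis]
  if (n %% 2L != 0L) stop("zero-padding requires even axis lengths")
  newdims <- dims
  newdims[axis] <- 2L * n
  Y <- array(0 + 0i, dim = newdims)
  half <- n %/% 2L
  body <- (-(half - 1L)):(half - 1L)        # signed, excluding Nyquist
  src <- body %% n + 1L
  dst <- body %% (2L * n) + 1L
  Y <- assign_axis(Y, axis, dst, take_axis(X, axis, src))
  nyq <- take_axis(X, axis, half + 1L) / 2  # signed -n/2 plane, halved
  Y <- assign_axis(Y, axis, (-half) %% (2L * n) + 1L, nyq)
  Y <- assign_axis(Y, axis, half %% (2L * n) + 1L, nyq)
  Y
}

#' Upsample a grid by zero-padding in Fourier space
#'
#' Band-limited interpolation: the Fourier coefficients of the input are
#' embedded in the low-frequency block of a grid \code{factor} times larger
#' per axis, newly created high-frequency coefficients are exactly zero,
#' and real-space values at the original sample positions are preserved
#' exactly.  Per-axis Nyquist coefficients are split evenly between the two
#' conjugate positions of the finer grid so the output remains real.
#'
#' @param g a \code{\link{real_grid}} with even axis lengths.
#' @param factor integer upsampling factor per axis, >= 2 (default 2).
#' @return a \code{\link{real_grid}} of shape \code{factor * shape} and
#'   voxel size \code{voxel_size / factor}.
#' @export
zero_pad_upsample <- function(g, factor = 2L) {
  stopifnot_real_grid(g)
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 2L) stop("'factor' must be an integer >= 2")
  if (any(g$shape %% 2L != 0L)) stop("all axis lengths must be even")
  if (bitwAnd(factor, factor - 1L) != 0L) {
    stop("'factor' must be a power of two")
  }
  X <- ufft(g$values)
  d <- grid_ndim(g)
  times <- as.integer(round(log2(factor)))
  for (i in seq_len(times)) {
    for (a in seq_len(d)) X <- pad_axis_double(X, a)
    X <- X * 2^(d / 2)  # unitary rescale so real-space values are preserved
  }
  real_grid(Re(uifft(X)), g$voxel_size / factor)
}

#' Hard radial low-pass filter
#'
#' Sets to zero all Fourier coefficients whose radial spatial frequency
#' \code{||k|| / (min(shape) * voxel_size)} is finer than the cutoff
#' resolution.  The cutoff is radial (spherical), so corner frequencies
#' beyond the inscribed Nyquist ball are removed even at a cutoff of twice
#' the voxel size (the Nyquist resolution); band-limited input is returned
#' unchanged at that cutoff.
#'
#' @param g a \code{\link{real_grid}}.
#' @param cutoff resolution in Angstrom at which to cut; must be at least
#'   \code{2 * voxel_size}.
#' @return the filtered \code{\link{real_grid}}.
#' @export
lowpass <- function(g, cutoff) {
  stopifnot_real_grid(g)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    stop("'cutoff' must be a single finite number (Angstrom)")
  }
  nyquist_res <- 2 * g$voxel_size
  if (cutoff < nyquist_res) {
    stop("cutoff (", format(cutoff), " A) is finer than the Nyquist limit of ",
         format(nyquist_res), " A for voxel size ", format(g$voxel_size), " A")
  }
  X <- ufft(g$values)
  f <- sqrt(radial_index_sq(g$shape)) / (min(g$shape) * g$voxel_size)
  X[f > (1 / cutoff) * (1 + 1e-12)] <- 0 + 0i
  real_grid(Re(uifft(X)), g$voxel_size)
}
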