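#' Real-space grid
#'
#' A \code{real_grid} is the basic container of the package: a real scalar
#' field sampled on a d-dimensional integer lattice (d = 1, 2 or 3) with a
#' uniform physical sampling interval (voxel size) in Angstrom.
#'
#' @param values numeric vector, matrix or array of finite values.  A plain
#'   vector is treated as a 1-D grid.
#' @param voxel_size physical sampling interval in Angstrom per voxel,
#'   uniform across axes.  Must be positive.
#' @return an object of class \code{real_grid} with elements \code{values}
#'   (an array carrying a \code{dim} attribute), \code{shape} and
#'   \code{voxel_size}.
#' @examples
#' g <- real_grid(matrix(rnorm(64), 8, 8), voxel_size = 1.05)
#' g$shape
#' @export
real_grid <- function(values, voxel_size = 1) {
  if (!is.numeric(values)) {
    stop("'values' must be numeric")
  }
  if (!all(is.finite(values))) {
    stop("'values' contains non-finite entries; grids must be finite")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop("'voxel_size' must be a single positive number (Angstrom)")
  }
  if (is.null(dim(values))) {
    dim(values) <- length(values)
  }
  d <- length(dim(values))
  if (d < 1L || d > 3L) {
    stop("only 1-D, 2-D and 3-D grids are supported")
  }
  structure(
    list(values = values, shape = dim(values), voxel_size = as.numeric(voxel_size)),
    class = "real_grid"
  )
}

#' @export
print.real_grid <- function(x, ...) {
  cat("real_grid: ", paste(x$shape, collapse = " x "),
      " voxels, voxel size ", format(x$voxel_size), " A\n", sep = "")
  cat("  range [", format(min(x$values)), ", ", format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.real_grid <- function(x) x$shape

grid_ndim <- function(g) length(g$shape)

stopifnot_real_grid <- function(g) {
  if (!inherits(g, "real_grid")) stop("expected a 'real_grid' object")
  invisible(g)
}

## unitary multidimensional DFT helpers (1/sqrt(N) per element overall)
ufft <- function(x) stats::fft(x) / sqrt(length(x))

uifft <- function(X) stats::fft(X, inverse = TRUE) / sqrt(length(X))

#' Forward unitary Fourier transform
#'
#' Computes the discrete Fourier transform of a grid under the unitary
#' convention (overall scale 1/sqrt(total number of voxels)), so that
#' Parseval's identity holds: the sum of squared real-space values equals
#' the sum of squared coefficient magnitudes.  All per-shell variance
#' statements in this package (e.g. unit noise variance after whitening)
#' are in this convention.
#'
#' @param g a \code{\link{real_grid}}.
#' @return an object of class \code{fourier_grid} with complex
#'   \code{coefficients} (same shape as the input), \code{shape},
#'   \code{voxel_size} and \code{normalization = "unitary"}.
#' @export
forward_transform <- function(g) {
  stopifnot_real_grid(g)
  fourier_grid(ufft(g$values), g$voxel_size)
}

fourier_grid <- function(coefficients, voxel_size) {
  structure(
    list(coefficients = coefficients, shape = dim(coefficients),
         voxel_size = voxel_size, normalization = "unitary"),
    class = "fourier_grid"
  )
}

#' @export
print.fourier_grid <- function(x, ...) {
  cat("fourier_grid: ", paste(x$shape, collapse = " x "),
      " coefficients (unitary), voxel size ", format(x$voxel_size), " A\n", sep = "")
  invisible(x)
}

#' Inverse unitary Fourier transform
#'
#' @param fg a \code{fourier_grid} as produced by
#'   \code{\link{forward_transform}}.
#' @return the corresponding \code{\link{real_grid}}.  The imaginary part of
#'   the inverse transform is discarded; for Hermitian-symmetric input it is
#'   at the level of rounding error.
#' @export
inverse_transform <- function(fg) {
  if (!inherits(fg, "fourier_grid")) stop("expected a 'fourier_grid' object")
  real_grid(Re(uifft(fg$coefficients)), fg$voxel_size)
}

## Centered signed DFT index for axis length n: 0, 1, ..., in storage order,
## mapped to the range [-floor(n/2), ceiling(n/2) - 1].
axis_freq <- function(n) {
  k <- 0:(n - 1L)
  ((k + floor(n / 2)) %% n) - floor(n / 2)
}

## Array of squared radial index ||k||^2 over the full grid, storage order.
radial_index_sq <- function(shape) {
  d <- length(shape)
  k2 <- array(0, dim = shape)
  for (a in seq_len(d)) {
    ka2 <- axis_freq(shape[a])^2
    before <- if (a == 1L) 1 else prod(shape[seq_len(a - 1L)])
    k2 <- k2 + array(rep(ka2, each = before), dim = shape)
  }
  k2
}

## Extract / assign a set of planes along one axis of an array.
take_axis <- function(arr, axis, idx) {
  d <- length(dim(arr))
  args <- rep(list(quote(expr = )), d)
  args[[axis]] <- idx
  out <- do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  out
}

assign_axis <- function(arr, axis, idx, value) {
  d <- length(dim(arr))
  args <- rep(list(quote(expr = )), d)
  args[[axis]] <- idx
  do.call(`[<-`, c(list(arr), args, list(value = value)))
}
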