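## Brute-force oracles, independent of the package's FFT-based code paths.

## O(N^2) DFT-matrix multiply, non-unitary convention.
brute_dft <- function(v) {
  n <- length(v)
  W <- exp(-2i * pi * outer(0:(n - 1), 0:(n - 1)) / n)
  as.vector(W %*% v)
}

## Unitary DFT of a 2-D array by explicit quadruple loop (tiny inputs only).
brute_dft2_unitary <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0 + 0i, n1, n2)
  for (k1 in 0:(n1 - 1)) for (k2 in 0:(n2 - 1)) {
    s <- 0 + 0i
    for (x1 in 0:(n1 - 1)) for (x2 in 0:(n2 - 1)) {
      s <- s + m[x1 + 1, x2 + 1] * exp(-2i * pi * (k1 * x1 / n1 + k2 * x2 / n2))
    }
    out[k1 + 1, k2 + 1] <- s
  }
  out / sqrt(n1 * n2)
}

## Signed centered frequency of storage index i (1-based) for axis length n.
signed_freq <- function(i, n) {
  k <- i - 1L
  ((k + floor(n / 2)) %% n) - floor(n / 2)
}

## Enumerate shell members of a small grid by looping over all indices.
brute_shell_members <- function(shape) {
  idx <- as.matrix(expand.grid(lapply(shape, function(n) 1:n)))
  ks <- sapply(seq_along(shape), function(a) signed_freq(idx[, a], shape[a]))
  if (is.null(dim(ks))) ks <- matrix(ks, ncol = length(shape))
  rad <- sqrt(rowSums(ks^2))
  label <- ifelse(rad > min(shape) / 2, NA_integer_, as.integer(round(rad)))
  list(index = idx, label = label)
}

## A smooth band-limited grid: sum of a few low-frequency cosines.
smooth_grid <- function(shape, voxel_size = 1) {
  d <- length(shape)
  coords <- lapply(seq_len(d), function(a) (0:(shape[a] - 1)) / shape[a])
  vals <- array(0, dim = shape)
  for (a in seq_len(d)) {
    before <- if (a == 1L) 1 else prod(shape[seq_len(a - 1L)])
    vals <- vals + array(rep(cos(2 * pi * 2 * coords[[a]]) +
                               0.5 * sin(2 * pi * 3 * coords[[a]]),
                             each = before), dim = shape)
  }
  real_grid(vals, voxel_size)
}

## Radially symmetric smooth 2-D image (Gaussian blob at the box center).
radial_blob <- function(n, voxel_size = 1, width_frac = 0.08) {
  c0 <- floor(n / 2)
  x <- (0:(n - 1)) - c0
  d2 <- outer(x^2, x^2, `+`)
  real_grid(exp(-d2 / (2 * (width_frac * n)^2)), voxel_size)
}

white_noise_grid <- function(shape, sd = 1, voxel_size = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  real_grid(array(rnorm(prod(shape), sd = sd), dim = shape), voxel_size)
}

## Keep every second sample along every axis (decimation to the original
## lattice after a factor-2 upsampling).
take_every_second <- function(arr) {
  if (is.null(dim(arr))) return(arr[seq(1, length(arr), 2)])
  d <- length(dim(arr))
  for (a in seq_len(d)) {
    args <- rep(list(quote(expr = )), d)
    args[[a]] <- seq(1, dim(arr)[a], 2)
    arr <- do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  }
  arr
}

## Interior shells of a decimated-band curve: the rapid-decay condition
## cannot hold on the outermost quarter, where the aliasing partner stays
## inside the occupied band (see the methods vignette).
interior_shells <- function(curve) {
  R <- length(curve$values) - 1L
  2:(floor(0.75 * R) + 1L)
}
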