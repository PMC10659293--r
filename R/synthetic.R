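#' Specification of a synthetic measurement
#'
#' Parameterizes the generative model used throughout validation: a
#' mean-zero Gaussian random signal with diagonal Fourier covariance,
#' constant on radial shells and decaying with a B-factor, plus additive
#' white or colored Gaussian noise scaled to a target real-space
#' signal-to-noise (variance) ratio.
#'
#' The defaults reproduce the reference validation condition: pixel size
#' 0.81 Angstrom, B-factor 100 A^2 on the signal, white noise, SNR 15.
#'
#' @param shape per-axis lengths (even).
#' @param voxel_size voxel size in Angstrom (default 0.81).
#' @param b_signal signal B-factor in A^2 (>= 0; 0 gives a flat spectrum).
#' @param b_noise noise B-factor in A^2 (0 = white noise).
#' @param snr target real-space variance ratio Var(signal)/Var(noise).
#' @param seed integer random seed; every sampling function seeds the R
#'   generator with it, so equal specs give identical draws.
#' @param base \code{"gaussian_field"} (default) or \code{"phantom"} (the
#'   deterministic phantom as signal instead of a Gaussian draw).
#' @param signal_amp,noise_amp optional explicit per-shell amplitude
#'   profiles over all parent shell labels (overriding the B-factor
#'   parameterization); entry r+1 is the amplitude at shell label r.
#' @return an object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(shape, voxel_size = 0.81, b_signal = 100, b_noise = 0,
                           snr = 15, seed = 1L,
                           base = c("gaussian_field", "phantom"),
                           signal_amp = NULL, noise_amp = NULL) {
  base <- match.arg(base)
  shape <- as.integer(shape)
  if (any(shape %% 2L != 0L)) stop("'shape' must be even along all axes")
  if (b_signal < 0 || b_noise < 0) stop("B-factors must be nonnegative")
  if (!is.numeric(snr) || snr <= 0) stop("'snr' must be positive")
  structure(
    list(shape = shape, voxel_size = voxel_size, b_signal = b_signal,
         b_noise = b_noise, snr = snr, seed = as.integer(seed), base = base,
         signal_amp = signal_amp, noise_amp = noise_amp),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("synthetic_spec: ", paste(x$shape, collapse = " x "), " grid, V = ",
      format(x$voxel_size), " A, B_signal = ", format(x$b_signal),
      " A^2, B_noise = ", format(x$b_noise), " A^2, SNR = ", format(x$snr),
      ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' B-factor amplitude attenuation per shell
#'
#' The standard crystallographic amplitude decay
#' \code{exp(-B s^2 / 4)} evaluated at the shell frequencies
#' \code{s = r / (N * V)} in 1/Angstrom.
#'
#' @param shells a \code{\link{build_shells}} object.
#' @param b B-factor in A^2 (>= 0).
#' @return a \code{\link{radial_profile}} of kind \code{"power"} holding
#'   the amplitude factors (1 at shell 0).
#' @export
bfactor_attenuation <- function(shells, b) {
  if (b < 0) stop("'b' must be nonnegative")
  radial_profile(exp(-b * shells$frequencies^2 / 4), shells, kind = "power")
}

## Number of shell labels over the full index cube (corners included).
full_label_count <- function(shape) {
  as.integer(round(sqrt(sum((shape %/% 2L)^2)))) + 1L
}

## Amplitude per full shell label from a spec component.
component_amplitude <- function(spec, which = c("signal", "noise")) {
  which <- match.arg(which)
  nlab <- full_label_count(spec$shape)
  expl <- if (which == "signal") spec$signal_amp else spec$noise_amp
  if (!is.null(expl)) {
    if (length(expl) < nlab) stop("explicit amplitude profile too short: need ",
                                  nlab, " labels")
    amp <- as.numeric(expl[seq_len(nlab)])
  } else {
    b <- if (which == "signal") spec$b_signal else spec$b_noise
    s <- (0:(nlab - 1L)) / (min(spec$shape) * spec$voxel_size)
    amp <- exp(-b * s^2 / 4)
  }
  amp[1L] <- 0  # mean-zero model: no DC component
  amp
}

## Draw one mean-zero Gaussian field whose Fourier coefficients have
## standard deviation amp[label+1] per coefficient (unitary convention).
## Realized by shaping the unitary transform of a white real field, which
## guarantees exact Hermitian symmetry.  Consumes the R RNG state.
draw_shaped_field <- function(shape, voxel_size, amp) {
  labels <- as.integer(round(sqrt(radial_index_sq(shape))))
  w <- array(stats::rnorm(prod(shape)), dim = shape)
  coef <- ufft(w) * amp[labels + 1L]
  real_grid(Re(uifft(coef)), voxel_size)
}

#' Sample a Gaussian random signal with B-factor decay
#'
#' Draws a mean-zero Gaussian field whose unitary Fourier coefficients are
#' independent with per-shell variance \code{lam2}, constant on shells and
#' shaped by the spec's signal amplitude profile.  Reproducible: the R
#' generator is seeded with \code{spec$seed}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a list with \code{grid} (the \code{\link{real_grid}}),
#'   \code{lam2} (true per-shell variance over the Nyquist-ball shells),
#'   \code{lam2_full} (over all shell labels including corners) and
#'   \code{shells}.
#' @export
sample_signal <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("expected a 'synthetic_spec'")
  set.seed(spec$seed)
  shells <- build_shells(spec$shape, spec$voxel_size)
  amp <- component_amplitude(spec, "signal")
  g <- draw_shaped_field(spec$shape, spec$voxel_size, amp)
  list(grid = g, lam2 = (amp^2)[seq_len(shells$n_shells)],
       lam2_full = amp^2, shells = shells)
}

#' Sample a noisy measurement with ground truth
#'
#' Draws \code{y = x + noise}: the signal from the spec's signal profile
#' (or the deterministic phantom if \code{base = "phantom"}) and Gaussian
#' noise shaped by the noise profile, scaled so that the expected
#' real-space variance ratio Var(x)/Var(noise) equals \code{spec$snr}.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a list with \code{y} (the measurement), and a \code{truth}
#'   list carrying \code{x}, \code{noise}, \code{lam2}, \code{sig2} (true
#'   per-shell variances on the Nyquist-ball shells), \code{lam2_full},
#'   \code{sig2_full} and \code{shells}.
#' @export
sample_measurement <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stop("expected a 'synthetic_spec'")
  set.seed(spec$seed)
  shells <- build_shells(spec$shape, spec$voxel_size)
  labels <- as.integer(round(sqrt(radial_index_sq(spec$shape))))
  amp_n <- component_amplitude(spec, "noise")
  if (spec$base == "phantom") {
    x <- phantom(spec$shape, spec$voxel_size)
    coef <- ufft(x$values)
    lam2_full <- (shell_sum(Re(coef)^2 + Im(coef)^2,
                            full_binning(spec$shape, spec$voxel_size)) /
                    tabulate(labels + 1L, nbins = full_label_count(spec$shape)))
    var_x <- mean(x$values^2)
  } else {
    amp_s <- component_amplitude(spec, "signal")
    x <- draw_shaped_field(spec$shape, spec$voxel_size, amp_s)
    lam2_full <- amp_s^2
    var_x <- mean(lam2_full[labels + 1L])  # expected, by Parseval
  }
  var_n0 <- mean((amp_n^2)[labels + 1L])
  scale_n <- sqrt(var_x / (spec$snr * var_n0))
  noise <- draw_shaped_field(spec$shape, spec$voxel_size, scale_n * amp_n)
  sig2_full <- (scale_n * amp_n)^2
  y <- real_grid(x$values + noise$values, spec$voxel_size)
  list(y = y,
       truth = list(x = x, noise = noise,
                    lam2 = lam2_full[seq_len(shells$n_shells)],
                    sig2 = sig2_full[seq_len(shells$n_shells)],
                    lam2_full = lam2_full, sig2_full = sig2_full,
                    shells = shells))
}

## Binning over the full index cube (no Nyquist-ball exclusion), used to
## tabulate per-label power of deterministic signals.
full_binning <- function(shape, voxel_size) {
  labels <- as.integer(round(sqrt(radial_index_sq(shape))))
  n_shells <- max(labels) + 1L
  sel <- seq_along(labels)
  structure(
    list(shape = as.integer(shape), voxel_size = voxel_size, labels = labels,
         sel = sel, shell_id = as.vector(labels) + 1L,
         counts = tabulate(labels + 1L, nbins = n_shells),
         frequencies = (0:(n_shells - 1L)) / (min(shape) * voxel_size),
         n_shells = n_shells),
    class = "shell_binning"
  )
}

#' Sample a pair of measurements with shared signal
#'
#' One signal draw, two independent noise draws: the ground-truth FSC
#' reference against which single-measurement estimates are validated.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a list with \code{y1}, \code{y2} and the \code{truth} bundle of
#'   \code{\link{sample_measurement}}.
#' @export
sample_measurement_pair <- function(spec) {
  m <- sample_measurement(spec)  # seeds RNG; draws x and first noise
  amp_n <- component_amplitude(spec, "noise")
  nz <- which(amp_n > 0)[1L]
  scale_n <- sqrt(m$truth$sig2_full[nz]) / amp_n[nz]
  noise2 <- draw_shaped_field(spec$shape, spec$voxel_size, scale_n * amp_n)
  list(y1 = m$y,
       y2 = real_grid(m$truth$x$values + noise2$values, spec$voxel_size),
       truth = m$truth)
}

#' Deterministic compact phantom
#'
#' A reproducible scene of soft-edged spheres and a ring confined to the
#' central half of the box, with a decaying power spectrum; a stand-in for
#' a compact molecular structure when a deterministic signal is needed.
#'
#' @param shape per-axis lengths (even), d = 2 or 3.
#' @param voxel_size voxel size in Angstrom (default 0.81).
#' @return a \code{\link{real_grid}}; identical across calls.
#' @export
phantom <- function(shape, voxel_size = 1) {
  shape <- as.integer(shape)
  if (any(shape %% 2L != 0L)) stop("'shape' must be even along all axes")
  d <- length(shape)
  if (d < 2L || d > 3L) stop("phantom is defined for 2-D and 3-D grids")
  extent <- min(shape) * voxel_size
  ## fractional centers (of the box), radii and densities; all features lie
  ## well inside the central half of the box
  feats <- list(
    list(c = c(0.00, 0.00, 0.00), r = 0.140, dens = 1.0),
    list(c = c(0.12, 0.05, -0.04), r = 0.060, dens = 0.8),
    list(c = c(-0.10, 0.10, 0.06), r = 0.045, dens = 1.2),
    list(c = c(-0.05, -0.12, 0.00), r = 0.050, dens = 0.6)
  )
  edge <- 0.015 * extent
  dist_from <- function(center_frac) {
    d2 <- array(0, dim = shape)
    for (a in seq_len(d)) {
      coord <- ((0:(shape[a] - 1L)) - floor(shape[a] / 2)) * voxel_size -
        center_frac[a] * extent
      before <- if (a == 1L) 1 else prod(shape[seq_len(a - 1L)])
      d2 <- d2 + array(rep(coord^2, each = before), dim = shape)
    }
    sqrt(d2)
  }
  vals <- array(0, dim = shape)
  for (f in feats) {
    dist <- dist_from(f$c[seq_len(d)])
    vals <- vals + f$dens / (1 + exp((dist - f$r * extent) / edge))
  }
  ## a soft ring (shell) around the central sphere
  dist0 <- dist_from(rep(0, d))
  ring <- exp(-((dist0 - 0.19 * extent) / (0.012 * extent))^2 / 2)
  vals <- vals + 0.5 * ring
  real_grid(vals, voxel_size)
}
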