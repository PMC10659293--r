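#' Correlation curve container
#'
#' Holds one correlation value per radial shell together with the shell
#' structure it was computed on.  Undefined shells (zero norm in either
#' member) are carried as \code{NA}, never as 0.
#'
#' @param values numeric vector in [-1, 1] (or \code{NA}).
#' @param shells the \code{\link{build_shells}} object of the grid the
#'   curve was computed on.
#' @param counts per-shell coefficient counts.
#' @param corrected logical; whether the even/odd variance rescaling
#'   (\code{\link{variance_correction}}) has been applied (or the estimator
#'   targets the FSC scale directly, as the upsampled estimator does).
#' @param provenance one of \code{"fsc"}, \code{"sfsc_axis"},
#'   \code{"sfsc_mean"}, \code{"sfsc_checkerboard"},
#'   \code{"esfsc_closed_form"}, \code{"efsc_closed_form"}.
#' @return an object of class \code{correlation_curve}.
#' @export
correlation_curve <- function(values, shells, counts = shells$counts,
                              corrected = FALSE,
                              provenance = c("fsc", "sfsc_axis", "sfsc_mean",
                                             "sfsc_checkerboard",
                                             "esfsc_closed_form",
                                             "efsc_closed_form")) {
  provenance <- match.arg(provenance)
  values <- as.numeric(values)
  if (any(abs(values) > 1 + 1e-9, na.rm = TRUE)) {
    stop("correlation values must lie in [-1, 1] (Cauchy-Schwarz)")
  }
  values <- pmin(1, pmax(-1, values))
  if (corrected && !grepl("^sfsc", provenance)) {
    stop("'corrected' applies only to sfsc-provenance curves")
  }
  structure(
    list(values = values, shells = shells,
         frequencies = shells$frequencies[seq_along(values)],
         counts = counts[seq_along(values)],
         corrected = corrected, provenance = provenance),
    class = "correlation_curve"
  )
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat("correlation_curve (", x$provenance,
      if (x$corrected) ", corrected" else "", "): ",
      length(x$values), " shells\n", sep = "")
  ok <- !is.na(x$values)
  cat("  values in [", format(min(x$values[ok])), ", ",
      format(max(x$values[ok])), "], ", sum(!ok), " undefined\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(
    shell = seq_along(x$values) - 1L,
    frequency_inv_angstrom = x$frequencies,
    resolution_angstrom = ifelse(x$frequencies > 0, 1 / x$frequencies, Inf),
    value = x$values,
    count = x$counts,
    defined = !is.na(x$values)
  )
}

## Per-shell normalized cross-correlation of two coefficient arrays.
fsc_from_coefficients <- function(c1, c2, binning) {
  num <- shell_sum(Re(Conj(c1) * c2), binning)
  d1 <- shell_sum(Re(c1)^2 + Im(c1)^2, binning)
  d2 <- shell_sum(Re(c2)^2 + Im(c2)^2, binning)
  den <- sqrt(d1 * d2)
  v <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), NA_real_)
  ## numerical safety: |v| can exceed 1 by rounding only
  pmin(1, pmax(-1, v))
}

#' Fourier shell correlation of two measurements
#'
#' The standard FSC: per radial shell, the real part of the inner product
#' of the two transforms divided by the product of their norms.
#'
#' @param g1,g2 \code{\link{real_grid}} objects of identical shape and
#'   voxel size.
#' @param shells optional \code{\link{build_shells}} for that shape.
#' @return a \code{\link{correlation_curve}} with provenance \code{"fsc"}.
#' @export
fsc <- function(g1, g2, shells = NULL) {
  stopifnot_real_grid(g1); stopifnot_real_grid(g2)
  if (!identical(g1$shape, g2$shape)) stop("grids have different shapes")
  if (!isTRUE(all.equal(g1$voxel_size, g2$voxel_size))) {
    stop("grids have different voxel sizes")
  }
  if (is.null(shells)) shells <- build_shells(g1$shape, g1$voxel_size)
  check_shells_match(g1, shells)
  v <- fsc_from_coefficients(ufft(g1$values), ufft(g2$values), shells)
  correlation_curve(v, shells, provenance = "fsc")
}

## Shell binning for the members of a split pair: index-radial shells on
## the downsampled shape with an effective voxel of twice the parent's, so
## that (for cubic parents) shell r sits at frequency r/(N_parent * V).
split_binning <- function(pair) {
  build_shells(dim(pair$first), 2 * pair$parent_voxel)
}

sfsc_one_axis <- function(g, axis, align = TRUE) {
  pair <- split_even_odd(g, axis)
  f1 <- ufft(pair$first)
  f2 <- ufft(pair$second)
  if (align) {
    f2 <- apply_half_voxel_phase(f2, axis, pair$parent_shape[axis])
  }
  binning <- split_binning(pair)
  list(values = fsc_from_coefficients(f1, f2, binning), binning = binning)
}

#' Self Fourier shell correlation of a single measurement
#'
#' Estimates an FSC-like curve from one noisy measurement.  For the default
#' per-axis scheme the measurement is decimated into even and odd samples
#' along each axis in turn, the odd member is phase-aligned by the
#' half-voxel translation, the FSC of each pair is computed on the shells
#' of the downsampled grid, and the reported curve is the unweighted mean
#' of the per-axis curves (shells undefined on an axis are excluded from
#' its mean).  The raw curve estimates the ESFSC, which under white noise
#' and a rapidly decaying signal spectrum approximates the FSC with a
#' doubled noise variance; apply \code{\link{variance_correction}} to map
#' it onto the FSC scale.
#'
#' The checkerboard scheme decimates all axes at once into the all-even and
#' all-odd parity classes (with the corresponding diagonal half-voxel
#' alignment) and inflates the noise variance by \code{2^d}; it is kept as
#' a comparison mode.
#'
#' @param g a \code{\link{real_grid}} with even axis lengths.
#' @param scheme \code{"axis"} (default) or \code{"checkerboard"}.
#' @param align apply the phase-shift alignment (default \code{TRUE};
#'   disabling it is only useful for diagnostics).
#' @return a \code{\link{correlation_curve}} with provenance
#'   \code{"sfsc_mean"} (or \code{"sfsc_axis"} in 1-D,
#'   \code{"sfsc_checkerboard"} for the checkerboard scheme) and
#'   \code{corrected = FALSE}.
#' @export
sfsc <- function(g, scheme = c("axis", "checkerboard"), align = TRUE) {
  stopifnot_real_grid(g)
  scheme <- match.arg(scheme)
  if (any(g$shape %% 2L != 0L)) {
    stop("all axis lengths must be even; crop the grid explicitly first")
  }
  d <- grid_ndim(g)
  if (scheme == "checkerboard") {
    pair <- split_checkerboard(g)
    f1 <- ufft(pair$first)
    f2 <- ufft(pair$second)
    if (align) {
      for (a in seq_len(d)) {
        f2 <- apply_half_voxel_phase(f2, a, pair$parent_shape[a])
      }
    }
    binning <- split_binning(pair)
    v <- fsc_from_coefficients(f1, f2, binning)
    return(correlation_curve(v, binning, provenance = "sfsc_checkerboard"))
  }
  per_axis <- lapply(seq_len(d), function(a) sfsc_one_axis(g, a, align = align))
  n_common <- min(vapply(per_axis, function(z) z$binning$n_shells, 1L))
  vals <- vapply(per_axis, function(z) z$values[seq_len(n_common)],
                 numeric(n_common))
  vals <- matrix(vals, nrow = n_common)
  mean_v <- rowMeans(vals, na.rm = TRUE)
  mean_v[!is.finite(mean_v)] <- NA_real_
  binning <- per_axis[[1L]]$binning
  counts <- rowSums(vapply(per_axis, function(z) z$binning$counts[seq_len(n_common)],
                           numeric(n_common)))
  correlation_curve(mean_v, binning, counts = counts,
                    provenance = if (d == 1L) "sfsc_axis" else "sfsc_mean")
}

#' Variance rescaling of the self FSC
#'
#' Maps a raw SFSC curve onto the FSC scale.  Under white noise and a
#' rapidly decaying signal spectrum the SFSC expectation approximates the
#' FSC with the noise variance doubled; the rescaling
#' \code{2 v / (1 + v)} per shell removes the doubling.
#'
#' @param c a raw (uncorrected) \code{\link{correlation_curve}} of sfsc
#'   provenance.
#' @return the corrected curve; undefined shells propagate, and a shell at
#'   exactly -1 (the pole of the map) becomes undefined.
#' @export
variance_correction <- function(c) {
  if (!inherits(c, "correlation_curve")) stop("expected a 'correlation_curve'")
  if (!c$provenance %in% c("sfsc_axis", "sfsc_mean", "sfsc_checkerboard",
                           "esfsc_closed_form")) {
    stop("variance correction applies to sfsc curves, not '", c$provenance, "'")
  }
  if (isTRUE(c$corrected)) {
    stop("curve is already corrected; applying the rescaling twice is an error")
  }
  v <- c$values
  pole <- !is.na(v) & v <= -1 + 1e-12
  v[pole] <- NA_real_
  out <- c
  out$values <- ifelse(is.na(v), NA_real_, 2 * v / (1 + v))
  out$values <- pmin(1, pmax(-1, out$values))
  out$corrected <- TRUE
  out
}

#' Closed-form expected self FSC (1-D decimation identity)
#'
#' Expectation-ratio of the aligned even/odd correlation under the
#' diagonal Gaussian model, evaluated per frequency index k of the
#' downsampled grid with aliasing partner \code{N/2 - k} on the parent
#' shells:
#' \deqn{(\lambda^2[k] - \lambda^2[p] + \sigma^2[k] - \sigma^2[p]) /
#'       (\lambda^2[k] + \lambda^2[p] + \sigma^2[k] + \sigma^2[p]).}
#'
#' @param lam2 numeric vector of per-shell signal variances on the parent
#'   grid's shells (index r+1 holds shell r), covering shells 0..N/2.
#' @param sig2 per-shell noise variances on the same shells.
#' @param parent_length parent grid length N (even); defaults to
#'   \code{2 * (length(lam2) - 1)}.
#' @param shells optional \code{\link{build_shells}} object for the
#'   downsampled grid, attached to the returned curve for plotting.
#' @return a \code{\link{correlation_curve}} over downsampled shells
#'   0..N/4 with provenance \code{"esfsc_closed_form"}.
#' @export
esfsc_closed_form <- function(lam2, sig2, parent_length = 2L * (length(lam2) - 1L),
                              shells = NULL) {
  if (length(lam2) != length(sig2)) stop("profile lengths differ")
  n <- as.integer(parent_length)
  if (n %% 2L != 0L) stop("'parent_length' must be even")
  half <- n %/% 2L
  if (length(lam2) < half + 1L) {
    stop("profiles must cover parent shells 0..", half)
  }
  ks <- 0:(half %/% 2L)
  partner <- half - ks
  num <- lam2[ks + 1L] - lam2[partner + 1L] + sig2[ks + 1L] - sig2[partner + 1L]
  den <- lam2[ks + 1L] + lam2[partner + 1L] + sig2[ks + 1L] + sig2[partner + 1L]
  v <- ifelse(den > 0, num / den, NA_real_)
  if (is.null(shells)) shells <- build_shells(rep(half, 1L), 2)
  correlation_curve(v[seq_len(min(length(v), shells$n_shells))], shells,
                    provenance = "esfsc_closed_form")
}

#' Closed-form expected FSC
#'
#' The deterministic expectation-ratio analogue of the FSC under the
#' diagonal Gaussian model: \code{lam2 / (lam2 + sig2)} per shell.
#'
#' @param lam2,sig2 per-shell signal and noise variances.
#' @param shells optional \code{\link{build_shells}} matching the profiles.
#' @return a \code{\link{correlation_curve}} with provenance
#'   \code{"efsc_closed_form"}.
#' @export
efsc_closed_form <- function(lam2, sig2, shells = NULL) {
  if (length(lam2) != length(sig2)) stop("profile lengths differ")
  den <- lam2 + sig2
  v <- ifelse(den > 0, lam2 / den, NA_real_)
  if (is.null(shells)) shells <- build_shells(rep(2L * (length(lam2) - 1L), 1L), 1)
  correlation_curve(v[seq_len(min(length(v), shells$n_shells))], shells,
                    provenance = "efsc_closed_form")
}

#' Exact expected SFSC on a grid (geometric aliasing partners)
#'
#' Ratio-of-expectations oracle for \code{\link{sfsc}} on a d-dimensional
#' grid: for every retained coefficient of each downsampled grid the true
#' aliasing partner index \code{k + (N_a/2) e_a} is enumerated, per-shell
#' expectations of numerator and denominator are summed, and the per-axis
#' ratio curves are averaged.  Used as the Monte-Carlo oracle in tests;
#' requires variance profiles over all parent shell labels including the
#' corner shells outside the inscribed ball.
#'
#' @param lam2_full,sig2_full numeric vectors indexed by parent shell label
#'   (entry r+1 is label r) covering labels 0..max over the full index cube.
#' @param shape parent grid shape (even lengths).
#' @param voxel_size parent voxel size in Angstrom.
#' @param order 1 for the plain ratio of expectations; 2 (default) adds the
#'   second-order (delta method) finite-shell correction for the expectation
#'   of the normalized correlation, which matters on shells with few
#'   coefficients.
#' @return a \code{\link{correlation_curve}} with provenance
#'   \code{"esfsc_closed_form"} on the downsampled shells.
#' @export
esfsc_expected_grid <- function(lam2_full, sig2_full, shape, voxel_size = 1,
                                order = 2L) {
  shape <- as.integer(shape)
  if (any(shape %% 2L != 0L)) stop("parent shape must be even")
  d <- length(shape)
  per_axis <- vector("list", d)
  for (a in seq_len(d)) {
    down <- shape
    down[a] <- down[a] %/% 2L
    binning <- build_shells(down, 2 * voxel_size)
    ## signed index arrays of the downsampled grid
    karr <- lapply(seq_len(d), function(b) {
      before <- if (b == 1L) 1 else prod(down[seq_len(b - 1L)])
      array(rep(axis_freq(down[b]), each = before), dim = down)
    })
    k2_direct <- Reduce(`+`, lapply(karr, function(z) z^2))
    pa <- karr[[a]] + shape[a] %/% 2L
    pa <- ((pa + shape[a] %/% 2L) %% shape[a]) - shape[a] %/% 2L  # wrap signed
    k2_partner <- k2_direct - karr[[a]]^2 + pa^2
    lab_d <- as.integer(round(sqrt(k2_direct))) + 1L
    lab_p <- as.integer(round(sqrt(k2_partner))) + 1L
    if (max(lab_d, lab_p) > length(lam2_full)) {
      stop("profiles must cover parent shell labels up to ",
           max(lab_d, lab_p) - 1L)
    }
    va <- lam2_full[lab_d] + sig2_full[lab_d]      # direct-coefficient variance
    vb <- lam2_full[lab_p] + sig2_full[lab_p]      # aliasing-partner variance
    dim(va) <- down; dim(vb) <- down
    ## per-shell first moments of numerator and (equal) denominators, in
    ## units of half the coefficient variance
    mu_n <- shell_sum((va - vb) / 2, binning)
    mu_d <- shell_sum((va + vb) / 2, binning)
    v <- ifelse(mu_d > 0, mu_n / mu_d, NA_real_)
    if (order >= 2L) {
      ## second moments per coefficient; shell sums doubled because
      ## conjugate index pairs contribute identically
      var_n <- 2 * shell_sum((va^2 + vb^2) / 4, binning)
      var_d <- 2 * shell_sum((va^2 + vb^2) / 4 + va * vb / 2, binning)
      cov_dd <- 2 * shell_sum((va^2 + vb^2) / 4 - va * vb / 2, binning)
      cov_nd <- 2 * shell_sum((va^2 - vb^2) / 4, binning)
      corr <- (mu_n / mu_d) * ((3 / 4) * var_d + (1 / 4) * cov_dd) / mu_d^2 -
        cov_nd / mu_d^2
      v <- ifelse(mu_d > 0, v + corr, v)
    }
    per_axis[[a]] <- list(values = pmin(1, pmax(-1, v)), binning = binning)
  }
  n_common <- min(vapply(per_axis, function(z) z$binning$n_shells, 1L))
  vals <- vapply(per_axis, function(z) z$values[seq_len(n_common)],
                 numeric(n_common))
  v <- rowMeans(matrix(vals, nrow = n_common), na.rm = TRUE)
  v[!is.finite(v)] <- NA_real_
  correlation_curve(v, per_axis[[1L]]$binning, provenance = "esfsc_closed_form")
}

#' Upsampled self FSC with noise subtraction
#'
#' Estimator for measurements whose (whitened) signal spectrum decays
#' slowly.  The whitened measurement is upsampled by zero-padding in
#' Fourier space, so every aliasing partner created by decimation carries
#' zero variance; the known flat noise level is then subtracted from the
#' per-shell correlation numerator.  The resulting curve targets the FSC
#' scale directly (no variance rescaling needed).
#'
#' The caller must supply a whitened measurement: per-coefficient noise
#' variance 1 in the unitary convention (\code{\link{whiten}} guarantees
#' this).  \code{gamma} is the subtraction constant in whitened parent
#' units; the default 1/4 is the value that makes the estimator's
#' expectation equal the expected FSC, and the internal bookkeeping
#' converts it to the scale of the upsampled, decimated coefficients.
#'
#' @param g_whitened a whitened \code{\link{real_grid}} with even axis
#'   lengths.
#' @param gamma noise subtraction constant in whitened units (default 1/4;
#'   0 disables the subtraction, for diagnostics).
#' @return a \code{\link{correlation_curve}} on shells up to the original
#'   Nyquist frequency with \code{corrected = TRUE} and provenance
#'   \code{"sfsc_mean"}.
#' @export
sfsc_upsampled <- function(g_whitened, gamma = 0.25) {
  stopifnot_real_grid(g_whitened)
  if (any(g_whitened$shape %% 2L != 0L)) {
    stop("all axis lengths must be even")
  }
  d <- grid_ndim(g_whitened)
  up <- zero_pad_upsample(g_whitened, 2L)
  ## per-coefficient noise bias of the aligned even/odd correlation, in the
  ## units of the unitary transforms of the decimated upsampled grid:
  ## upsampling scales coefficient variance by 2^d and decimation halves it,
  ## so a whitened-units gamma of sigma^2/4 corresponds to gamma * 2^(d+1).
  gamma_eff <- gamma * 2^(d + 1)
  per_axis <- vector("list", d)
  for (a in seq_len(d)) {
    pair <- split_even_odd(up, a)
    f1 <- ufft(pair$first)
    f2 <- apply_half_voxel_phase(ufft(pair$second), a, pair$parent_shape[a])
    binning <- split_binning(pair)
    num <- shell_sum(Re(Conj(f1) * f2), binning) - binning$counts * gamma_eff
    d1 <- shell_sum(Re(f1)^2 + Im(f1)^2, binning)
    d2 <- shell_sum(Re(f2)^2 + Im(f2)^2, binning)
    den <- sqrt(d1 * d2)
    v <- ifelse(den > 0, num / den, NA_real_)
    per_axis[[a]] <- list(values = pmin(1, pmax(-1, v)), binning = binning)
  }
  n_common <- min(vapply(per_axis, function(z) z$binning$n_shells, 1L))
  vals <- vapply(per_axis, function(z) z$values[seq_len(n_common)],
                 numeric(n_common))
  v <- rowMeans(matrix(vals, nrow = n_common), na.rm = TRUE)
  v[!is.finite(v)] <- NA_real_
  binning <- per_axis[[1L]]$binning
  correlation_curve(v, binning, corrected = TRUE, provenance = "sfsc_mean")
}
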