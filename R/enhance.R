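#' Convert a correlation curve to per-shell SSNR
#'
#' Uses the expectation-level identity between the FSC and the spectral
#' signal-to-noise ratio: \code{SSNR = c / (1 - c)} per shell.  Negative
#' correlation values carry no usable signal estimate and are clamped at
#' zero; a value of exactly 1 means infinite SSNR and is returned as
#' \code{Inf}.
#'
#' @param c a \code{\link{correlation_curve}} (on the FSC scale, i.e.
#'   corrected, for sfsc provenance).
#' @return a \code{\link{radial_profile}} of kind \code{"ssnr"} with
#'   attribute \code{"clamped"} marking shells clamped at zero.
#' @export
ssnr_from_fsc <- function(c) {
  if (!inherits(c, "correlation_curve")) stop("expected a 'correlation_curve'")
  v <- c$values
  clamped <- !is.na(v) & v < 0
  v[clamped] <- 0
  out <- ifelse(is.na(v), NA_real_, ifelse(v >= 1, Inf, v / (1 - v)))
  prof <- radial_profile(ifelse(is.na(out), 0, out), c$shells, kind = "ssnr")
  prof$values <- out
  attr(prof, "clamped") <- clamped
  prof
}

#' Resolution at a correlation threshold
#'
#' Scans the curve from low to high frequency for the first crossing of
#' the threshold from above, interpolates linearly in frequency between
#' the bracketing shells, and reports the inverse frequency in Angstrom.
#' If the curve never drops below the threshold the Nyquist resolution
#' (\code{2 * voxel size}) is returned with flag \code{"nyquist"}; if it
#' is already below the threshold at the first defined shell the
#' resolution is undefined (flag \code{"below_at_first_shell"}).
#'
#' @param c a \code{\link{correlation_curve}} defined on at least 2 shells.
#' @param threshold correlation threshold, default 1/7 (the single-map
#'   convention; 1/7 corresponds to a per-shell SSNR of 1/6).
#' @return a list with \code{resolution_angstrom}, \code{frequency}
#'   (1/Angstrom) and \code{flag} (\code{"crossed"}, \code{"nyquist"} or
#'   \code{"below_at_first_shell"}).
#' @export
resolution_at_threshold <- function(c, threshold = 1 / 7) {
  if (!inherits(c, "correlation_curve")) stop("expected a 'correlation_curve'")
  ok <- which(!is.na(c$values))
  if (length(ok) < 2L) stop("curve must be defined on at least 2 shells")
  v <- c$values[ok]
  f <- c$frequencies[ok]
  if (v[1L] < threshold) {
    return(list(resolution_angstrom = NA_real_, frequency = NA_real_,
                flag = "below_at_first_shell"))
  }
  below <- which(v < threshold)
  if (length(below) == 0L) {
    fmax <- max(c$shells$frequencies)
    return(list(resolution_angstrom = 1 / fmax, frequency = fmax,
                flag = "nyquist"))
  }
  j <- below[1L]
  i <- j - 1L
  fc <- f[i] + (v[i] - threshold) / (v[i] - v[j]) * (f[j] - f[i])
  list(resolution_angstrom = 1 / fc, frequency = fc, flag = "crossed")
}

#' Data-driven Wiener filter from a correlation curve
#'
#' Weights each Fourier shell of the measurement by the estimated expected
#' FSC, which equals the minimum mean-square-error (Wiener) gain
#' \code{SSNR / (1 + SSNR)}.  The curve (typically a corrected SFSC
#' computed on a decimated or upsampled grid) is mapped onto the
#' measurement's shells by linear interpolation in physical frequency;
#' shells beyond the curve's frequency range, including corner
#' frequencies, receive zero gain.  Gains are clamped to [0, 1]; negative
#' correlations carry no usable gain.
#'
#' @param g the \code{\link{real_grid}} to filter.
#' @param c a \code{\link{correlation_curve}} on the FSC scale
#'   (\code{corrected = TRUE} for sfsc provenance).
#' @param apply_cutoff also apply a hard low-pass at the resolution where
#'   the curve crosses 1/7 (default \code{FALSE}).
#' @return an object of class \code{wiener_result} with elements
#'   \code{filtered} (\code{real_grid}), \code{gain}
#'   (\code{\link{radial_profile}} of kind \code{"correlation_gain"}),
#'   \code{cutoff_used} (Angstrom or \code{NA}) and \code{source_curve}.
#' @export
wiener_filter <- function(g, c, apply_cutoff = FALSE) {
  stopifnot_real_grid(g)
  if (!inherits(c, "correlation_curve")) stop("expected a 'correlation_curve'")
  if (grepl("^sfsc", c$provenance) && !isTRUE(c$corrected)) {
    stop("raw sfsc curves double-count the noise; apply variance_correction() ",
         "first (or use sfsc_upsampled, which is already on the FSC scale)")
  }
  shells <- build_shells(g$shape, g$voxel_size)
  ok <- !is.na(c$values)
  if (sum(ok) < 2L) stop("curve has fewer than 2 defined shells")
  gain_shell <- stats::approx(x = c$frequencies[ok],
                              y = pmin(1, pmax(0, c$values[ok])),
                              xout = shells$frequencies, rule = 2)$y
  gain_shell[shells$frequencies > max(c$frequencies[ok]) * (1 + 1e-12)] <- 0
  cutoff_used <- NA_real_
  filtered <- apply_gain(g, gain_shell, length(gain_shell))
  if (apply_cutoff) {
    res <- resolution_at_threshold(c, 1 / 7)
    if (res$flag != "below_at_first_shell" &&
        res$resolution_angstrom >= 2 * g$voxel_size) {
      filtered <- lowpass(filtered, res$resolution_angstrom)
      cutoff_used <- res$resolution_angstrom
    }
  }
  structure(
    list(filtered = filtered,
         gain = radial_profile(gain_shell, shells, kind = "correlation_gain"),
         cutoff_used = cutoff_used, source_curve = c),
    class = "wiener_result"
  )
}

## Multiply coefficients shell-wise by a gain vector (corner indices
## beyond the ball get zero gain).
apply_gain <- function(g, gain, n_shells) {
  labels <- as.integer(round(sqrt(radial_index_sq(g$shape))))
  garr <- ifelse(labels + 1L <= n_shells, gain[pmin(labels + 1L, n_shells)], 0)
  garr[labels + 1L > n_shells] <- 0
  dim(garr) <- g$shape
  real_grid(Re(uifft(ufft(g$values) * garr)), g$voxel_size)
}

#' @export
print.wiener_result <- function(x, ...) {
  cat("wiener_result: filtered ", paste(x$filtered$shape, collapse = " x "),
      " grid", sep = "")
  if (!is.na(x$cutoff_used)) cat(", low-pass at ", format(x$cutoff_used), " A", sep = "")
  cat("\n  gain range [", format(min(x$gain$values)), ", ",
      format(max(x$gain$values)), "]\n", sep = "")
  invisible(x)
}

#' Check the spectral assumptions behind the self FSC
#'
#' The raw (variance-corrected) SFSC is only a faithful FSC estimate when
#' the noise is white and the signal spectrum decays rapidly.  Both are
#' visible in the spherically averaged power spectrum: white noise makes
#' the upper half of the spectrum approximately flat, and rapid signal
#' decay makes the lower half much stronger than the upper half.  This
#' diagnostic reports the coefficient of variation of the upper-half
#' shells (flat if below \code{cv_threshold}) and the low/high power
#' ratio, and recommends preprocessing accordingly: whitening when the
#' tail is not flat, upsampling when it is flat but the spectrum decays
#' slowly.
#'
#' @param g a \code{\link{real_grid}}.
#' @param cv_threshold flatness threshold on the coefficient of variation
#'   of the upper-half shells (default 0.1).
#' @param decay_threshold minimum low/high mean power ratio regarded as
#'   rapid decay (default 10).
#' @return a list with \code{flat} (logical), \code{cv_upper},
#'   \code{decay_ratio}, \code{recommendation} (character vector, possibly
#'   empty) and the \code{power} profile.
#' @export
diagnose <- function(g, cv_threshold = 0.1, decay_threshold = 10) {
  stopifnot_real_grid(g)
  ps <- radial_power_spectrum(g)
  n <- length(ps$values)
  upper <- ps$values[(floor(n / 2) + 1L):n]
  lower <- ps$values[2:max(2L, floor(n / 2))]
  cv <- stats::sd(upper) / mean(upper)
  decay_ratio <- mean(lower) / mean(upper)
  flat <- is.finite(cv) && cv < cv_threshold
  rec <- character(0)
  if (!flat) rec <- c(rec, "whiten")
  if (flat && decay_ratio < decay_threshold) rec <- c(rec, "upsample")
  list(flat = flat, cv_upper = cv, decay_ratio = decay_ratio,
       recommendation = rec, power = ps)
}
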