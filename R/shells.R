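#' Radial shell binning of Fourier indices
#'
#' Partitions the centered DFT indices of a grid into radial shells.  The
#' shell label of index k is \code{round(||k||)} using signed centered
#' integer frequencies per axis; indices beyond the inscribed Nyquist ball
#' (\code{||k|| > min(shape)/2}) are excluded, since shells there are
#' incomplete and anisotropic.  Shell r corresponds to the physical spatial
#' frequency \code{r / (min(shape) * voxel_size)} in 1/Angstrom.
#'
#' @param shape integer vector of per-axis lengths (all >= 2).
#' @param voxel_size sampling interval in Angstrom.
#' @return an object of class \code{shell_binning} with elements
#'   \code{shape}, \code{voxel_size}, \code{labels} (integer array over the
#'   full grid, \code{NA} outside the Nyquist ball), \code{sel} (linear
#'   indices of retained coefficients), \code{shell_id} (1-based shell of
#'   each retained coefficient), \code{counts}, \code{frequencies} (1/A at
#'   each shell), and \code{n_shells}.
#' @examples
#' b <- build_shells(c(4, 4), voxel_size = 1)
#' b$counts
#' @export
build_shells <- function(shape, voxel_size = 1) {
  shape <- as.integer(shape)
  if (any(shape < 2L)) stop("all axis lengths must be >= 2")
  if (voxel_size <= 0) stop("'voxel_size' must be positive")
  kn <- sqrt(radial_index_sq(shape))
  labels <- as.integer(round(kn))
  labels[kn > min(shape) / 2] <- NA_integer_
  sel <- which(!is.na(labels))
  shell_id <- labels[sel] + 1L
  n_shells <- max(shell_id)
  counts <- tabulate(shell_id, nbins = n_shells)
  freqs <- (seq_len(n_shells) - 1) / (min(shape) * voxel_size)
  structure(
    list(shape = shape, voxel_size = voxel_size, labels = labels,
         sel = sel, shell_id = shell_id, counts = counts,
         frequencies = freqs, n_shells = n_shells),
    class = "shell_binning"
  )
}

#' @export
print.shell_binning <- function(x, ...) {
  cat("shell_binning: ", paste(x$shape, collapse = " x "),
      " grid, ", x$n_shells, " shells, max frequency ",
      format(max(x$frequencies)), " 1/A\n", sep = "")
  invisible(x)
}

## Sum of a real array over shells; returns one value per shell.
shell_sum <- function(x, binning) {
  v <- x[binning$sel]
  out <- numeric(binning$n_shells)
  s <- rowsum(v, binning$shell_id)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

check_shells_match <- function(g, binning) {
  if (!identical(as.integer(g$shape), as.integer(binning$shape))) {
    stop("grid shape (", paste(g$shape, collapse = "x"),
         ") does not match shell binning shape (",
         paste(binning$shape, collapse = "x"), ")")
  }
  invisible(TRUE)
}

#' Radial profile container
#'
#' One real value per radial shell, used for power spectra, per-shell noise
#' variances, SSNR curves and Wiener gains.
#'
#' @param values numeric vector, one entry per shell.
#' @param shells the \code{\link{build_shells}} object the values refer to.
#' @param kind one of \code{"power"}, \code{"noise_variance"},
#'   \code{"ssnr"}, \code{"correlation_gain"}.
#' @return an object of class \code{radial_profile}.
#' @export
radial_profile <- function(values, shells,
                           kind = c("power", "noise_variance", "ssnr",
                                    "correlation_gain")) {
  kind <- match.arg(kind)
  if (length(values) != shells$n_shells) {
    stop("profile length (", length(values), ") does not match number of shells (",
         shells$n_shells, ")")
  }
  if (kind %in% c("power", "noise_variance") && any(values < 0, na.rm = TRUE)) {
    stop(kind, " profiles must be nonnegative")
  }
  structure(
    list(values = as.numeric(values), shells = shells,
         frequencies = shells$frequencies, kind = kind),
    class = "radial_profile"
  )
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("radial_profile (", x$kind, "): ", length(x$values), " shells\n", sep = "")
  invisible(x)
}

#' Spherically averaged power spectrum
#'
#' Mean of \code{|coefficient|^2} over each radial shell under the unitary
#' transform convention, so white noise of unit variance gives a flat
#' profile near 1.  The mean (rather than the shell sum) is used so the
#' profile is directly comparable to per-coefficient variances; all
#' consumers use it ratio-wise.
#'
#' @param g a \code{\link{real_grid}}.
#' @param shells a \code{\link{build_shells}} object built for \code{g}'s
#'   shape; built on the fly when omitted.
#' @return a \code{\link{radial_profile}} of kind \code{"power"}.
#' @export
radial_power_spectrum <- function(g, shells = NULL) {
  stopifnot_real_grid(g)
  if (is.null(shells)) shells <- build_shells(g$shape, g$voxel_size)
  check_shells_match(g, shells)
  coef <- ufft(g$values)
  p <- shell_sum(Re(coef)^2 + Im(coef)^2, shells) / shells$counts
  radial_profile(p, shells, kind = "power")
}
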