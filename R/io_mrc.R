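## MRC/CCP4 volume input/output.
##
## Minimal, self-contained reader/writer for the 1024-byte MRC2014 header
## plus raw data block, supporting modes 0 (int8), 1 (int16) and 2
## (float32), little-endian.  The header's axis-order words (mapc/mapr/maps)
## are honored on read; data are written in storage order with axis order
## 1,2,3 and no silent transposition.

MRC_HEADER_BYTES <- 1024L

#' Read a volume or 1-D signal
#'
#' Reads an MRC/CCP4 file (modes 0, 1 and 2) into a
#' \code{\link{real_grid}}, taking the voxel size from the header cell
#' dimensions.  Files whose name ends in \code{.txt}, \code{.dat} or
#' \code{.csv} are read as single-column text and returned as a 1-D grid.
#'
#' @param path file to read.
#' @param voxel_size override for the voxel size in Angstrom; required when
#'   an MRC header carries a zero cell (voxel size cannot be inferred).
#' @return a \code{\link{real_grid}}.
#' @export
read_volume <- function(path, voxel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(txt|dat|csv)$", path, ignore.case = TRUE)) {
    v <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#",
              sep = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "")
    return(real_grid(v, if (is.null(voxel_size)) 1 else voxel_size))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_ints <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr_ints[1L]; ny <- hdr_ints[2L]; nz <- hdr_ints[3L]
  mode <- hdr_ints[4L]
  mx <- hdr_ints[8L]; my <- hdr_ints[9L]; mz <- hdr_ints[10L]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  if (any(c(nx, ny, nz) < 1L) || any(c(nx, ny, nz) > 1e5)) {
    stop("corrupted MRC header in ", path, ": grid size ",
         paste(c(nx, ny, nz), collapse = "x"))
  }
  if (!mode %in% c(0L, 1L, 2L)) {
    stop("unsupported MRC mode ", mode, " in ", path,
         " (modes 0, 1 and 2 are supported)")
  }
  seek(con, 64L)  # words 17..19: mapc, mapr, maps
  axis_order <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  if (!setequal(axis_order, 1:3)) axis_order <- 1:3
  v <- if (mx > 0) cella[1L] / mx else 0
  if (v <= 0) {
    if (is.null(voxel_size)) {
      stop("MRC header of ", path, " has a zero cell; pass an explicit ",
           "voxel_size override")
    }
    v <- voxel_size
  } else if (!is.null(voxel_size)) {
    v <- voxel_size
  }
  seek(con, MRC_HEADER_BYTES)
  n <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1L, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4L, endian = "little"))
  if (length(data) < n) stop("truncated MRC data block in ", path)
  arr <- array(as.numeric(data), dim = c(nx, ny, nz))
  if (!identical(axis_order, 1:3)) arr <- aperm(arr, order(axis_order))
  dims <- dim(arr)
  ## drop trailing singleton axes (1-D signals and 2-D images stored as MRC)
  while (length(dims) > 1L && dims[length(dims)] == 1L) {
    dims <- dims[-length(dims)]
  }
  dim(arr) <- dims
  real_grid(arr, v)
}

#' Write a grid as MRC (mode 2, float32)
#'
#' @param g a \code{\link{real_grid}} (1-D grids are written as Nx1x1).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(g, path) {
  stopifnot_real_grid(g)
  shape3 <- c(g$shape, rep(1L, 3L - grid_ndim(g)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(shape3, 2L, 0L, 0L, 0L, shape3)), con, size = 4L,
           endian = "little")                                   # words 1..10
  writeBin(as.numeric(shape3) * g$voxel_size, con, size = 4L,
           endian = "little")                                   # cella
  writeBin(rep(90, 3), con, size = 4L, endian = "little")       # cellb
  writeBin(1:3, con, size = 4L, endian = "little")              # mapc/r/s
  stats_v <- c(min(g$values), max(g$values), mean(g$values))
  writeBin(as.numeric(stats_v), con, size = 4L, endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")        # ispg, nsymbt
  writeBin(raw(100L), con)                                      # extra
  writeBin(rep(0, 3), con, size = 4L, endian = "little")        # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)              # machst LE
  writeBin(as.numeric(stats::sd(g$values)), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")               # nlabl
  writeBin(raw(800L), con)                                      # labels
  writeBin(as.numeric(g$values), con, size = 4L, endian = "little")
  invisible(path)
}

#' Write a correlation curve or radial profile as CSV
#'
#' Canonical plotting format with fixed column order \code{shell},
#' \code{frequency_inv_angstrom}, \code{resolution_angstrom},
#' \code{value}, \code{count}, \code{defined}.
#'
#' @param x a \code{\link{correlation_curve}}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a correlation curve as JSON with provenance metadata
#'
#' @param x a \code{\link{correlation_curve}}.
#' @param path output JSON file.
#' @param extra named list of additional metadata (e.g. seed, parameters).
#' @return \code{path}, invisibly.
#' @export
write_curve_json <- function(x, path, extra = list()) {
  payload <- c(list(
    provenance = x$provenance,
    corrected = x$corrected,
    shell = seq_along(x$values) - 1L,
    frequency_inv_angstrom = x$frequencies,
    value = x$values,
    count = x$counts
  ), extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Write a noise model as JSON
#'
#' @param nm a \code{\link{noise_model}}.
#' @param path output JSON file.
#' @return \code{path}, invisibly.
#' @export
write_noise_model_json <- function(nm, path) {
  payload <- list(
    method = nm$method,
    region_spec = nm$region_spec,
    frequency_inv_angstrom = nm$frequencies,
    sigma2 = nm$sigma2
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
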