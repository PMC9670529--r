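#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii`, optionally
#' gzip-compressed `.nii.gz`).  Only the features needed for parameter-map
#' exchange are implemented: 3D/4D arrays, little- or big-endian input,
#' datatypes uint8 / int16 / int32 / float32 / float64, `scl_slope`/
#' `scl_inter` scaling on read, and voxel spacing via `pixdim`.  Written
#' files carry an sform with a diagonal spacing affine so standard viewers
#' display them correctly.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_nifti()` returns a list with `data` (numeric array) and
#'   `spacing` (voxel size in mm, one entry per spatial dimension).
#' @name nifti_io
NULL

.nii_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- .nii_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 4L)
  sizeof_hdr <- readBin(hdr, "integer", n = 1L, size = 4L, endian = "little")
  endian <- if (sizeof_hdr == 348L) "little" else "big"
  if (endian == "big") {
    sizeof_hdr <- readBin(hdr, "integer", n = 1L, size = 4L, endian = "big")
  }
  if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  readBin(con, "raw", n = 36L)                       # unused header fields
  dim <- readBin(con, "integer", n = 8L, size = 2L, endian = endian)
  readBin(con, "raw", n = 14L)                       # intent params etc.
  datatype <- readBin(con, "integer", n = 1L, size = 2L, endian = endian)
  readBin(con, "integer", n = 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "integer", n = 1L, size = 2L, endian = endian)  # slice_start
  pixdim <- readBin(con, "numeric", n = 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", n = 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", n = 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", n = 1L, size = 4L, endian = endian)
  # we are at byte offset 120; skip ahead to the data block
  readBin(con, "raw", n = as.integer(vox_offset) - 120L)

  ndim <- dim[1L]
  if (ndim < 1L || ndim > 7L) stop("invalid NIfTI dim[0]: ", ndim)
  shape <- dim[2L:(1L + ndim)]
  nvox <- prod(shape)
  spec <- switch(as.character(datatype),
    "2"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "integer", size = 2L, signed = TRUE),
    "8"  = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "numeric", size = 4L, signed = TRUE),
    "64" = list(what = "numeric", size = 8L, signed = TRUE),
    stop("unsupported NIfTI datatype code: ", datatype)
  )
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != nvox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(as.numeric(vals), dim = shape),
       spacing = pixdim[2L:(1L + min(ndim, 3L))])
}

#' @rdname nifti_io
#' @param data numeric 2D/3D/4D array.
#' @param spacing voxel size in mm per spatial dimension (recycled/padded to
#'   3 values).
#' @param datatype `"float64"` (default, lossless) or `"float32"`.  Undefined voxels
#'   (`NA`) are written as quiet NaN, which viewers treat as background.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1),
                        datatype = c("float64", "float32")) {
  datatype <- match.arg(datatype)
  if (is.null(dim(data))) dim(data) <- length(data)
  ndim <- length(dim(data))
  if (ndim > 7L) stop("too many dimensions for NIfTI")
  spacing <- rep_len(as.numeric(spacing), 3L)
  dt_code <- if (datatype == "float64") 64L else 16L
  bitpix <- if (datatype == "float64") 64L else 32L
  size <- bitpix %/% 8L

  dimv <- rep(1L, 8L)
  dimv[1L] <- ndim
  dimv[2L:(1L + ndim)] <- dim(data)
  pixdim <- rep(0, 8L)
  pixdim[1L] <- 1                      # qfac
  pixdim[2L:4L] <- spacing
  if (ndim >= 4L) pixdim[5L] <- 1

  con <- .nii_connection(path, "wb")
  on.exit(close(con))
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f4 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i4(348L)                           # sizeof_hdr
  w_raw(35L)                           # data_type, db_name, extents, ...
  writeBin(as.raw(0L), con)            # dim_info
  w_i2(dimv)
  w_f4(c(0, 0, 0))                     # intent_p1..p3
  w_i2(0L)                             # intent_code
  w_i2(dt_code)
  w_i2(bitpix)
  w_i2(0L)                             # slice_start
  w_f4(pixdim)
  w_f4(352)                            # vox_offset
  w_f4(1)                              # scl_slope
  w_f4(0)                              # scl_inter
  w_i2(0L)                             # slice_end
  writeBin(as.raw(c(0L, 0L)), con)     # slice_code, xyzt_units
  w_f4(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  w_i4(c(0L, 0L))                      # glmax, glmin
  w_raw(80L + 24L)                     # descrip, aux_file
  w_i2(0L)                             # qform_code
  w_i2(2L)                             # sform_code: aligned
  w_f4(c(0, 0, 0, 0, 0, 0))            # quaternions + offsets
  w_f4(c(spacing[1], 0, 0, 0))         # srow_x
  w_f4(c(0, spacing[2], 0, 0))         # srow_y
  w_f4(c(0, 0, spacing[3], 0))         # srow_z
  w_raw(16L)                           # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL)
  writeBin(as.raw(0L), con)
  w_raw(4L)                            # extension flag
  vals <- as.numeric(data)
  vals[is.na(vals)] <- NaN
  writeBin(vals, con, size = size, endian = "little")
  invisible(path)
}

#' FSL-style b-value sidecar files
#'
#' A `.bval` file holds the b-values as one space-separated line; the signal
#' averages, which plain bval files cannot carry, round-trip through a JSON
#' sidecar written by [write_scheme_json()].
#'
#' @param scheme a [bvalue_scheme()].
#' @param path output path.
#' @export
write_bval <- function(scheme, path) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  writeLines(paste(format(scheme$b_values, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' @rdname write_bval
#' @param averages optional vector of signal averages to pair with the read
#'   b-values (defaults to one average each).
#' @return `read_bval()` returns a [bvalue_scheme()].
#' @export
read_bval <- function(path, averages = NULL) {
  b <- scan(path, quiet = TRUE)
  if (is.null(averages)) averages <- rep(1L, length(b))
  bvalue_scheme(b, averages)
}

#' @rdname write_bval
#' @export
write_scheme_json <- function(scheme, path) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  jsonlite::write_json(unclass(scheme), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bval
#' @export
read_scheme_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  bvalue_scheme(x$b_values, x$averages)
}
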