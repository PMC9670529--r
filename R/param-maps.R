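#' Multi-b-value DWI series
#'
#' Container for a stack of signal volumes indexed by b-value.  The data are
#' held as a 4D array whose fourth dimension runs over the b-values of the
#' scheme; 2D multi-slice and true 3D acquisitions share this layout (the
#' slice axis is the third dimension).
#'
#' @param scheme a [bvalue_scheme()].
#' @param data numeric 4D array `[x, y, z, b]` with `dim(data)[4] ==
#'   length(scheme)`.
#' @param spacing voxel size in mm, length 3.  Default is the
#'   1.3 x 1.3 x 3.0 mm acquisition voxel.
#' @return an object of class `dwi_series`.
#' @export
dwi_series <- function(scheme, data, spacing = c(1.3, 1.3, 3.0)) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  if (length(dim(data)) != 4L) stop("`data` must be a 4D array [x, y, z, b]")
  if (dim(data)[4L] != length(scheme)) {
    stop("fourth dimension of `data` must match the number of b-values")
  }
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive voxel sizes (mm)")
  }
  structure(list(scheme = scheme, data = data, spacing = as.numeric(spacing)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("DWI series: %d x %d x %d voxels, %d b-values (%s s/mm^2), voxel %.2g x %.2g x %.2g mm\n",
              d[1], d[2], d[3], d[4],
              paste(range(x$scheme$b_values), collapse = "-"),
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Intensity mask from the unweighted volume
#'
#' Voxels whose b = 0 intensity is lower than `fraction` times the
#' volume-wide maximum intensity are masked out; a voxel at exactly the
#' threshold stays inside ("lower than" is strict).  The maximum is taken
#' over the whole volume, not per slice.
#'
#' @param b0_volume numeric array of unweighted (b = 0) intensities.
#' @param fraction threshold as a fraction of the maximum intensity
#'   (default 0.30).
#' @return logical array of the same shape; `TRUE` inside the mask.
#' @examples
#' compute_mask(c(100, 40, 29.9))   # TRUE TRUE FALSE
#' @export
compute_mask <- function(b0_volume, fraction = 0.30) {
  if (length(b0_volume) == 0L) stop("empty volume")
  mx <- max(b0_volume, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) {
    stop("b = 0 volume has no positive maximum; cannot scale the mask threshold")
  }
  m <- !is.na(b0_volume) & (b0_volume >= fraction * mx)
  if (!is.null(dim(b0_volume))) dim(m) <- dim(b0_volume)
  m
}

#' Voxelwise segmented IVIM fit of a DWI series
#'
#' Applies the 30%-of-maximum intensity mask to the b = 0 volume, runs the
#' segmented two-step fit ([segmented_fit()]) on every masked-in voxel's
#' signal curve, and the two-point mono-exponential ADC on its (b = 0,
#' b = max) pair.  Masked-out voxels and failed fits carry the
#' undefined-voxel marker `NA`; failures are recorded (with voxel indices)
#' in the returned object, never raised, so one bad voxel cannot abort a
#' map.  Output is deterministic given the series and configuration.
#'
#' @param series a [dwi_series()].
#' @param cfg a [fit_config()].
#' @param mask_fraction fraction of the maximum b = 0 intensity below which
#'   voxels are masked out (default 0.30).
#' @return an object of class `parameter_maps`: arrays `D`, `f`, `Dp`, `ADC`
#'   (internal units mm^2/s and fraction), logical `mask`, the voxel
#'   `spacing`, and `failed` (linear indices of masked-in voxels whose fit
#'   failed).
#' @export
fit_volume <- function(series, cfg = fit_config(), mask_fraction = 0.30) {
  stopifnot(inherits(series, "dwi_series"), inherits(cfg, "fit_config"))
  b <- series$scheme$b_values
  d <- dim(series$data)
  shape <- d[1:3]
  nvox <- prod(shape)
  flat <- matrix(series$data, nrow = nvox, ncol = d[4L])

  mask <- compute_mask(array(flat[, 1L], dim = shape), fraction = mask_fraction)
  idx <- which(as.vector(mask))

  mk <- function() array(NA_real_, dim = shape)
  D_map <- mk(); f_map <- mk(); Dp_map <- mk(); ADC_map <- mk()
  failed <- integer(0)

  if (length(idx)) {
    fit <- .fit_curves(flat[idx, , drop = FALSE], b, cfg)
    D_map[idx] <- fit$D
    f_map[idx] <- fit$f
    Dp_map[idx] <- fit$Dp
    ADC_map[idx] <- fit_adc_two_point(flat[idx, 1L], flat[idx, d[4L]],
                                      b_high = b[d[4L]])
    failed <- idx[grepl("fit_failed", fit$flags)]
  }

  structure(list(D = D_map, f = f_map, Dp = Dp_map, ADC = ADC_map,
                 mask = mask, spacing = series$spacing, failed = failed),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  n_in <- sum(x$mask)
  cat(sprintf("IVIM parameter maps: %s voxels, %d masked-in, %d failed fits\n",
              paste(dim(x$mask), collapse = " x "), n_in, length(x$failed)))
  if (n_in) {
    cat(sprintf("  D:   %.3g x 10^-3 mm^2/s (map mean)\n", mean(x$D, na.rm = TRUE) * 1e3))
    cat(sprintf("  f:   %.3g %% (map mean)\n", mean(x$f, na.rm = TRUE) * 100))
  }
  invisible(x)
}

#' Export parameter maps as NIfTI volumes
#'
#' Maps are written in the conventional display units: D and ADC in
#' 10^-3 mm^2/s (so a typical tissue value reads ~1-3), the perfusion
#' fraction in percent (0-100), Dp in 10^-3 mm^2/s, and the mask as 0/1.
#' Undefined voxels are NaN.
#'
#' @param maps a `parameter_maps` object from [fit_volume()].
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix.
#' @param gzip write `.nii.gz` instead of `.nii`.
#' @return named character vector of the written paths, invisibly.
#' @export
write_parameter_maps <- function(maps, dir, prefix = "ivim", gzip = FALSE) {
  stopifnot(inherits(maps, "parameter_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (gzip) ".nii.gz" else ".nii"
  out <- c(
    D    = file.path(dir, paste0(prefix, "_D", ext)),
    f    = file.path(dir, paste0(prefix, "_f", ext)),
    Dp   = file.path(dir, paste0(prefix, "_Dp", ext)),
    ADC  = file.path(dir, paste0(prefix, "_ADC", ext)),
    mask = file.path(dir, paste0(prefix, "_mask", ext))
  )
  write_nifti(maps$D * 1e3, out["D"], spacing = maps$spacing)
  write_nifti(maps$f * 100, out["f"], spacing = maps$spacing)
  write_nifti(maps$Dp * 1e3, out["Dp"], spacing = maps$spacing)
  write_nifti(maps$ADC * 1e3, out["ADC"], spacing = maps$spacing)
  write_nifti(maps$mask * 1, out["mask"], spacing = maps$spacing)
  invisible(out)
}

#' Read a DWI series from NIfTI + b-value sidecar
#'
#' @param nii_path 4D NIfTI file.
#' @param bval_path FSL-style `.bval` text file, or a scheme JSON written by
#'   [write_scheme_json()] (detected by the `.json` extension).
#' @return a [dwi_series()].
#' @export
read_dwi_series <- function(nii_path, bval_path) {
  v <- read_nifti(nii_path)
  scheme <- if (grepl("\\.json$", bval_path)) read_scheme_json(bval_path)
            else read_bval(bval_path)
  data <- v$data
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data)[1:2], 1L, dim(data)[3L])
  dwi_series(scheme, data, spacing = rep_len(v$spacing, 3L))
}

#' Write a DWI series as NIfTI + sidecars
#'
#' @param series a [dwi_series()].
#' @param nii_path output NIfTI path.
#' @param bval_path output `.bval` path (default: `nii_path` with extension
#'   swapped).  A scheme JSON carrying the averages is written alongside.
#' @return the NIfTI path, invisibly.
#' @export
write_dwi_series <- function(series, nii_path, bval_path = NULL) {
  stopifnot(inherits(series, "dwi_series"))
  base <- sub("\\.nii(\\.gz)?$", "", nii_path)
  if (is.null(bval_path)) bval_path <- paste0(base, ".bval")
  write_nifti(series$data, nii_path, spacing = series$spacing)
  write_bval(series$scheme, bval_path)
  write_scheme_json(series$scheme, paste0(base, "_scheme.json"))
  invisible(nii_path)
}
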