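#' Tissue parameter defaults for the knee phantom
#'
#' Group-wise IVIM tissue parameters for muscle, joint effusion and synovium,
#' as measured in a pediatric synovitis cohort ("patients") and healthy adult
#' volunteers ("volunteers"): mean and standard deviation of the tissue
#' diffusion coefficient D (mm^2/s) and perfusion fraction f, plus the
#' observed per-group ranges where published (synovium and effusion; muscle
#' ranges default to mean +/- 2 SD).  The pseudo-diffusion coefficient has no
#' published value and defaults to 10 x D, reflecting that pseudo-diffusion
#' is typically about one order of magnitude faster than tissue diffusion.
#' Baseline b = 0 intensities (arbitrary units) are package choices: fluid
#' brightest, synovium intermediate, muscle lowest, background near zero.
#'
#' @param group `"patients"` or `"volunteers"`.
#' @return a data.frame with one row per tissue: `name`, `label` (integer
#'   code used in label maps; background = 0), `S0`, `D`, `D_sd`, `D_lo`,
#'   `D_hi`, `f`, `f_sd`, `f_lo`, `f_hi`, `Dp`.
#' @export
tissue_table <- function(group = c("patients", "volunteers")) {
  group <- match.arg(group)
  if (group == "patients") {
    tab <- data.frame(
      name = c("muscle", "synovium", "effusion"),
      label = c(1L, 2L, 3L),
      S0 = c(100, 150, 200),
      D = c(1.60e-3, 1.81e-3, 2.43e-3),
      D_sd = c(0.14e-3, 0.28e-3, 0.41e-3),
      D_lo = c(NA, 1.51e-3, 1.87e-3),
      D_hi = c(NA, 2.27e-3, 3.32e-3),
      f = c(0.069, 0.109, 0.028),
      f_sd = c(0.0205, 0.025, 0.013),
      f_lo = c(NA, 0.083, 0.012),
      f_hi = c(NA, 0.141, 0.059)
    )
  } else {
    tab <- data.frame(
      name = c("muscle", "synovium", "effusion"),
      label = c(1L, 2L, 3L),
      S0 = c(100, 150, 200),
      D = c(1.70e-3, 2.61e-3, 2.09e-3),
      D_sd = c(0.25e-3, 0.34e-3, 0.44e-3),
      D_lo = c(NA, 2.21e-3, 1.66e-3),
      D_hi = c(NA, 2.94e-3, 2.32e-3),
      f = c(0.074, 0.044, 0.132),
      f_sd = c(0.026, 0.018, 0.071),
      f_lo = c(NA, 0.021, 0.064),
      f_hi = c(NA, 0.061, 0.223)
    )
  }
  # unpublished ranges: mean +/- 2 SD, floored at a small positive value
  miss <- is.na(tab$D_lo)
  tab$D_lo[miss] <- pmax(tab$D[miss] - 2 * tab$D_sd[miss], 1e-5)
  tab$D_hi[miss] <- tab$D[miss] + 2 * tab$D_sd[miss]
  miss <- is.na(tab$f_lo)
  tab$f_lo[miss] <- pmax(tab$f[miss] - 2 * tab$f_sd[miss], 0)
  tab$f_hi[miss] <- pmin(tab$f[miss] + 2 * tab$f_sd[miss], 1)
  tab$Dp <- 10 * tab$D
  tab
}

#' Knee phantom specification
#'
#' A 2D multi-slice digital phantom with concentric in-plane compartments:
#' an inner effusion disc, a synovial ring of configurable thickness, a
#' surrounding muscle disc, and background outside.  Geometry is expressed
#' in voxel units in the slice plane and replicated across slices.
#'
#' @param group tissue parameter set, `"patients"` or `"volunteers"`.
#' @param shape integer length-3 image shape (default 64 x 64 x 5).
#' @param spacing voxel size in mm (default 1.3 x 1.3 x 3.0).
#' @param center in-plane center in voxel coordinates (default image center).
#' @param r_effusion radius of the inner effusion disc (voxels).
#' @param r_synovium outer radius of the synovial ring (voxels); ring
#'   thickness is `r_synovium - r_effusion`.
#' @param r_muscle outer radius of the muscle compartment (voxels).
#' @param tissues tissue parameter table; default [tissue_table()] for
#'   `group`.
#' @param sigma Rician noise standard deviation in the same arbitrary units
#'   as S0 (default 2, i.e. SNR 50 on muscle at b = 0); the effective noise
#'   at each b-value is `sigma / sqrt(averages)`.
#' @param seed RNG seed for the noise draw.
#' @param scheme a [bvalue_scheme()]; default [default_bvalue_scheme()].
#' @param truncate_perfusion_above diffusion weighting (s/mm^2) at/above
#'   which the simulated perfusion term is set exactly to zero (the signal
#'   follows [high_b_signal()] there).  Default `Inf`: the full
#'   bi-exponential model at every b.  Setting this to the fit's
#'   b-threshold creates the idealized regime in which the segmented
#'   estimator is exact, isolating pipeline plumbing from the method's
#'   small model-mismatch bias in identity tests.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(group = c("patients", "volunteers"),
                         shape = c(64L, 64L, 5L),
                         spacing = c(1.3, 1.3, 3.0),
                         center = NULL,
                         r_effusion = 8,
                         r_synovium = 12,
                         r_muscle = 26,
                         tissues = NULL,
                         sigma = 2,
                         seed = 1L,
                         scheme = default_bvalue_scheme(),
                         truncate_perfusion_above = Inf) {
  group <- match.arg(group)
  if (is.null(tissues)) tissues <- tissue_table(group)
  if (is.null(center)) center <- (shape[1:2] + 1) / 2
  if (length(shape) != 3L || any(shape < 1)) stop("`shape` must be 3 positive sizes")
  if (!(r_effusion >= 0 && r_synovium >= r_effusion && r_muscle > r_synovium)) {
    stop("radii must be nested: 0 <= r_effusion <= r_synovium < r_muscle")
  }
  if (sigma < 0) stop("`sigma` must be >= 0")
  stopifnot(inherits(scheme, "bvalue_scheme"))
  structure(
    list(group = group, shape = as.integer(shape), spacing = as.numeric(spacing),
         center = as.numeric(center), r_effusion = r_effusion,
         r_synovium = r_synovium, r_muscle = r_muscle, tissues = tissues,
         sigma = sigma, seed = as.integer(seed), scheme = scheme,
         truncate_perfusion_above = truncate_perfusion_above),
    class = "phantom_spec"
  )
}

#' Serialize / restore a phantom specification (JSON)
#'
#' @param spec a [phantom_spec()].
#' @param path output / input file path.
#' @export
phantom_spec_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  x <- unclass(spec)
  x$scheme <- unclass(x$scheme)
  if (!is.finite(x$truncate_perfusion_above)) x$truncate_perfusion_above <- NULL
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname phantom_spec_to_json
#' @export
phantom_spec_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  phantom_spec(group = x$group, shape = x$shape, spacing = x$spacing,
               center = x$center, r_effusion = x$r_effusion,
               r_synovium = x$r_synovium, r_muscle = x$r_muscle,
               tissues = x$tissues, sigma = x$sigma, seed = x$seed,
               scheme = bvalue_scheme(x$scheme$b_values, x$scheme$averages),
               truncate_perfusion_above =
                 if (is.null(x$truncate_perfusion_above)) Inf
                 else x$truncate_perfusion_above)
}

#' Tissue label map of the phantom
#'
#' Assigns every voxel exactly one label by nested in-plane region
#' membership: effusion (3) inside `r_effusion`, synovium (2) in the ring,
#' muscle (1) inside `r_muscle`, background (0) outside.  Deterministic.
#'
#' @param spec a [phantom_spec()].
#' @return integer array of the spec's shape.
#' @export
make_label_map <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$shape[1L]; ny <- spec$shape[2L]; nz <- spec$shape[3L]
  x <- matrix(seq_len(nx), nx, ny) - spec$center[1L]
  y <- matrix(seq_len(ny), nx, ny, byrow = TRUE) - spec$center[2L]
  r <- sqrt(x^2 + y^2)
  sl <- matrix(0L, nx, ny)
  sl[r <= spec$r_muscle] <- 1L
  sl[r <= spec$r_synovium] <- 2L
  sl[r <= spec$r_effusion] <- 3L
  array(sl, dim = c(nx, ny, nz))
}

#' Rician noise draw
#'
#' Magnitude-MRI noise: `sqrt((S + n1)^2 + n2^2)` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation `sigma`.  At high
#' SNR the mean approaches the noiseless signal; at low SNR the magnitude
#' operation produces the well-known positive bias.
#'
#' @param S numeric vector/array of noiseless signals.
#' @param sigma noise standard deviation (scalar or same shape as `S`).
#' @return noisy magnitudes, same shape as `S`.  Uses the current RNG
#'   stream; seed externally for reproducibility.
#' @export
add_rician_noise <- function(S, sigma) {
  if (any(sigma < 0)) stop("`sigma` must be >= 0")
  n <- length(S)
  out <- sqrt((S + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(S))) dim(out) <- dim(S)
  out
}

#' Simulate a multi-b-value DWI series of the phantom
#'
#' Per voxel and b-value the noiseless signal is the bi-exponential forward
#' model of the voxel's tissue ([ivim_signal()]); the observed signal is a
#' Rician draw whose Gaussian components have standard deviation
#' `sigma / sqrt(averages(b))`, reflecting signal averaging.  With
#' `sigma = 0` the series equals the forward model exactly.  Seeded and
#' reproducible: the same spec yields the identical series.
#'
#' @param spec a [phantom_spec()].
#' @return a list with `series` (a [dwi_series()]) and `labels` (integer
#'   array).
#' @export
simulate_dwi <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  labels <- make_label_map(spec)
  b <- spec$scheme$b_values
  nb <- length(b)
  tis <- spec$tissues

  # per-tissue noiseless signal table: rows = label 0..3, cols = b
  sig_tab <- matrix(0, nrow = 4L, ncol = nb)
  trunc <- b >= spec$truncate_perfusion_above
  for (i in seq_len(nrow(tis))) {
    p <- ivim_params(S0 = tis$S0[i], D = tis$D[i], f = tis$f[i], Dp = tis$Dp[i])
    s <- ivim_signal(p, b)
    if (any(trunc)) s[trunc] <- high_b_signal(p, b[trunc])
    sig_tab[tis$label[i] + 1L, ] <- s
  }

  nvox <- prod(spec$shape)
  lab_flat <- as.integer(labels) + 1L
  clean <- sig_tab[lab_flat, , drop = FALSE]        # nvox x nb

  if (spec$sigma > 0) {
    set.seed(spec$seed)
    noisy <- clean
    for (j in seq_len(nb)) {
      s_eff <- spec$sigma / sqrt(spec$scheme$averages[j])
      noisy[, j] <- add_rician_noise(clean[, j], s_eff)
    }
  } else {
    noisy <- clean
  }
  data <- array(noisy, dim = c(spec$shape, nb))
  list(series = dwi_series(spec$scheme, data, spacing = spec$spacing),
       labels = labels)
}

# truncated normal by rejection; deterministic given the RNG state
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1L, mean, sd)
      if (x >= lo && x <= hi) break
    }
    out[i] <- x
  }
  out
}

#' Simulate a cohort of phantom subjects
#'
#' Each subject's tissue parameters are drawn around the group defaults
#' using the group's between-subject standard deviations, truncated to the
#' group's observed parameter ranges (so e.g. a patient's synovial perfusion
#' fraction never strays outside the published patient range).  Each subject
#' receives a distinct child seed derived from `base_seed`, making the
#' cohort fully reproducible.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param group `"patients"` or `"volunteers"`.
#' @param base_seed integer seed for the whole cohort.
#' @param jitter multiplier on the between-subject spread (0 = every subject
#'   at the group mean).
#' @param sigma noise level passed to each subject's [phantom_spec()]
#'   (default 2).
#' @param ... further arguments passed to [phantom_spec()] (geometry etc.).
#' @return a list of subjects, each a list with `id`, `series`, `labels`,
#'   `truth` (the subject's tissue table) and `seed`.
#' @export
make_cohort <- function(n_subjects, group = c("patients", "volunteers"),
                        base_seed = 1L, jitter = 1, sigma = 2, ...) {
  group <- match.arg(group)
  if (n_subjects < 1) stop("`n_subjects` must be >= 1")
  base <- tissue_table(group)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    child_seed <- (base_seed * 131L + i * 7919L) %% 2147483000L
    set.seed(child_seed)
    tis <- base
    if (jitter > 0) {
      for (k in seq_len(nrow(tis))) {
        tis$D[k] <- .rtruncnorm(1L, base$D[k], jitter * base$D_sd[k],
                                base$D_lo[k], base$D_hi[k])
        tis$f[k] <- .rtruncnorm(1L, base$f[k], jitter * base$f_sd[k],
                                base$f_lo[k], base$f_hi[k])
      }
      tis$Dp <- 10 * tis$D
    }
    spec <- phantom_spec(group = group, tissues = tis, sigma = sigma,
                         seed = (child_seed + 1L) %% 2147483000L, ...)
    sim <- simulate_dwi(spec)
    subjects[[i]] <- list(id = sprintf("%s_%02d", substr(group, 1, 3), i),
                          series = sim$series, labels = sim$labels,
                          truth = tis, seed = child_seed)
  }
  subjects
}
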