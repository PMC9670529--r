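#' IVIM parameter set
#'
#' The intravoxel incoherent motion (IVIM) model describes the
#' diffusion-weighted signal of a voxel as the superposition of a slowly
#' decaying tissue-diffusion compartment and a fast pseudo-diffusion
#' (perfusion) compartment.  `ivim_params()` bundles and validates the four
#' model parameters.
#'
#' @param S0 unweighted (b = 0) signal, arbitrary units, `>= 0`.
#' @param D tissue diffusion coefficient, mm^2/s, `> 0`.
#' @param f perfusion fraction (dimensionless, in `[0, 1]`).
#' @param Dp pseudo-diffusion coefficient, mm^2/s; must satisfy `Dp >= D`.
#' @return an object of class `ivim_params`.
#' @export
ivim_params <- function(S0, D, f, Dp) {
  stopifnot(length(S0) == 1L, length(D) == 1L, length(f) == 1L, length(Dp) == 1L)
  if (!is.finite(S0) || S0 < 0) stop("`S0` must be finite and >= 0")
  if (!is.finite(D) || D <= 0) stop("`D` must be finite and > 0")
  if (!is.finite(f) || f < 0 || f > 1) stop("`f` must lie in [0, 1]")
  if (!is.finite(Dp) || Dp < D) stop("`Dp` must be finite and >= D")
  structure(list(S0 = S0, D = D, f = f, Dp = Dp), class = "ivim_params")
}

#' @export
print.ivim_params <- function(x, ...) {
  cat(sprintf("IVIM params: S0 = %.4g, D = %.4g mm^2/s (%.3g x 10^-3), f = %.4g (%.3g%%), Dp = %.4g mm^2/s\n",
              x$S0, x$D, x$D * 1e3, x$f, x$f * 100, x$Dp))
  invisible(x)
}

#' Bi-exponential IVIM forward model
#'
#' Signal at diffusion weighting `b`:
#' `S(b) = S0 * ((1 - f) * exp(-b * D) + f * exp(-b * Dp))`.
#'
#' @param p an [ivim_params()] object (or a list with fields S0, D, f, Dp
#'   satisfying the same invariants).
#' @param b diffusion weighting(s), s/mm^2, non-negative; vectorized.
#' @return signal intensity, same length as `b`.  Equals `S0` exactly at
#'   b = 0 and is non-increasing in b.
#' @examples
#' p <- ivim_params(S0 = 100, D = 1.81e-3, f = 0.109, Dp = 0.02)
#' ivim_signal(p, c(0, 200, 1000))
#' @export
ivim_signal <- function(p, b) {
  .check_params(p)
  if (any(!is.finite(b)) || any(b < 0)) stop("`b` must be finite and >= 0")
  p$S0 * ((1 - p$f) * exp(-b * p$D) + p$f * exp(-b * p$Dp))
}

#' High-b mono-exponential approximation
#'
#' At high diffusion weighting the perfusion compartment has decayed away and
#' the signal reduces to `S_high(b) = S0 * (1 - f) * exp(-b * D)`: a
#' mono-exponential with intercept `S0 * (1 - f)`.  This is the model of the
#' first (log-linear) stage of the segmented fit.
#'
#' @inheritParams ivim_signal
#' @return signal intensity, same length as `b`.
#' @export
high_b_signal <- function(p, b) {
  .check_params(p)
  if (any(!is.finite(b)) || any(b < 0)) stop("`b` must be finite and >= 0")
  p$S0 * (1 - p$f) * exp(-b * p$D)
}

.check_params <- function(p) {
  if (inherits(p, "ivim_params")) return(invisible(TRUE))
  need <- c("S0", "D", "f", "Dp")
  if (!is.list(p) || !all(need %in% names(p))) {
    stop("`p` must be an ivim_params object or a list with S0, D, f, Dp")
  }
  if (!is.finite(p$S0) || p$S0 < 0 || !is.finite(p$D) || p$D <= 0 ||
      !is.finite(p$f) || p$f < 0 || p$f > 1 || !is.finite(p$Dp) || p$Dp < p$D) {
    stop("invalid IVIM parameters")
  }
  invisible(TRUE)
}

#' Two-point apparent diffusion coefficient
#'
#' Mono-exponential ADC from the b = 0 and b = b_high (default 1000 s/mm^2)
#' signals: `ADC = log(s0 / s_high) / b_high`.  Non-positive signals yield the
#' undefined-voxel marker `NA` rather than an error, so a single bad voxel
#' cannot abort a map computation.  Vectorized.
#'
#' @param s0 signal at b = 0.
#' @param s_high signal at `b_high`.
#' @param b_high the high diffusion weighting in s/mm^2 (default 1000).
#' @return ADC in mm^2/s (`NA` where either signal is non-positive or
#'   non-finite).
#' @examples
#' fit_adc_two_point(200, 40)          # log(5)/1000
#' fit_adc_two_point(100, 100 * exp(-1))  # 1e-3
#' @export
fit_adc_two_point <- function(s0, s_high, b_high = 1000) {
  if (length(s0) != length(s_high)) stop("`s0` and `s_high` must have equal length")
  ok <- is.finite(s0) & is.finite(s_high) & s0 > 0 & s_high > 0
  adc <- rep(NA_real_, length(s0))
  adc[ok] <- log(s0[ok] / s_high[ok]) / b_high
  adc
}

#' Configuration of the segmented IVIM fit
#'
#' @param b_threshold diffusion weighting (s/mm^2) at/above which the
#'   perfusion signal is treated as negligible; membership is inclusive
#'   (b = `b_threshold` belongs to the high-b set).  Default 200.
#' @param D_bounds numeric length-2, bounds for D in mm^2/s.
#' @param f_bounds numeric length-2, bounds for the perfusion fraction.
#' @param Dp_max upper bound for the pseudo-diffusion coefficient, mm^2/s.
#'   The lower bound is the fitted D of each voxel.
#' @param Dp_init_factor initial Dp as a multiple of D (pseudo-diffusion is
#'   typically about one order of magnitude faster than tissue diffusion);
#'   used when Dp is unidentifiable (f = 0).
#' @param tol absolute convergence tolerance of the one-parameter Dp search.
#' @param max_iter iteration cap of the Dp search (golden-section steps).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(b_threshold = 200,
                       D_bounds = c(1e-5, 4e-3),
                       f_bounds = c(0, 1),
                       Dp_max = 0.5,
                       Dp_init_factor = 10,
                       tol = 1e-12,
                       max_iter = 100L) {
  stopifnot(length(D_bounds) == 2L, D_bounds[1] > 0, diff(D_bounds) > 0,
            length(f_bounds) == 2L, f_bounds[1] >= 0, f_bounds[2] <= 1,
            diff(f_bounds) > 0, Dp_max > D_bounds[2], Dp_init_factor > 1,
            tol > 0, max_iter >= 10L)
  structure(
    list(b_threshold = b_threshold, D_bounds = as.numeric(D_bounds),
         f_bounds = as.numeric(f_bounds), Dp_max = Dp_max,
         Dp_init_factor = Dp_init_factor, tol = tol,
         max_iter = as.integer(max_iter)),
    class = "fit_config"
  )
}

#' Serialize / restore a fit configuration
#'
#' @param cfg a [fit_config()].
#' @param path file path; when `NULL`, `fit_config_to_json` returns the JSON
#'   string instead of writing it.
#' @return `fit_config_to_json`: the JSON string (invisibly if written to a
#'   file); `fit_config_from_json`: a `fit_config`.
#' @export
fit_config_to_json <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "fit_config"))
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname fit_config_to_json
#' @param json a JSON string (ignored when `path` is given).
#' @export
fit_config_from_json <- function(json = NULL, path = NULL) {
  if (!is.null(path)) json <- paste(readLines(path, warn = FALSE), collapse = "\n")
  x <- jsonlite::fromJSON(json)
  do.call(fit_config, x)
}

# Vectorized fitting core shared by segmented_fit() and fit_volume().
# Y: n_voxel x n_b matrix of signals; b: b-values.  Returns per-voxel
# vectors D, f, Dp, S0 plus a character flag vector ("" when clean).
.fit_curves <- function(Y, b, cfg) {
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  nb <- length(b)
  stopifnot(ncol(Y) == nb, b[1] == 0)
  n <- nrow(Y)
  hi <- which(b >= cfg$b_threshold)
  if (length(hi) < 3L) stop("need at least 3 b-values at/above b_threshold")
  bh <- b[hi]

  flags <- character(n)
  s_b0 <- Y[, 1L]

  # --- step 1: weighted (0/1) OLS of log-signal vs b over the high-b set ---
  Yh <- Y[, hi, drop = FALSE]
  W <- is.finite(Yh) & (Yh > 0)
  L <- matrix(0, n, length(hi))
  L[W] <- log(Yh[W])
  Wn <- W * 1
  m <- rowSums(Wn)
  sx <- as.vector(Wn %*% bh)
  sxx <- as.vector(Wn %*% (bh^2))
  sy <- rowSums(Wn * L)
  sxy <- as.vector(rowSums(Wn * sweep(L, 2L, bh, `*`)))
  denom <- m * sxx - sx^2
  usable <- (m >= 3L) & (denom > 0) & is.finite(s_b0) & (s_b0 > 0)
  slope <- intercept <- rep(NA_real_, n)
  slope[usable] <- (m * sxy - sx * sy)[usable] / denom[usable]
  intercept[usable] <- (sy[usable] - slope[usable] * sx[usable]) / m[usable]

  D <- -slope
  # clamp into bounds; flag only violations beyond numerical round-off
  eps <- 1e-9
  lowD <- usable & (D < cfg$D_bounds[1])
  highD <- usable & (D > cfg$D_bounds[2])
  mark <- (usable & (D < cfg$D_bounds[1] - eps)) |
          (usable & (D > cfg$D_bounds[2] + eps))
  D[lowD] <- cfg$D_bounds[1]
  D[highD] <- cfg$D_bounds[2]
  flags[mark] <- paste0(flags[mark], "D_clamped;")

  # f against the MEASURED unweighted signal S(0)
  f <- 1 - exp(intercept) / s_b0
  lowf <- usable & (f < cfg$f_bounds[1])
  highf <- usable & (f > cfg$f_bounds[2])
  mark <- (usable & (f < cfg$f_bounds[1] - eps)) |
          (usable & (f > cfg$f_bounds[2] + eps))
  f[lowf] <- cfg$f_bounds[1]
  f[highf] <- cfg$f_bounds[2]
  flags[mark] <- paste0(flags[mark], "f_clamped;")
  flags[!usable] <- "fit_failed;"

  # --- step 2: one-parameter bounded LS for Dp over ALL b-values ---------
  Dp <- rep(NA_real_, n)
  fit2 <- usable & (f > 0)
  if (any(fit2)) {
    idx <- which(fit2)
    A <- (s_b0[idx] * (1 - f[idx])) * exp(-outer(D[idx], b))   # tissue term
    Cf <- s_b0[idx] * f[idx]                                    # perfusion amp
    Yf <- Y[idx, , drop = FALSE]
    sse <- function(dp) {
      # dp: vector over idx; residual sum of squares per voxel
      R <- A + Cf * exp(-outer(dp, b)) - Yf
      rowSums(R * R)
    }
    lo <- pmax(D[idx], cfg$D_bounds[1])
    hiB <- rep(cfg$Dp_max, length(idx))
    Dp[idx] <- .golden_min_vec(sse, lo, hiB, tol = cfg$tol,
                               max_iter = cfg$max_iter)
  }
  # unidentifiable perfusion compartment: conventional Dp = k * D
  noperf <- usable & (f <= 0)
  if (any(noperf)) {
    Dp[noperf] <- pmin(cfg$Dp_init_factor * D[noperf], cfg$Dp_max)
    flags[noperf] <- paste0(flags[noperf], "Dp_unidentifiable;")
  }
  # enforce Dp >= D
  Dp[usable] <- pmax(Dp[usable], D[usable])

  list(S0 = ifelse(usable, s_b0, NA_real_), D = ifelse(usable, D, NA_real_),
       f = ifelse(usable, f, NA_real_), Dp = Dp, flags = flags)
}

# Simultaneous golden-section minimization over many voxels.
# fn(x) must accept and return a vector (one scalar objective per voxel).
.golden_min_vec <- function(fn, lower, upper, tol = 1e-12, max_iter = 100L) {
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - phi * (b - a)
  x2 <- a + phi * (b - a)
  f1 <- fn(x1); f2 <- fn(x2)
  for (i in seq_len(max_iter)) {
    if (all(b - a < tol)) break
    left <- f1 <= f2
    b[left] <- x2[left]
    x2[left] <- x1[left]
    f2[left] <- f1[left]
    x1[left] <- b[left] - phi * (b[left] - a[left])
    rt <- !left
    a[rt] <- x1[rt]
    x1[rt] <- x2[rt]
    f1[rt] <- f2[rt]
    x2[rt] <- a[rt] + phi * (b[rt] - a[rt])
    fl <- fn(ifelse(left, x1, x2))
    f1[left] <- fl[left]
    f2[rt] <- fl[rt]
  }
  (a + b) / 2
}

#' Segmented two-step IVIM fit of a single signal curve
#'
#' Step 1 estimates D and f from the b-values at/above `cfg$b_threshold`,
#' where the perfusion signal has decayed away and the model is
#' mono-exponential: an ordinary least-squares line fit of `log(signal)`
#' versus b gives `-D` as slope, and the perfusion fraction follows from the
#' intercept as `f = 1 - exp(intercept) / S(b = 0)` (the fraction is defined
#' against the measured unweighted signal).  Step 2 holds D and f fixed and
#' estimates the pseudo-diffusion coefficient Dp by bounded one-parameter
#' least squares of the full bi-exponential model over ALL b-values
#' (deterministic golden-section search).
#'
#' @param curve a [signal_curve()].
#' @param cfg a [fit_config()].
#' @return a list of class `ivim_fit`: elements `S0` (the measured b = 0
#'   signal), `D`, `f`, `Dp` and `flags` (empty string when the fit is clean;
#'   `"fit_failed;"` when fewer than 3 positive high-b samples were available,
#'   in which case the estimates are `NA`).
#' @examples
#' sch <- default_bvalue_scheme()
#' p <- ivim_params(100, 1.81e-3, 0.109, 0.015)
#' fit <- segmented_fit(signal_curve(sch, ivim_signal(p, sch$b_values)))
#' c(fit$D, fit$f)
#' @export
segmented_fit <- function(curve, cfg = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"), inherits(cfg, "fit_config"))
  b <- curve$scheme$b_values
  if (cfg$b_threshold > max(b)) stop("b_threshold exceeds the largest b-value")
  r <- .fit_curves(matrix(curve$signal, nrow = 1L), b, cfg)
  structure(list(S0 = r$S0[1], D = r$D[1], f = r$f[1], Dp = r$Dp[1],
                 flags = r$flags[1]),
            class = "ivim_fit")
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat(sprintf("segmented IVIM fit: D = %.4g x 10^-3 mm^2/s, f = %.3g%%, Dp = %.4g mm^2/s%s\n",
              x$D * 1e3, x$f * 100, x$Dp,
              if (nzchar(x$flags)) paste0("  [", x$flags, "]") else ""))
  invisible(x)
}
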