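#' ROI statistics from parameter maps
#'
#' Computes mean, standard deviation (sample, n - 1 denominator), minimum,
#' maximum and voxel count of the D and f maps over the intersection of an
#' ROI label with the validity mask.  Masked-out or undefined voxels never
#' contribute.
#'
#' @param maps a `parameter_maps` object from [fit_volume()].
#' @param roi integer label array of the maps' spatial shape.
#' @param label the ROI label to extract.
#' @return a list of class `roi_stats` with components `D` and `f` (each
#'   `mean`, `sd`, `min`, `max`) and `n_voxels`.
#' @export
extract_roi_stats <- function(maps, roi, label) {
  stopifnot(inherits(maps, "parameter_maps"))
  if (!identical(dim(roi), dim(maps$mask))) {
    stop("`roi` shape must match the parameter maps")
  }
  sel <- (roi == label) & maps$mask & !is.na(maps$D) & !is.na(maps$f)
  if (!any(sel)) {
    stop("empty ROI: label ", label,
         " has no masked-in voxels with a valid fit")
  }
  stat4 <- function(v) {
    v <- v[sel]
    list(mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else 0,
         min = min(v), max = max(v))
  }
  structure(list(D = stat4(maps$D), f = stat4(maps$f), n_voxels = sum(sel)),
            class = "roi_stats")
}

#' Jitter an ROI by a seeded one-voxel boundary perturbation
#'
#' Emulates a second, independently drawn ROI: in-plane boundary voxels of
#' the ROI are randomly dropped and adjacent outside voxels randomly added
#' (probability 1/2 each), reproducing the 1-voxel placement variability of
#' repeated manual segmentation.  Deterministic for a given seed.
#'
#' @param roi integer label array.
#' @param label the label to perturb.
#' @param seed RNG seed.
#' @param prob per-voxel toggle probability at the boundary.
#' @return a logical array: the perturbed ROI mask.
#' @export
perturb_roi <- function(roi, label, seed, prob = 0.5) {
  m <- roi == label
  d <- dim(m)
  if (length(d) != 3L) stop("`roi` must be a 3D label array")
  shift <- function(a, dx, dy) {
    out <- array(FALSE, dim = d)
    xs <- seq_len(d[1]); ys <- seq_len(d[2])
    xs_src <- xs - dx; ys_src <- ys - dy
    okx <- xs_src >= 1 & xs_src <= d[1]
    oky <- ys_src >= 1 & ys_src <= d[2]
    out[xs[okx], ys[oky], ] <- a[xs_src[okx], ys_src[oky], , drop = FALSE]
    out
  }
  nb <- shift(m, 1, 0) | shift(m, -1, 0) | shift(m, 0, 1) | shift(m, 0, -1)
  inner_boundary <- m & !(shift(m, 1, 0) & shift(m, -1, 0) &
                          shift(m, 0, 1) & shift(m, 0, -1))
  outer_boundary <- !m & nb
  set.seed(seed)
  drop_idx <- which(inner_boundary)
  add_idx <- which(outer_boundary)
  out <- m
  if (length(drop_idx)) {
    out[drop_idx[stats::runif(length(drop_idx)) < prob]] <- FALSE
  }
  if (length(add_idx)) {
    out[add_idx[stats::runif(length(add_idx)) < prob]] <- TRUE
  }
  out
}

#' Quantify one subject: all tissues, with a measurement repeat
#'
#' For each tissue ROI this computes the D/f statistics of
#' [extract_roi_stats()] from the drawn ROI, repeats the measurement on a
#' boundary-perturbed ROI (emulating the second of two independent ROI
#' drawings), and records the b = 1000 s/mm^2 signal intensity as the mean
#' of the two repeats.
#'
#' @param maps a `parameter_maps` object.
#' @param series the subject's [dwi_series()] (for the b = 1000 signal).
#' @param roi integer label array.
#' @param subject_id character id used in the output rows.
#' @param labels named integer vector mapping tissue name to ROI label.
#' @param repeat_seed seed of the boundary perturbation.
#' @return a data.frame, one row per tissue: first-measurement statistics
#'   (`D_mean`, `D_sd`, `D_min`, `D_max`, `f_*`, `n_voxels`), the repeat
#'   means (`D_mean_rep2`, `f_mean_rep2`) and `si_b1000` (mean of the two
#'   b = 1000 ROI means).  D in mm^2/s, f as a fraction.
#' @export
measure_subject <- function(maps, series, roi, subject_id = "subj",
                            labels = c(muscle = 1L, synovium = 2L, effusion = 3L),
                            repeat_seed = 1L) {
  stopifnot(inherits(maps, "parameter_maps"), inherits(series, "dwi_series"))
  b <- series$scheme$b_values
  j1000 <- which.max(b)          # highest b-value volume (1000 by default)
  v1000 <- series$data[, , , j1000]
  rows <- lapply(seq_along(labels), function(k) {
    lab <- labels[[k]]
    s1 <- extract_roi_stats(maps, roi, lab)
    m2 <- perturb_roi(roi, lab, seed = repeat_seed + 101L * lab)
    roi2 <- array(0L, dim = dim(roi)); roi2[m2] <- lab
    s2 <- extract_roi_stats(maps, roi2, lab)
    si1 <- mean(v1000[(roi == lab) & maps$mask])
    si2 <- mean(v1000[m2 & maps$mask])
    data.frame(subject = subject_id, tissue = names(labels)[k],
               n_voxels = s1$n_voxels,
               D_mean = s1$D$mean, D_sd = s1$D$sd, D_min = s1$D$min,
               D_max = s1$D$max,
               f_mean = s1$f$mean, f_sd = s1$f$sd, f_min = s1$f$min,
               f_max = s1$f$max,
               D_mean_rep2 = s2$D$mean, f_mean_rep2 = s2$f$mean,
               si_b1000 = (si1 + si2) / 2)
  })
  do.call(rbind, rows)
}

#' Within-subject coefficient of variation of paired repeats
#'
#' For each pair the CoV is the standard deviation of the two values divided
#' by their mean; pairs are pooled by root-mean-square, the standard
#' within-subject CoV.  Returned in percent.
#'
#' @param first,second equal-length numeric vectors of paired measurements.
#' @return pooled CoV in percent.
#' @examples
#' repeat_cov(10, 12)   # 12.86 %
#' @export
repeat_cov <- function(first, second) {
  if (length(first) != length(second) || length(first) < 1L) {
    stop("`first` and `second` must be non-empty vectors of equal length")
  }
  mu <- (first + second) / 2
  if (any(mu <= 0)) stop("pair means must be positive")
  cv <- abs(first - second) / sqrt(2) / mu   # sd of 2 values = |diff|/sqrt(2)
  sqrt(mean(cv^2)) * 100
}

#' Mann-Whitney U test for two independent groups
#'
#' The U statistic is computed from midranks (average ranks for ties).  When
#' both groups are free of ties and `n1 * n2 <= 400` the two-sided p-value
#' is exact, from the null distribution of U; otherwise a normal
#' approximation with tie and continuity correction is used.  Deterministic.
#'
#' @param group_a,group_b numeric vectors of observations.
#' @param var_name optional label carried into the result.
#' @return a list of class `mw_test`: `U` (the statistic of `group_a`; note
#'   `U(A, B) + U(B, A) = n1 * n2`), `p` (two-sided), `n`, `method`
#'   (`"exact"` or `"normal_approx"`), per-group `summary` (mean, sd, range)
#'   and `ranges_overlap`.
#' @export
mann_whitney <- function(group_a, group_b, var_name = "") {
  if (!length(group_a) || !length(group_b)) stop("both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b)
  x <- c(group_a, group_b)
  r <- rank(x)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(x)
  has_ties <- any(ties > 1)

  if (!has_ties && n1 * n2 <= 400) {
    method <- "exact"
    p <- if (U1 > n1 * n2 / 2) {
      2 * stats::pwilcox(U1 - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(U1, n1, n2)
    }
    p <- min(1, p)
  } else {
    method <- "normal_approx"
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sigma2)   # continuity corr.
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  summ <- function(v) c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                        min = min(v), max = max(v))
  sa <- summ(group_a); sb <- summ(group_b)
  overlap <- (sa["min"] <= sb["max"]) && (sb["min"] <= sa["max"])
  structure(list(variable = var_name, U = U1, p = p, n = c(n1, n2),
                 method = method, summary = list(a = sa, b = sb),
                 ranges_overlap = unname(overlap)),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U (%s): U = %.1f, n = %d vs %d, p = %.4g (%s)\n",
              if (nzchar(x$variable)) x$variable else "two groups",
              x$U, x$n[1], x$n[2], x$p, x$method))
  invisible(x)
}

#' Group summary with Mann-Whitney comparisons
#'
#' Builds a grouped summary of per-subject ROI means: for every tissue and
#' variable (D, f), the mean +/- SD of each group in display units
#' (10^-3 mm^2/s and percent), the observed ranges, whether they overlap,
#' and the Mann-Whitney U and two-sided p comparing the groups on per-knee
#' means.
#'
#' @param meas_a,meas_b data.frames from [measure_subject()] (rows of the
#'   two groups, e.g. patients and volunteers).
#' @param group_names character length-2 group labels.
#' @return a data.frame, one row per tissue x variable.
#' @export
group_summary <- function(meas_a, meas_b,
                          group_names = c("patients", "volunteers")) {
  vars <- c(D = "D_mean", f = "f_mean")
  scale <- c(D = 1e3, f = 100)
  rows <- list()
  for (tis in unique(meas_a$tissue)) {
    for (v in names(vars)) {
      a <- meas_a[meas_a$tissue == tis, vars[[v]]] * scale[[v]]
      b <- meas_b[meas_b$tissue == tis, vars[[v]]] * scale[[v]]
      mw <- mann_whitney(a, b, var_name = paste(tis, v))
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = tis, variable = v,
        units = if (v == "D") "1e-3 mm^2/s" else "%",
        mean_a = mean(a), sd_a = stats::sd(a),
        min_a = min(a), max_a = max(a),
        mean_b = mean(b), sd_b = stats::sd(b),
        min_b = min(b), max_b = max(b),
        U = mw$U, p = mw$p, ranges_overlap = mw$ranges_overlap
      )
    }
  }
  out <- do.call(rbind, rows)
  names(out) <- sub("_a$", paste0("_", group_names[1]), names(out))
  names(out) <- sub("_b$", paste0("_", group_names[2]), names(out))
  out
}
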