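# Independent oracles.  These deliberately re-derive results by brute force
# (grid search, full enumeration) and never call the code paths they check.

# Brute-force grid-search minimizer of the segmented fit's two objectives:
# stage 1 minimizes the log-domain SSE over (D, f) on the high-b points with
# the intercept tied to f via the measured S(0); stage 2 minimizes the
# bi-exponential SSE over Dp with (D, f) fixed.  Each grid is refined twice
# around the incumbent.
oracle_segmented_fit <- function(signal, b, b_threshold = 200,
                                 D_range = c(1e-5, 4e-3), f_range = c(0, 0.6),
                                 Dp_max = 0.5, n_grid = 121L, n_refine = 2L) {
  hi <- b >= b_threshold
  s0 <- signal[b == 0]
  obj1 <- function(D, f) {
    pred <- log(s0 * (1 - f)) - b[hi] * D
    sum((pred - log(signal[hi]))^2)
  }
  Dr <- D_range; fr <- f_range
  best <- c(NA, NA)
  for (lvl in 0:n_refine) {
    Ds <- seq(Dr[1], Dr[2], length.out = n_grid)
    fs <- seq(fr[1], fr[2], length.out = n_grid)
    vals <- outer(Ds, fs, Vectorize(obj1))
    ij <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    best <- c(Ds[ij[1]], fs[ij[2]])
    stepD <- diff(Dr) / (n_grid - 1); stepf <- diff(fr) / (n_grid - 1)
    Dr <- c(max(D_range[1], best[1] - 2 * stepD),
            min(D_range[2], best[1] + 2 * stepD))
    fr <- c(max(f_range[1], best[2] - 2 * stepf),
            min(f_range[2], best[2] + 2 * stepf))
  }
  D <- best[1]; f <- best[2]
  obj2 <- function(Dp) {
    pred <- s0 * ((1 - f) * exp(-b * D) + f * exp(-b * Dp))
    sum((pred - signal)^2)
  }
  Dpr <- c(D, Dp_max)
  for (lvl in 0:n_refine) {
    Dps <- seq(Dpr[1], Dpr[2], length.out = 4L * n_grid)
    vals <- vapply(Dps, obj2, numeric(1))
    Dp <- Dps[which.min(vals)]
    step <- diff(Dpr) / (4L * n_grid - 1)
    Dpr <- c(max(D, Dp - 2 * step), min(Dp_max, Dp + 2 * step))
  }
  list(D = D, f = f, Dp = Dp)
}

# Exact two-sided Mann-Whitney p by full enumeration of all
# choose(n1 + n2, n1) group labelings (tie-free data).  The two-sided p is
# the probability of a U at least as extreme (either tail) as observed.
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  x <- c(a, b)
  u_of <- function(idx) {
    r <- rank(x)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) sum(rank(x)[idx]) - n1 * (n1 + 1) / 2)
  lo <- min(u_obs, n1 * n2 - u_obs)
  hi <- max(u_obs, n1 * n2 - u_obs)
  mean(us <= lo | us >= hi)
}

# Hand-computed kappa from a contingency table (independent arithmetic).
oracle_kappa <- function(tab) {
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# Rician-noise replicate curves of a tissue at a given b-zero SNR.
make_noisy_curves <- function(p, scheme, snr, n_rep, seed) {
  b <- scheme$b_values
  clean <- ivim_signal(p, b)
  sigma <- p$S0 / snr
  set.seed(seed)
  Y <- matrix(0, n_rep, length(b))
  for (j in seq_along(b)) {
    s <- sigma / sqrt(scheme$averages[j])
    Y[, j] <- sqrt((clean[j] + rnorm(n_rep, 0, s))^2 + rnorm(n_rep, 0, s)^2)
  }
  Y
}

# Fit many curves (rows of Y) with segmented_fit, returning D and f vectors.
fit_curve_matrix <- function(Y, scheme, cfg = fit_config()) {
  out <- apply(Y, 1, function(sig) {
    fit <- segmented_fit(signal_curve(scheme, sig), cfg)
    c(fit$D, fit$f)
  })
  list(D = out[1, ], f = out[2, ])
}
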