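# small helper: parameter maps with prescribed D/f values and full mask
fake_maps <- function(D, f = D * 50, shape = dim(D)) {
  structure(list(D = D, f = f, Dp = D * 10, ADC = D,
                 mask = array(TRUE, dim = shape),
                 spacing = c(1, 1, 1), failed = integer(0)),
            class = "parameter_maps")
}

test_that("ROI statistics cover mean/SD/min/max over mask-ROI intersection", {
  D <- array(2e-3, c(3, 3, 1))
  roi <- array(0L, c(3, 3, 1)); roi[1:2, 1, 1] <- 1L
  maps <- fake_maps(D)
  s <- extract_roi_stats(maps, roi, 1L)
  expect_equal(s$D$mean, 2e-3)
  expect_equal(s$D$sd, 0)
  expect_equal(s$D$min, s$D$max)
  expect_identical(s$n_voxels, 2L)

  # two-voxel ROI with distinct values
  D2 <- D; D2[1, 1, 1] <- 1e-3; D2[2, 1, 1] <- 3e-3
  s2 <- extract_roi_stats(fake_maps(D2), roi, 1L)
  expect_equal(s2$D$mean, 2e-3)
  expect_equal(s2$D$min, 1e-3)
  expect_equal(s2$D$max, 3e-3)
  expect_equal(s2$D$sd, sd(c(1e-3, 3e-3)))   # n-1 denominator

  # masked-out voxels never contribute
  maps3 <- fake_maps(D2); maps3$mask[1, 1, 1] <- FALSE
  s3 <- extract_roi_stats(maps3, roi, 1L)
  expect_identical(s3$n_voxels, 1L)
  expect_equal(s3$D$mean, 3e-3)

  maps4 <- fake_maps(D2); maps4$mask[] <- FALSE
  expect_error(extract_roi_stats(maps4, roi, 1L), "empty ROI")
  expect_error(extract_roi_stats(maps3, array(0L, c(2, 2, 1)), 1L), "shape")
})

test_that("ROI statistics recover phantom truth on the noiseless phantom", {
  spec <- phantom_spec("patients", sigma = 0, truncate_perfusion_above = 200)
  sim <- simulate_dwi(spec)
  maps <- fit_volume(sim$series)
  s <- extract_roi_stats(maps, sim$labels, 2L)     # synovium
  tt <- spec$tissues
  expect_lt(abs(s$D$mean - tt$D[2]) / tt$D[2], 1e-9)
  expect_lt(abs(s$f$mean - tt$f[2]) / tt$f[2], 1e-9)
})

test_that("repeat CoV is the RMS-pooled within-pair CoV in percent", {
  expect_equal(repeat_cov(c(5, 8, 2), c(5, 8, 2)), 0)
  # single pair (10, 12): sd = sqrt(2), mean = 11
  expect_equal(repeat_cov(10, 12), 100 * sqrt(2) / 11, tolerance = 1e-12)
  # scale invariance
  a <- c(10, 20, 30); b <- c(11, 19, 33)
  expect_equal(repeat_cov(a * 10, b * 10), repeat_cov(a, b), tolerance = 1e-12)
  # pooled value is the RMS of per-pair CoVs
  cv1 <- sd(c(10, 11)) / mean(c(10, 11))
  cv2 <- sd(c(20, 19)) / mean(c(20, 19))
  cv3 <- sd(c(30, 33)) / mean(c(30, 33))
  expect_equal(repeat_cov(a, b), 100 * sqrt(mean(c(cv1, cv2, cv3)^2)),
               tolerance = 1e-12)
  expect_error(repeat_cov(c(1, 2), 3), "equal length")
  expect_error(repeat_cov(1, -1), "positive")
})

test_that("ROI perturbation is seeded, 1-voxel and label-preserving", {
  spec <- phantom_spec("patients")
  lab <- make_label_map(spec)
  m1 <- perturb_roi(lab, 2L, seed = 5)
  m2 <- perturb_roi(lab, 2L, seed = 5)
  m3 <- perturb_roi(lab, 2L, seed = 6)
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
  # prob = 0 leaves the ROI untouched
  expect_identical(perturb_roi(lab, 2L, seed = 1, prob = 0), lab == 2L)
  # every change lies within one in-plane voxel of the original ROI edge:
  # dropped voxels were in the ROI, added voxels are 4-adjacent to it
  orig <- lab == 2L
  changed <- which(m1 != orig)
  expect_true(length(changed) > 0)
  idx <- arrayInd(changed, dim(orig))
  near <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    if (orig[i, j, k]) return(TRUE)                 # dropped: was inside
    any(c(i > 1 && orig[i - 1, j, k], i < dim(orig)[1] && orig[i + 1, j, k],
          j > 1 && orig[i, j - 1, k], j < dim(orig)[2] && orig[i, j + 1, k]))
  }, logical(1))
  expect_true(all(near))
  # overlap with the original ROI stays large (1-voxel perturbation)
  expect_gt(sum(m1 & orig) / sum(orig), 0.5)
})

test_that("Mann-Whitney U, symmetry and exact p match theory", {
  # identical groups: U = n1 n2 / 2 by symmetry
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 4.5)
  # complete separation of 3 vs 3: U = 0, exact two-sided p = 0.1
  r2 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$U, 0)
  expect_equal(r2$p, 0.1, tolerance = 1e-12)
  expect_identical(r2$method, "exact")
  expect_false(r2$ranges_overlap)
  # U(A,B) + U(B,A) = n1 n2, with and without ties
  set.seed(31)
  for (i in 1:10) {
    a <- sample(1:6, 5, replace = TRUE)
    b <- sample(1:6, 7, replace = TRUE)
    expect_equal(mann_whitney(a, b)$U + mann_whitney(b, a)$U, 35)
  }
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p agrees with full enumeration, n1+n2 <= 10", {
  set.seed(77)
  for (n1 in 2:5) {
    for (n2 in 2:(10 - n1)) {
      a <- rnorm(n1); b <- rnorm(n2, mean = 0.8)
      got <- mann_whitney(a, b)
      expect_identical(got$method, "exact")
      expect_equal(got$p, oracle_mw_exact_p(a, b), tolerance = 1e-12,
                   label = sprintf("p at n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  a <- c(1, 2, 2, 3, 5); b <- c(2, 3, 3, 4, 6)
  r <- mann_whitney(a, b)
  expect_identical(r$method, "normal_approx")
  # cross-check against base R's identical approximation
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)
  expect_equal(r$U, unname(ref$statistic))
})

test_that("measure_subject returns tidy per-tissue rows with repeats", {
  spec <- phantom_spec("patients", sigma = 2, seed = 8)
  sim <- simulate_dwi(spec)
  maps <- fit_volume(sim$series)
  m <- measure_subject(maps, sim$series, sim$labels, subject_id = "s1",
                       repeat_seed = 3)
  expect_identical(nrow(m), 3L)
  expect_setequal(m$tissue, c("muscle", "synovium", "effusion"))
  expect_true(all(m$D_min <= m$D_mean & m$D_mean <= m$D_max))
  expect_true(all(m$f_min <= m$f_mean & m$f_mean <= m$f_max))
  expect_true(all(m$n_voxels >= 1))
  expect_true(all(is.finite(m$si_b1000) & m$si_b1000 > 0))
  # repeats differ from the first drawing but are close
  expect_true(all(abs(m$D_mean_rep2 - m$D_mean) / m$D_mean < 0.2))
  # deterministic
  m2 <- measure_subject(maps, sim$series, sim$labels, subject_id = "s1",
                        repeat_seed = 3)
  expect_identical(m, m2)
})
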