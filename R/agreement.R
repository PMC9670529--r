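#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; agreement statistics are
#' conventionally reported with half-up rounding (0.6555 -> 0.656).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Dichotomize a synovitis Likert category
#'
#' The 5-level reading scale (0 = non-diagnostic, 1 = no synovitis,
#' 2 = mild synovial irritation, 3 = synovitis, 4 = synovitis with synovial
#' thickening >= 2 mm) collapses to a binary outcome: categories 1 and 2
#' mean no active synovitis (0), categories 3 and 4 active synovitis (1).
#' Category 0 marks non-diagnostic image quality and is rejected.
#'
#' @param category integer vector of categories in 1..4.
#' @return integer vector of 0/1.
#' @export
dichotomize <- function(category) {
  if (any(category == 0)) stop("category 0 = non-diagnostic image quality; cannot dichotomize")
  if (any(!(category %in% 1:4))) stop("categories must lie in 1..4")
  as.integer(category >= 3)
}

#' Rater-by-rater contingency table
#'
#' @param a,b equal-length vectors of categorical ratings of the same cases
#'   by two raters.
#' @param levels ordered category labels; default the sorted union of both
#'   raters' values.
#' @return a square integer matrix of class `contingency_table` (rows:
#'   rater a, columns: rater b).
#' @export
contingency_table <- function(a, b, levels = NULL) {
  if (length(a) != length(b) || !length(a)) {
    stop("`a` and `b` must be non-empty vectors of equal length")
  }
  if (is.null(levels)) levels <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = levels), factor(b, levels = levels))
  structure(unclass(tab), class = "contingency_table")
}

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement: with observed agreement
#' `P_o = trace / N` and expected agreement
#' `P_e = sum_k (row_k / N) (col_k / N)`,
#' `kappa = (P_o - P_e) / (1 - P_e)`.  Perfect agreement on a degenerate
#' table (`P_e = 1` with `P_o = 1`) is defined as kappa = 1; `P_e = 1` with
#' imperfect agreement is undefined and raises an error.
#'
#' @param tab a square count matrix (rows rater A, columns rater B), e.g.
#'   from [contingency_table()].
#' @return a list of class `agreement_result`: `po`, `pe`, `kappa`,
#'   `kappa_round` (half-up to 3 decimals), `label` (Landis-Koch band) and
#'   `n`.
#' @examples
#' cohens_kappa(diag(c(2, 5, 3)))   # kappa = 1
#' @export
cohens_kappa <- function(tab) {
  tab <- unclass(tab)
  if (!is.matrix(tab) || nrow(tab) != ncol(tab)) stop("`tab` must be square")
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  if (n <= 0) stop("`tab` must contain at least one rating pair")
  po <- sum(diag(tab)) / n
  pe <- sum((rowSums(tab) / n) * (colSums(tab) / n))
  kappa <- if (pe >= 1) {
    if (po >= 1) 1 else stop("expected agreement is 1 with imperfect observed agreement; kappa undefined")
  } else {
    (po - pe) / (1 - pe)
  }
  structure(list(po = po, pe = pe, kappa = kappa,
                 kappa_round = round_half_up(kappa, 3),
                 label = landis_koch_label(kappa), n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (P_o = %.2f, P_e = %.3f, n = %d): %s agreement\n",
              x$kappa, x$po, x$pe, x$n, x$label))
  invisible(x)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Conventional verbal bands: below 0 poor, 0-0.20 slight, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect.
#'
#' @param kappa numeric, `<= 1`.
#' @return character label.
#' @export
landis_koch_label <- function(kappa) {
  if (any(kappa > 1 + 1e-12)) stop("kappa cannot exceed 1")
  cut_one <- function(k) {
    if (k < 0) "poor"
    else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else "almost perfect"
  }
  vapply(kappa, cut_one, character(1))
}

#' The reconstructed 10-knee reader study
#'
#' Rating records of the two-reader synovitis study on 10 symptomatic
#' pediatric knees: each knee was rated on contrast-enhanced T1w (`ceT1w`,
#' the diagnostic standard) and on high-b DWI (`DWI`) by two readers, on the
#' 5-level category scale with a 3-level level-of-confidence (LoC).
#' The joint category counts are fully determined by the published marginal
#' distributions and discordance descriptions; which particular knee carries
#' which discordance is not, so this fixture fixes one consistent
#' assignment (every statistic computed from it depends only on the joint
#' counts).
#'
#' Reader 1, ceT1w: categories 2,2,3,3,3,3,3,4,4,4; LoC 3 except one 2.
#' Reader 1, DWI: two category-4 knees downgraded to 3 (both with LoC 3);
#'   LoC 3 x5, 2 x4, 1 x1 (the low-confidence rating on a category-1/2
#'   decision).
#' Reader 2, ceT1w: three 4->3 downgrades, one 3->2, one 2->1, one 3->4
#'   upgrade; all LoC 3.
#' Reader 2, DWI: relative to reader-1 ceT1w one 2->3, one 3->4, one 4->3,
#'   one 3->2, one 2->1; LoC 3 x5 and 2 x5, with three of the five
#'   discordant ratings at high confidence.
#'
#' @return a data.frame of rating records with columns `knee_id`,
#'   `modality` (`"ceT1w"` or `"DWI"`), `reader` (1 or 2), `category`
#'   (0-4) and `loc` (1-3).
#' @export
study_fixture <- function() {
  knee <- sprintf("k%02d", 1:10)
  r1ce  <- c(2, 2, 3, 3, 3, 3, 3, 4, 4, 4)
  r1dwi <- c(2, 2, 3, 3, 3, 3, 3, 4, 3, 3)   # two 4 -> 3 downgrades
  r2ce  <- c(1, 2, 2, 4, 3, 3, 3, 3, 3, 3)   # 3x 4->3, 3->2, 2->1, 3->4
  r2dwi <- c(1, 3, 3, 3, 4, 2, 3, 3, 4, 4)   # 2->3, 3->4, 4->3, 3->2, 2->1

  loc_r1ce  <- c(2, 3, 3, 3, 3, 3, 3, 3, 3, 3)   # nine high, one medium
  # low-confidence rating on the category-1/2 decision (knee 1, rated 2);
  # the two 4->3 downgrades (knees 9, 10) were high-confidence
  loc_r1dwi <- c(1, 2, 2, 3, 3, 2, 2, 3, 3, 3)
  loc_r2ce  <- rep(3, 10)
  # five high / five intermediate; discordant knees 2, 5, 8 at high and
  # knees 1, 6 at intermediate confidence (3 of 5 discordances high)
  loc_r2dwi <- c(2, 3, 3, 3, 3, 2, 2, 3, 2, 2)

  rbind(
    data.frame(knee_id = knee, modality = "ceT1w", reader = 1L,
               category = r1ce, loc = loc_r1ce),
    data.frame(knee_id = knee, modality = "DWI", reader = 1L,
               category = r1dwi, loc = loc_r1dwi),
    data.frame(knee_id = knee, modality = "ceT1w", reader = 2L,
               category = r2ce, loc = loc_r2ce),
    data.frame(knee_id = knee, modality = "DWI", reader = 2L,
               category = r2dwi, loc = loc_r2dwi)
  )
}

#' Extract one reading (category vector ordered by knee)
#'
#' @param records rating records as from [study_fixture()] or
#'   [read_ratings()].
#' @param modality `"ceT1w"` or `"DWI"`.
#' @param reader 1 or 2.
#' @param what `"category"` or `"loc"`.
#' @return vector ordered by `knee_id`.
#' @export
rating_vector <- function(records, modality, reader, what = "category") {
  sel <- records$modality == modality & records$reader == reader
  if (!any(sel)) stop("no records for reader ", reader, " on ", modality)
  r <- records[sel, ]
  r <- r[order(r$knee_id), ]
  r[[what]]
}

#' Level-of-confidence summary
#'
#' Per reader and modality: the median LoC (the median of an even-length
#' series is the midpoint mean, so e.g. five 3s and five 2s give 2.5) and
#' the proportion of ratings at each confidence level, in percent.
#'
#' @param records rating records.
#' @return a data.frame with one row per reader x modality: `median_loc`
#'   and `pct_loc1`..`pct_loc3`.
#' @export
loc_summary <- function(records) {
  if (!nrow(records)) stop("no rating records")
  combos <- unique(records[, c("reader", "modality")])
  combos <- combos[order(combos$reader, combos$modality), ]
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sel <- records$reader == combos$reader[i] &
           records$modality == combos$modality[i]
    l <- records$loc[sel]
    data.frame(reader = combos$reader[i], modality = combos$modality[i],
               n = length(l), median_loc = stats::median(l),
               pct_loc1 = 100 * mean(l == 1),
               pct_loc2 = 100 * mean(l == 2),
               pct_loc3 = 100 * mean(l == 3))
  })
  do.call(rbind, rows)
}

#' Full agreement report
#'
#' Computes every pairwise reader/modality agreement of the study design,
#' on the raw 4-category scale and after dichotomization, plus the LoC
#' summary.  Reader 1 on contrast-enhanced T1w is the diagnostic reference.
#' The 4-category comparison of reader-2 DWI against the reference is
#' flagged: its unweighted kappa (0.219 after rounding) does not reproduce
#' the originally reported 0.220, suggesting the original computation used
#' a slightly different table or weighting.
#'
#' @param records rating records; default [study_fixture()].
#' @return a list with `comparisons` (data.frame: comparison, scale, po,
#'   pe, kappa, kappa_round, label, flag), `loc` (the [loc_summary()]) and
#'   `n_synovitis` (knees dichotomized positive by the reference reading).
#' @export
agreement_report <- function(records = study_fixture()) {
  r1ce <- rating_vector(records, "ceT1w", 1L)
  r1dwi <- rating_vector(records, "DWI", 1L)
  r2ce <- rating_vector(records, "ceT1w", 2L)
  r2dwi <- rating_vector(records, "DWI", 2L)

  pairs <- list(
    r1_ce_vs_r1_dwi = list(a = r1ce, b = r1dwi),
    r1_ce_vs_r2_ce = list(a = r1ce, b = r2ce),
    r1_ce_vs_r2_dwi = list(a = r1ce, b = r2dwi),
    r1_dwi_vs_r2_dwi = list(a = r1dwi, b = r2dwi)
  )
  rows <- list()
  for (nm in names(pairs)) {
    a <- pairs[[nm]]$a; b <- pairs[[nm]]$b
    for (scale in c("categories", "dichotomous")) {
      if (scale == "dichotomous") { a2 <- dichotomize(a); b2 <- dichotomize(b) }
      else { a2 <- a; b2 <- b }
      k <- cohens_kappa(contingency_table(a2, b2))
      flag <- if (nm == "r1_ce_vs_r2_dwi" && scale == "categories") {
        "reported value 0.220 not reproduced by the unweighted formula (computes to 0.219)"
      } else ""
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = nm, scale = scale, po = k$po, pe = k$pe,
        kappa = k$kappa, kappa_round = k$kappa_round, label = k$label,
        flag = flag)
    }
  }
  list(comparisons = do.call(rbind, rows),
       loc = loc_summary(records),
       n_synovitis = sum(dichotomize(r1ce)))
}

#' Read / write rating tables (CSV)
#'
#' CSV with header `knee_id, modality, reader, category, loc`.
#'
#' @param path file path.
#' @export
read_ratings <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("knee_id", "modality", "reader", "category", "loc")
  if (!all(need %in% names(r))) {
    stop("ratings CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!(r$category %in% 0:4))) stop("categories must lie in 0..4")
  if (any(!(r$loc %in% 1:3))) stop("LoC must lie in 1..3")
  r
}

#' @rdname read_ratings
#' @param records rating records data.frame.
#' @export
write_ratings <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
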