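#' Difference-in-proportion (DIP) test
#'
#' Pooled two-proportion z-test comparing a block's share of two sequencing
#' libraries: with `p1 = x1/n1`, `p2 = x2/n2` and pooled
#' `p = (x1+x2)/(n1+n2)`, the statistic is
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with a two-sided
#' standard-normal p-value.  The library totals provide the normalization,
#' so counts are passed raw (never RPM-scaled).  `z^2` equals the Pearson
#' chi-square statistic (no continuity correction) of the corresponding
#' 2x2 table.
#'
#' @param x1,x2 block counts (may be non-integer weighted counts).
#' @param n1,n2 library totals.
#' @return list with `z` and `p`.
#' @export
dip_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  if (any(x1 == 0 & x2 == 0))
    stop("DIP undefined for x1 = x2 = 0 (prefilter should prevent this)")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Bonferroni correction
#'
#' @param p_values vector of raw p-values.
#' @param m number of tests in the family (defaults to `length(p_values)`).
#' @return adjusted p-values, `min(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m == 0) return(numeric(0))
  pmin(1, p_values * m)
}

#' Run one pairwise differential expression comparison
#'
#' Blocks with expression strictly greater than `rpm_min` reads per million
#' in at least one of the two libraries are tested with [dip_test()] on raw
#' weighted counts; p-values are Bonferroni-corrected within the comparison;
#' a block is called differential when the corrected p-value is below
#' `alpha` and the RPM fold change reaches `fc_min` in either direction.
#'
#' @param mat count matrix (blocks x libraries) of weighted counts.
#' @param lib_a,lib_b column names of the two libraries.
#' @param rpm_min low-expression filter (RPM, strict inequality).
#' @param fc_min fold-change cutoff (applied in either direction).
#' @param alpha significance level on the corrected p-value.
#' @param comparison label stored in the result.
#' @param totals optional named vector of library totals; defaults to the
#'   genome-mapped column sums of `mat`.
#' @return `data.table` with one row per block: counts, totals, `rpm_a`,
#'   `rpm_b`, `z`, `p`, `p_adj`, `fold_change` (RPM of `lib_b` over
#'   `lib_a`), and `status` in `not_tested, tested_ns, de_up, de_down`.
#' @export
run_comparison <- function(mat, lib_a, lib_b, rpm_min = 20, fc_min = 2,
                           alpha = 0.05,
                           comparison = paste0(lib_b, "_vs_", lib_a),
                           totals = colSums(mat)) {
  if (!lib_a %in% colnames(mat)) stop("unknown library id: ", lib_a)
  if (!lib_b %in% colnames(mat)) stop("unknown library id: ", lib_b)
  n1 <- totals[[lib_a]]; n2 <- totals[[lib_b]]
  stopifnot(n1 > 0, n2 > 0)
  res <- data.table::data.table(
    block_id = rownames(mat), comparison = comparison,
    count_a = mat[, lib_a], count_b = mat[, lib_b],
    total_a = n1, total_b = n2)
  res[, rpm_a := count_a * 1e6 / total_a]
  res[, rpm_b := count_b * 1e6 / total_b]
  res[, tested := rpm_a > rpm_min | rpm_b > rpm_min]
  res[, `:=`(z = NA_real_, p = NA_real_, p_adj = NA_real_)]
  m <- sum(res$tested)
  if (m > 0) {
    tt <- res[tested == TRUE]
    dd <- dip_test(tt$count_a, n1, tt$count_b, n2)
    res[tested == TRUE, `:=`(z = dd$z, p = dd$p)]
    res[tested == TRUE, p_adj := bonferroni(p, m)]
  }
  res[, fold_change := rpm_b / rpm_a]
  res[, status := "not_tested"]
  res[tested == TRUE, status := data.table::fcase(
    p_adj < alpha & fold_change >= fc_min, "de_up",
    p_adj < alpha & fold_change <= 1 / fc_min, "de_down",
    default = "tested_ns")]
  res[, tested := NULL]
  res[]
}

#' The six standard survey comparisons
#'
#' Far-red versus dark within each tissue (cotyledon, hypocotyl, hook
#' concave, hook convex) plus convex versus concave under each light, using
#' the default library identifiers of [default_library_design()].
#'
#' @return `data.frame` with `comparison, lib_a, lib_b` (the comparison
#'   tests `lib_b` against baseline `lib_a`).
#' @export
standard_comparisons <- function() {
  data.frame(
    comparison = c("cot_fr_vs_dark", "hyp_fr_vs_dark", "hkcc_fr_vs_dark",
                   "hkcv_fr_vs_dark", "hook_cv_vs_cc_dark",
                   "hook_cv_vs_cc_fr"),
    lib_a = c("cot_dark", "hyp_dark", "hkcc_dark", "hkcv_dark",
              "hkcc_dark", "hkcc_fr"),
    lib_b = c("cot_fr", "hyp_fr", "hkcc_fr", "hkcv_fr",
              "hkcv_dark", "hkcv_fr"),
    stringsAsFactors = FALSE)
}

#' Run a set of comparisons
#'
#' @param mat count matrix (blocks x libraries).
#' @param comparisons `data.frame` as from [standard_comparisons()]; only
#'   comparisons whose libraries are all present in `mat` are run.
#' @inheritParams run_comparison
#' @return named list of per-comparison result tables.
#' @export
run_comparisons <- function(mat, comparisons = standard_comparisons(),
                            rpm_min = 20, fc_min = 2, alpha = 0.05) {
  out <- list()
  for (i in seq_len(nrow(comparisons))) {
    a <- comparisons$lib_a[i]; b <- comparisons$lib_b[i]
    if (!a %in% colnames(mat) || !b %in% colnames(mat)) next
    out[[comparisons$comparison[i]]] <-
      run_comparison(mat, a, b, rpm_min = rpm_min, fc_min = fc_min,
                     alpha = alpha, comparison = comparisons$comparison[i])
  }
  out
}
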