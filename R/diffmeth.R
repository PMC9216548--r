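#' Mann-Whitney U test (Wilcoxon rank-sum) between two value sets
#'
#' Two-sided test through [stats::wilcox.test()]. In `auto` mode the
#' exact distribution is used when both groups have at most 25 values and
#' there are no ties; otherwise the normal approximation with
#' tie-corrected variance and continuity correction. The U statistic is
#' computed from rank sums with midranks for ties.
#'
#' @param values_a,values_b numeric vectors (`NA` dropped); each
#'   non-empty.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return list with `u` (the U statistic for `values_a`) and `p_value`
#'   (two-sided).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))   # U = 0, p = 0.1
mann_whitney <- function(values_a, values_b, mode = "auto") {
  mode <- match.arg(mode, c("auto", "exact", "normal"))
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both groups must contain at least one value", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- switch(mode,
                      auto = length(a) <= 25 && length(b) <= 25 && !ties,
                      exact = TRUE,
                      normal = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = use_exact,
                                            correct = TRUE))
  list(u = unname(wt$statistic), p_value = min(1, wt$p.value))
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha_new = alpha_original / n_tests`. At array scale (e.g. 485 512
#' sites at alpha 0.05) this lands just above 1e-7, which is why
#' per-site p-values below 1e-7 are conventionally demanded genome-wide.
#'
#' @param alpha_original original significance level in (0, 1\].
#' @param n_tests number of tests performed.
#' @return the corrected per-test threshold.
#' @export
bonferroni_threshold <- function(alpha_original, n_tests) {
  if (length(alpha_original) != 1 || is.na(alpha_original) ||
      alpha_original <= 0 || alpha_original > 1)
    stop("alpha_original must lie in (0, 1]", call. = FALSE)
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1 ||
      n_tests != round(n_tests))
    stop("n_tests must be a positive integer", call. = FALSE)
  alpha_original / n_tests
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(1, p * n)`) or Benjamini-Hochberg step-up, through
#' [stats::p.adjust()]; output order matches input order.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p_values, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = if (method == "bh") "BH" else
    "bonferroni")
}

#' Per-site differential methylation between two sample groups
#'
#' For every site shared by the two groups, runs [mann_whitney()] on the
#' per-group beta values (missing values dropped per site and group),
#' adjusts the p-values by both Bonferroni and BH, reports the median
#' difference (group B minus group A) as the effect size, and flags
#' tendency inversions (MTS under one condition, UTS under the other --
#' the strongest form of differential methylation). The table is sorted
#' by BH-adjusted p, then by descending absolute median difference.
#'
#' @param m a [beta_matrix()].
#' @param group_a,group_b character vectors of sample IDs in `m`.
#' @param alpha significance level used for the per-group tendency calls.
#' @param min_n minimum per-group n for a tendency call (sites below it
#'   get `INVERTED = NA`).
#' @param delta optional biological-effect filter: keep only sites with
#'   `|MEDIAN_DIFF| >= delta` (default 0 = off).
#' @param mode test mode, see [mann_whitney()].
#' @return data frame with columns SITE, N_A, N_B, U, P, P_BONF, P_BH,
#'   MEDIAN_DIFF, INVERTED.
#' @export
differential_table <- function(m, group_a, group_b, alpha = 0.05,
                               min_n = 4L, delta = 0, mode = "auto") {
  stopifnot(inherits(m, "beta_matrix"))
  missing_ids <- setdiff(c(group_a, group_b), sample_ids(m))
  if (length(missing_ids))
    stop("sample IDs not in matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap", call. = FALSE)
  va <- m$values[, group_a, drop = FALSE]
  vb <- m$values[, group_b, drop = FALSE]
  rows <- lapply(seq_len(nrow(va)), function(i) {
    a <- va[i, ]; a <- a[!is.na(a)]
    b <- vb[i, ]; b <- b[!is.na(b)]
    if (length(a) == 0 || length(b) == 0) return(NULL)
    mw <- mann_whitney(a, b, mode = mode)
    inv <- if (length(a) >= min_n && length(b) >= min_n) {
      ca <- classify_tendency(a, alpha = alpha, min_n = min_n,
                              site_id = site_ids(m)[i])
      cb <- classify_tendency(b, alpha = alpha, min_n = min_n,
                              site_id = site_ids(m)[i])
      tendency_inversion(ca, cb)
    } else NA
    data.frame(SITE = site_ids(m)[i], N_A = length(a), N_B = length(b),
               U = mw$u, P = mw$p_value,
               MEDIAN_DIFF = stats::median(b) - stats::median(a),
               INVERTED = inv, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    warning("no shared sites with data in both groups")
    return(data.frame(SITE = character(), N_A = integer(), N_B = integer(),
                      U = numeric(), P = numeric(), P_BONF = numeric(),
                      P_BH = numeric(), MEDIAN_DIFF = numeric(),
                      INVERTED = logical()))
  }
  out <- do.call(rbind, rows)
  out$P_BONF <- adjust_pvalues(out$P, "bonferroni")
  out$P_BH <- adjust_pvalues(out$P, "bh")
  out <- out[, c("SITE", "N_A", "N_B", "U", "P", "P_BONF", "P_BH",
                 "MEDIAN_DIFF", "INVERTED")]
  if (delta > 0) out <- out[abs(out$MEDIAN_DIFF) >= delta, , drop = FALSE]
  out <- out[order(out$P_BH, -abs(out$MEDIAN_DIFF), out$SITE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
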