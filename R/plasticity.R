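MPL_METHODS <- c("iqr", "q95_q5", "sd", "range")

#' Per-site distribution summary
#'
#' Tukey five-number summary (via [stats::fivenum()]), mean, sample
#' standard deviation (n-1 denominator) and the three spread measures used
#' to quantify methylation plasticity: the interquartile range Q75-Q25,
#' the wider quantile range Q95-Q5, and the extreme difference (range,
#' max-min). The quantile-range quantiles use linear interpolation of
#' order statistics (type-7, [stats::quantile()]'s default), which for
#' some n differs from the Tukey hinges reported in `q1`/`q3`; both are
#' exposed, and `iqr` is defined from the type-7 quartiles.
#'
#' @param values beta values for one site; `NA` dropped; at least one
#'   non-missing value required.
#' @param site_id optional label.
#' @return a one-row `data.frame` with columns `site_id, n, min, q1,
#'   median, q3, max, mean, sd, iqr, q95_q5, range`. `sd` is `NA` when
#'   n < 2.
#' @export
summarize_site <- function(values, site_id = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0)
    stop("summarize_site needs at least one non-missing value", call. = FALSE)
  fn <- stats::fivenum(values)
  q <- stats::quantile(values, c(0.05, 0.25, 0.75, 0.95), type = 7,
                       names = FALSE)
  data.frame(site_id = site_id, n = n,
             min = fn[1], q1 = fn[2], median = fn[3], q3 = fn[4], max = fn[5],
             mean = mean(values),
             sd = if (n >= 2) stats::sd(values) else NA_real_,
             iqr = q[3] - q[2],
             q95_q5 = q[4] - q[1],
             range = fn[5] - fn[1],
             stringsAsFactors = FALSE)
}

#' Methylation plasticity (MPL) score of one site
#'
#' The MPL score quantifies how variable a site's methylation level is
#' across samples. Four spread measures are supported: `iqr` (Q75-Q25,
#' the default and the recommended measure: robust to outliers with 50%
#' of the data outside the range to support the variability), `q95_q5`
#' (wider, only 10% outside), `sd` (sample standard deviation) and
#' `range` (extreme difference max-min, maximally sensitive but unable to
#' tell an outlier from a true extreme).
#'
#' @param values beta values; `NA` dropped; at least 2 required.
#' @param method one of `"iqr"`, `"q95_q5"`, `"sd"`, `"range"`.
#' @return the selected spread measure (a single number).
#' @export
#' @examples
#' mpl_score(c(rep(0.05, 5), rep(0.95, 5)))            # iqr = 0.9
#' mpl_score(c(rep(0, 5), rep(1, 5)), method = "range") # 1
mpl_score <- function(values, method = "iqr") {
  if (length(method) != 1 || !(method %in% MPL_METHODS))
    stop("unknown MPL method '", paste(method, collapse = ","),
         "'; use one of ", paste(MPL_METHODS, collapse = ", "), call. = FALSE)
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("mpl_score needs at least 2 non-missing values", call. = FALSE)
  switch(method,
         iqr = {
           q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
           q[2] - q[1]
         },
         q95_q5 = {
           q <- stats::quantile(values, c(0.05, 0.95), type = 7, names = FALSE)
           q[2] - q[1]
         },
         sd = stats::sd(values),
         range = max(values) - min(values))
}

#' Rank sites by plasticity and keep the high-plasticity ones
#'
#' Scores every site of the matrix with [mpl_score()] and returns those at
#' or above the threshold, sorted by descending score with ties broken by
#' site ID. Sites with fewer than 2 non-missing values receive no score
#' and are excluded (a message reports how many).
#'
#' @param m a [beta_matrix()].
#' @param threshold minimum MPL score, in \[0,1\].
#' @param method spread measure, see [mpl_score()].
#' @return data frame with columns `site_id`, `n`, `score`.
#' @export
high_plasticity_sites <- function(m, threshold = 0.5, method = "iqr") {
  stopifnot(inherits(m, "beta_matrix"))
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]", call. = FALSE)
  if (!(method %in% MPL_METHODS))
    stop("unknown MPL method '", method, "'", call. = FALSE)
  if (nrow(m$values) == 0)
    return(data.frame(site_id = character(), n = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  ns <- apply(m$values, 1, function(x) sum(!is.na(x)))
  scorable <- ns >= 2
  if (any(!scorable))
    message(sum(!scorable), " site(s) with n < 2 excluded from MPL ranking")
  ids <- site_ids(m)[scorable]
  scores <- apply(m$values[scorable, , drop = FALSE], 1, mpl_score,
                  method = method)
  out <- data.frame(site_id = ids, n = ns[scorable], score = unname(scores),
                    stringsAsFactors = FALSE)
  out <- out[out$score >= threshold, , drop = FALSE]
  out <- out[order(-out$score, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two MPL measures across sites
#'
#' @param m a [beta_matrix()].
#' @param method_a,method_b spread measures, see [mpl_score()].
#' @return Pearson r of the per-site scores, or `NA` with a warning when
#'   one of the score vectors has zero variance (correlation undefined).
#' @export
measure_correlation <- function(m, method_a, method_b) {
  stopifnot(inherits(m, "beta_matrix"))
  ok <- apply(m$values, 1, function(x) sum(!is.na(x)) >= 2)
  if (sum(ok) < 3)
    stop("need at least 3 sites with defined scores", call. = FALSE)
  v <- m$values[ok, , drop = FALSE]
  a <- apply(v, 1, mpl_score, method = method_a)
  b <- apply(v, 1, mpl_score, method = method_b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in score vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "pearson")
}

#' Full plasticity table for a matrix
#'
#' One [summarize_site()] row per site (n >= 1), plus a `score` column for
#' the chosen measure (NA when n < 2).
#'
#' @inheritParams high_plasticity_sites
#' @return data frame, one row per site, in matrix site order.
#' @export
plasticity_table <- function(m, method = "iqr") {
  stopifnot(inherits(m, "beta_matrix"))
  rows <- lapply(seq_len(nrow(m$values)), function(i) {
    v <- m$values[i, ]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    s <- summarize_site(v, site_id = site_ids(m)[i])
    s$score <- if (length(v) >= 2) mpl_score(v, method = method) else NA_real_
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
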