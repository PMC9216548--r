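#' Classify the methylation tendency of a site
#'
#' A beta value of 0.5 marks balanced methylated/unmethylated probe
#' signals, so values in (0.5, 1\] reflect biased methylated and values in
#' \[0, 0.5) biased unmethylated signal. A one-degree-of-freedom
#' chi-square goodness-of-fit test (equal expected counts, no continuity
#' correction) on the below/above counts decides whether the imbalance is
#' significant: p <= alpha with more values above 0.5 gives a methylation
#' tendency site (MTS), p <= alpha with more below gives an unmethylation
#' tendency site (UTS), and p > alpha a nonbiased site (NTS; this label
#' also covers dual-tendency sites, whose multimodality is reported
#' separately by the split-methylation module). Values exactly equal to
#' 0.5 belong to neither interval and are excluded from both counts.
#'
#' @param values beta values for one site; `NA` dropped.
#' @param alpha significance level (default 0.05).
#' @param min_n minimum non-missing values required for a call (default 4,
#'   i.e. sample sizes larger than 3).
#' @param site_id,dataset_id optional labels.
#' @return an object of class `tendency_call`: list with `site_id`,
#'   `dataset_id`, `n`, `n_lower`, `n_upper`, `n_half`, `chi2`, `p_value`,
#'   `label` (`"MTS"`, `"UTS"` or `"NTS"`) and `strict_label`
#'   (see [strict_tendency()]). When every value is exactly 0.5 the site
#'   is NTS with p = 1 by convention (with a message).
#' @export
#' @examples
#' classify_tendency(rep(0.9, 20))$label     # "MTS"; chi2 = 20
classify_tendency <- function(values, alpha = 0.05, min_n = 4L,
                              site_id = NA_character_,
                              dataset_id = NA_character_) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < min_n)
    stop(structure(class = c("mplkit_insufficient_samples", "error",
                             "condition"),
                   list(message = paste0("tendency call needs at least ",
                                         min_n, " values (got ", n, ")"),
                        call = sys.call(-1))))
  if (any(values < 0 | values > 1))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  n_lower <- sum(values < 0.5)
  n_upper <- sum(values > 0.5)
  n_half <- n - n_lower - n_upper
  if (n_lower + n_upper == 0) {
    message("all values exactly 0.5; NTS by convention")
    chi2 <- 0; p <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(c(n_lower, n_upper)))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  label <- if (p <= alpha && n_upper > n_lower) "MTS"
           else if (p <= alpha && n_lower > n_upper) "UTS"
           else "NTS"
  structure(list(site_id = site_id, dataset_id = dataset_id, n = n,
                 n_lower = n_lower, n_upper = n_upper, n_half = n_half,
                 chi2 = chi2, p_value = p, label = label,
                 strict_label = strict_tendency(values)),
            class = "tendency_call")
}

#' @export
print.tendency_call <- function(x, ...) {
  cat(sprintf("tendency_call %s: %s (chi2 = %.3g, p = %.3g; %d below / %d above 0.5%s)\n",
              ifelse(is.na(x$site_id), "", x$site_id), x$label, x$chi2,
              x$p_value, x$n_lower, x$n_upper,
              if (x$n_half > 0) sprintf(", %d at 0.5", x$n_half) else ""))
  invisible(x)
}

#' Strict tendency label
#'
#' The strict variant requires all (100%) of a site's beta values across
#' samples to fall on one side of 0.5: every value > 0.5 gives
#' `strict_MTS`, every value < 0.5 gives `strict_UTS`, anything else
#' (including a value exactly at 0.5, which satisfies neither strict
#' inequality) gives `none`.
#'
#' @param values beta values; `NA` dropped; at least one required.
#' @return `"strict_MTS"`, `"strict_UTS"` or `"none"`.
#' @export
strict_tendency <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop("strict_tendency needs at least one value", call. = FALSE)
  if (all(values > 0.5)) "strict_MTS"
  else if (all(values < 0.5)) "strict_UTS"
  else "none"
}

#' Tendency inversion between two conditions
#'
#' An inversion -- a site called MTS under one condition and UTS under the
#' other -- marks strong differential methylation.
#'
#' @param call_a,call_b [classify_tendency()] calls for the same site.
#' @return `TRUE` iff one call is MTS and the other UTS.
#' @export
tendency_inversion <- function(call_a, call_b) {
  stopifnot(inherits(call_a, "tendency_call"),
            inherits(call_b, "tendency_call"))
  if (!identical(call_a$site_id, call_b$site_id))
    stop("tendency_inversion: calls are for different sites (",
         call_a$site_id, " vs ", call_b$site_id, ")", call. = FALSE)
  setequal(c(call_a$label, call_b$label), c("MTS", "UTS")) &&
    call_a$label != call_b$label
}

#' Tendency calls for every site, per study dataset
#'
#' Classifies each site within each study dataset (from the sample
#' sheet's `dataset_id`; without a sheet the whole matrix is one
#' dataset), and summarizes the MTS/UTS/NTS label fractions per dataset.
#' Datasets with fewer than `min_n` samples are skipped with a warning,
#' as are individual sites falling below `min_n` non-missing values.
#'
#' @param m a [beta_matrix()].
#' @param groups optional [sample_sheet()] covering `m`'s samples.
#' @param alpha,min_n see [classify_tendency()].
#' @return list with `calls` (data frame: SITE, DATASET, N, N_LOWER,
#'   N_UPPER, N_HALF, CHI2, P, LABEL, STRICT) and `summary` (per-dataset
#'   label fractions).
#' @export
tendency_table <- function(m, groups = NULL, alpha = 0.05, min_n = 4L) {
  stopifnot(inherits(m, "beta_matrix"))
  if (is.null(groups)) {
    ds <- stats::setNames(rep(if (is.null(m$dataset_id)) "all" else
      m$dataset_id, ncol(m$values)), sample_ids(m))
  } else {
    if (!all(sample_ids(m) %in% groups$sample_id))
      stop("sample sheet does not cover all matrix samples", call. = FALSE)
    ds <- stats::setNames(groups$dataset_id[match(sample_ids(m),
                                                  groups$sample_id)],
                          sample_ids(m))
  }
  calls <- list()
  for (d in unique(ds)) {
    cols <- names(ds)[ds == d]
    if (length(cols) < min_n) {
      warning("dataset ", d, " has fewer than ", min_n,
              " samples; skipped")
      next
    }
    v <- m$values[, cols, drop = FALSE]
    skipped <- 0L
    for (i in seq_len(nrow(v))) {
      tc <- tryCatch(classify_tendency(v[i, ], alpha = alpha, min_n = min_n,
                                       site_id = site_ids(m)[i],
                                       dataset_id = d),
                     mplkit_insufficient_samples = function(e) NULL)
      if (is.null(tc)) { skipped <- skipped + 1L; next }
      calls[[length(calls) + 1L]] <- data.frame(
        SITE = tc$site_id, DATASET = d, N = tc$n, N_LOWER = tc$n_lower,
        N_UPPER = tc$n_upper, N_HALF = tc$n_half, CHI2 = tc$chi2,
        P = tc$p_value, LABEL = tc$label, STRICT = tc$strict_label,
        stringsAsFactors = FALSE)
    }
    if (skipped > 0)
      warning(skipped, " site(s) in dataset ", d, " below min_n; skipped")
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(SITE = character(), DATASET = character(), N = integer(),
               N_LOWER = integer(), N_UPPER = integer(), N_HALF = integer(),
               CHI2 = numeric(), P = numeric(), LABEL = character(),
               STRICT = character())
  summ <- do.call(rbind, lapply(split(calls, calls$DATASET), function(cc)
    data.frame(DATASET = cc$DATASET[1], N_SITES = nrow(cc),
               FRAC_MTS = mean(cc$LABEL == "MTS"),
               FRAC_UTS = mean(cc$LABEL == "UTS"),
               FRAC_NTS = mean(cc$LABEL == "NTS"))))
  rownames(summ) <- NULL
  list(calls = calls, summary = summ)
}
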