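# Total absolute deviation of sorted[i..j] about its lower-median element,
# via prefix sums; `i` may be a vector, `j` is scalar. The lower median is
# an exact 1-D medoid of the interval and gives a deterministic tie-break.
interval_cost <- function(sorted, S, i, j) {
  m <- (i + j) %/% 2L
  (S[j + 1] - S[m] - S[m + 1] + S[i]) + sorted[m] * (2 * m - i - j)
}

# Exact 1-D k-medoids on sorted values: optimal clusters are contiguous
# runs, so dynamic programming over split points finds the global optimum
# of the total absolute-distance objective. Returns interval starts.
kmedoid_1d_dp <- function(sorted, k) {
  n <- length(sorted)
  S <- c(0, cumsum(sorted))
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  cost[1, ] <- vapply(seq_len(n), function(j)
    interval_cost(sorted, S, 1L, j), numeric(1))
  back[1, ] <- 1L
  if (k > 1) {
    for (kk in 2:k) {
      for (j in kk:n) {
        i_cand <- kk:j
        cand <- cost[kk - 1, i_cand - 1L] +
          interval_cost(sorted, S, i_cand, j)
        best <- which.min(cand)  # leftmost minimum: deterministic
        cost[kk, j] <- cand[best]
        back[kk, j] <- i_cand[best]
      }
    }
  }
  starts <- integer(k)
  j <- n
  for (kk in k:1) {
    starts[kk] <- back[kk, j]
    j <- starts[kk] - 1L
  }
  list(starts = starts, total_cost = cost[k, n])
}

#' One-dimensional k-medoids
#'
#' Partitioning around medoids on a vector of beta values with
#' absolute-difference distance. Because the data are one-dimensional,
#' the optimal clusters are contiguous runs of the sorted values, and the
#' partition minimizing the k-medoids objective (total absolute distance
#' to the nearest medoid, medoids being data points) is found exactly by
#' dynamic programming over split points -- the same objective the
#' classical BUILD+SWAP search descends on, solved to global optimality
#' and deterministically (interval medoids are lower medians; cost ties
#' break to the leftmost split). Input order is canonicalized by sorting
#' with a stable original-index mapping; medoids come out ascending.
#'
#' @param values numeric vector (`NA` dropped).
#' @param k number of clusters; must not exceed the number of distinct
#'   values.
#' @return list with `medoids` (ascending), `assignments` (cluster index
#'   per input value, in input order, `NA` where the input was missing)
#'   and `total_cost` (sum of absolute distances to assigned medoids).
#' @export
#' @examples
#' pam_1d(c(0.1, 0.1, 0.9, 0.9), 2)$medoids   # 0.1 0.9
pam_1d <- function(values, k) {
  keep <- !is.na(values)
  v <- values[keep]
  n <- length(v)
  n_distinct <- length(unique(v))
  if (length(k) != 1 || k < 1 || k != round(k))
    stop("k must be a positive integer", call. = FALSE)
  if (k > n_distinct)
    stop("k = ", k, " exceeds the number of distinct values (", n_distinct,
         ")", call. = FALSE)
  k <- as.integer(k)
  ord <- order(v)
  sorted <- v[ord]
  dp <- kmedoid_1d_dp(sorted, k)
  bounds <- c(dp$starts, n + 1L)
  clus_sorted <- rep(seq_len(k), diff(bounds))
  medoids <- vapply(seq_len(k), function(cl) {
    i <- bounds[cl]; j <- bounds[cl + 1L] - 1L
    sorted[(i + j) %/% 2L]
  }, numeric(1))
  assignments <- rep(NA_integer_, length(values))
  tmp <- integer(n)
  tmp[ord] <- clus_sorted
  assignments[keep] <- tmp
  list(medoids = medoids, assignments = assignments,
       total_cost = dp$total_cost)
}

# Average silhouette width for contiguous clusters of sorted 1-D values,
# computed exactly from prefix sums (mean |x_i - .| over an index range).
silhouette_1d <- function(sorted, starts) {
  n <- length(sorted)
  k <- length(starts)
  S <- c(0, cumsum(sorted))
  bounds <- c(starts, n + 1L)
  mean_dist <- function(i, lo, hi) {
    # mean absolute distance from sorted[i] to sorted[lo..hi] (self incl.)
    x <- sorted[i]
    il <- pmin(pmax(i, lo - 1L), hi)  # split point of the interval at x
    (x * (il - lo + 1) - (S[il + 1] - S[lo]) +
       (S[hi + 1] - S[il + 1]) - x * (hi - il)) / (hi - lo + 1)
  }
  s <- numeric(n)
  for (cl in seq_len(k)) {
    lo <- bounds[cl]; hi <- bounds[cl + 1L] - 1L
    size <- hi - lo + 1L
    idx <- lo:hi
    if (size == 1L) { s[idx] <- 0; next }
    a <- mean_dist(idx, lo, hi) * size / (size - 1L)  # exclude self
    b <- rep(Inf, size)
    for (other in seq_len(k)[-cl]) {
      olo <- bounds[other]; ohi <- bounds[other + 1L] - 1L
      b <- pmin(b, mean_dist(idx, olo, ohi))
    }
    s[idx] <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  }
  mean(s)
}

#' Duda-Hart homogeneity test
#'
#' Tests whether a set of beta values forms a single cluster. The values
#' are split in two by [pam_1d()]; the statistic is the ratio of the
#' two-cluster within-group sum of squares to the one-cluster sum of
#' squares, compared against the Duda & Hart critical value for dimension
#' p = 1,
#' `1 - 2/(pi*p) - z(alpha) * sqrt(2 * (1 - 8/(pi^2*p)) / (n*p))`.
#' The site is homogeneous iff the ratio is at or above the critical
#' value (a genuinely bimodal split drives the within-SS, and hence the
#' ratio, toward 0). All-identical input is homogeneous by convention
#' (both sums of squares vanish).
#'
#' @param values numeric vector (`NA` dropped); at least 4 values.
#' @param alpha significance level of the test (default 0.001, the
#'   conventional default for this homogeneity criterion).
#' @return list with `homogeneous` (logical), `dh_ratio`, `dh_critical`.
#' @export
duda_hart <- function(values, alpha = 0.001) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n < 4) stop("duda_hart needs at least 4 values", call. = FALSE)
  z <- stats::qnorm(1 - alpha)
  crit <- 1 - 2 / pi - z * sqrt(2 * (1 - 8 / pi^2) / n)
  ss1 <- sum((v - mean(v))^2)
  if (ss1 == 0) {
    message("all values identical; homogeneous by convention")
    return(list(homogeneous = TRUE, dh_ratio = 1, dh_critical = crit))
  }
  part <- pam_1d(v, 2)
  ss2 <- sum(vapply(1:2, function(cl) {
    x <- v[part$assignments == cl]
    sum((x - mean(x))^2)
  }, numeric(1)))
  ratio <- ss2 / ss1
  list(homogeneous = ratio >= crit, dh_ratio = ratio, dh_critical = crit)
}

#' Select the number of clusters for one site
#'
#' If [duda_hart()] accepts homogeneity the site has k = 1. Otherwise k
#' is chosen over 2..`k_max` (capped by the number of distinct values
#' minus one, and by n - 1) as the k maximizing the average silhouette
#' width of the [pam_1d()] partition, ties going to the smaller k. With
#' only two distinct values a heterogeneous site is k = 2 directly.
#'
#' @param values numeric vector (`NA` dropped); at least 4 values.
#' @param k_max largest cluster number considered (default 10).
#' @param alpha Duda-Hart significance level.
#' @param site_id optional label.
#' @return an object of class `split_call`: list with `site_id`,
#'   `homogeneous`, `k`, `medoids`, `assignments` (input order),
#'   `avg_silhouette` (`NA` for k = 1), `dh_ratio`, `dh_critical`.
#' @export
select_k <- function(values, k_max = 10L, alpha = 0.001,
                     site_id = NA_character_) {
  keep <- !is.na(values)
  v <- values[keep]
  n <- length(v)
  if (n < 4) stop("select_k needs at least 4 values", call. = FALSE)
  dh <- duda_hart(v, alpha = alpha)
  if (dh$homogeneous) {
    p1 <- pam_1d(values, 1)
    return(structure(list(site_id = site_id, homogeneous = TRUE, k = 1L,
                          medoids = p1$medoids,
                          assignments = p1$assignments,
                          avg_silhouette = NA_real_,
                          dh_ratio = dh$dh_ratio,
                          dh_critical = dh$dh_critical),
                     class = "split_call"))
  }
  n_distinct <- length(unique(v))
  upper <- min(k_max, n_distinct - 1L, n - 1L)
  ks <- if (upper < 2) 2L else 2:upper
  sorted <- sort(v)
  best_k <- NA_integer_; best_sil <- -Inf
  for (k in ks) {
    dp <- kmedoid_1d_dp(sorted, k)
    sil <- silhouette_1d(sorted, dp$starts)
    if (sil > best_sil + 1e-12) { best_sil <- sil; best_k <- k }
  }
  part <- pam_1d(values, best_k)
  structure(list(site_id = site_id, homogeneous = FALSE, k = best_k,
                 medoids = part$medoids, assignments = part$assignments,
                 avg_silhouette = best_sil, dh_ratio = dh$dh_ratio,
                 dh_critical = dh$dh_critical),
            class = "split_call")
}

#' @export
print.split_call <- function(x, ...) {
  cat(sprintf("split_call %s: %s (k = %d%s; DH ratio %.3f vs critical %.3f)\n",
              ifelse(is.na(x$site_id), "", x$site_id),
              if (x$homogeneous) "homogeneous" else "split", x$k,
              if (x$k > 1) paste0(", medoids ",
                                  paste(round(x$medoids, 3), collapse = "/"))
              else "",
              x$dh_ratio, x$dh_critical))
  invisible(x)
}

#' Detect split-methylation sites across a matrix
#'
#' Runs [select_k()] on every site; split sites are those with k >= 2,
#' i.e. sites whose beta values aggregate into two or more methylation
#' tendencies within the dataset (trimodal SNP-driven sites, sex-linked
#' bimodal sites, condition mixtures, ...). Sites with fewer than 4
#' non-missing values are skipped with a warning.
#'
#' @param m a [beta_matrix()] with at least 4 samples.
#' @param k_max,alpha see [select_k()].
#' @return list with `table` (data frame: SITE, HOMOGENEOUS, K, AVG_SIL,
#'   DH_RATIO, DH_CRITICAL, MEDOIDS as slash-separated text) and `calls`
#'   (named list of `split_call` objects).
#' @export
detect_split_sites <- function(m, k_max = 10L, alpha = 0.001) {
  stopifnot(inherits(m, "beta_matrix"))
  if (ncol(m$values) < 4)
    stop("detect_split_sites needs at least 4 samples", call. = FALSE)
  calls <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(m$values))) {
    id <- site_ids(m)[i]
    v <- m$values[i, ]
    if (sum(!is.na(v)) < 4) { skipped <- c(skipped, id); next }
    calls[[id]] <- select_k(v, k_max = k_max, alpha = alpha, site_id = id)
  }
  if (length(skipped))
    warning(length(skipped), " site(s) with < 4 non-missing values skipped: ",
            paste(utils::head(skipped, 3), collapse = ", "),
            if (length(skipped) > 3) ", ...")
  tab <- do.call(rbind, lapply(calls, function(x)
    data.frame(SITE = x$site_id, HOMOGENEOUS = x$homogeneous, K = x$k,
               AVG_SIL = x$avg_silhouette, DH_RATIO = x$dh_ratio,
               DH_CRITICAL = x$dh_critical,
               MEDOIDS = paste(signif(x$medoids, 6), collapse = "/"),
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  list(table = tab, calls = calls)
}

#' Stratify samples by combinations of split sites
#'
#' Each sample receives a composite label: the tuple of its per-site
#' cluster indices over the chosen split sites. Groups are the distinct
#' labels, ordered by descending size; combining s independent split
#' sites with k_i clusters can yield up to prod(k_i) groups (fewer when
#' site clusters are correlated, e.g. linked SNPs). A sample ordering for
#' heatmap display (grouped samples contiguous) is also returned.
#'
#' @param m a [beta_matrix()].
#' @param sites character vector of split-site IDs to combine.
#' @param calls optional result of [detect_split_sites()]; computed on
#'   `m[sites, ]` when absent. Every chosen site must have k >= 2.
#' @return list with `sites_used`, `labels` (data frame: SAMPLE, GROUP,
#'   one cluster column per site; GROUP is `NA` for samples missing a
#'   value at any chosen site), `group_count`, `group_sizes` and
#'   `sample_order`.
#' @export
stratify <- function(m, sites, calls = NULL) {
  stopifnot(inherits(m, "beta_matrix"))
  if (!all(sites %in% site_ids(m)))
    stop("sites not in matrix: ",
         paste(setdiff(sites, site_ids(m)), collapse = ", "), call. = FALSE)
  if (is.null(calls)) calls <- detect_split_sites(m[sites, ])
  cl <- calls$calls[sites]
  if (any(vapply(cl, is.null, logical(1))))
    stop("no split call for site(s): ",
         paste(sites[vapply(cl, is.null, logical(1))], collapse = ", "),
         call. = FALSE)
  bad <- vapply(cl, function(x) x$k < 2, logical(1))
  if (any(bad))
    stop("site(s) without split methylation (k = 1): ",
         paste(sites[bad], collapse = ", "), call. = FALSE)
  amat <- do.call(cbind, lapply(cl, function(x) x$assignments))
  colnames(amat) <- sites
  label <- apply(amat, 1, function(r)
    if (anyNA(r)) NA_character_ else paste(r, collapse = "."))
  sizes <- sort(table(label), decreasing = TRUE)
  group_of <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- data.frame(SAMPLE = sample_ids(m),
                       GROUP = unname(group_of[label]),
                       amat, check.names = FALSE, stringsAsFactors = FALSE)
  ord <- order(labels$GROUP, labels$SAMPLE, na.last = TRUE)
  list(sites_used = sites, labels = labels,
       group_count = length(sizes),
       group_sizes = as.integer(sizes),
       sample_order = labels$SAMPLE[ord])
}
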