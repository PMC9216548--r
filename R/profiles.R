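#' Round beta values to the r-beta grid
#'
#' Central rounding rule for the whole package: round-half-to-even at two
#' decimals (the behavior of base [round()]). Swapping in a half-up rule
#' would be a one-line change here and nowhere else.
#'
#' @param x numeric vector of beta values.
#' @return values rounded to 2 decimals.
#' @export
round_beta <- function(x) round(x, 2)

#' The 101-point r-beta grid (0.00, 0.01, ..., 1.00)
#' @return numeric vector of length 101.
#' @export
rbeta_grid <- function() seq(0, 1, by = 0.01)

#' Build an r-beta methylation profile
#'
#' Beta values are rounded to two decimals, assigning each to one of 101
#' grid points 0.00..1.00; the profile is the vector of sample proportions
#' at each grid point (bin count divided by the number of non-missing
#' values). The proportions therefore sum to exactly 1, and the curve of
#' proportions against the grid is the site's methylation profile: its
#' width, height and peak position summarize methylation intensity and
#' its variability across samples.
#'
#' @param values beta values in \[0,1\] for one site across the samples of
#'   one study dataset; `NA`s are excluded before binning.
#' @param site_id,dataset_id optional labels carried on the result.
#' @return an object of class `methylation_profile`: list with `site_id`,
#'   `dataset_id`, `grid` (length 101), `proportions` (length 101),
#'   `counts` and `n_samples` (the post-exclusion count).
#' @export
#' @examples
#' p <- rbeta_profile(c(0.91, 0.92, 0.92, 0.5))
#' p$proportions[p$grid == 0.92]   # 0.5
rbeta_profile <- function(values, site_id = NA_character_,
                          dataset_id = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) == 0)
    stop("rbeta_profile needs at least one non-missing value", call. = FALSE)
  if (any(values < 0 | values > 1))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  bin <- as.integer(round(round_beta(values) * 100)) + 1L
  counts <- tabulate(bin, nbins = 101L)
  structure(list(site_id = site_id, dataset_id = dataset_id,
                 grid = rbeta_grid(),
                 proportions = counts / length(values),
                 counts = counts,
                 n_samples = length(values)),
            class = "methylation_profile")
}

#' @export
print.methylation_profile <- function(x, ...) {
  cat("methylation_profile", if (!is.na(x$site_id)) x$site_id,
      if (!is.na(x$dataset_id)) paste0("[", x$dataset_id, "]"),
      "n =", x$n_samples, "\n")
  top <- order(x$proportions, decreasing = TRUE)[1:3]
  top <- top[x$proportions[top] > 0]
  cat("  top grid points:",
      paste(sprintf("%.2f (%.3f)", x$grid[top], x$proportions[top]),
            collapse = ", "), "\n")
  invisible(x)
}

# Moving-average smoothing; the grid carries proportion mass, so values
# outside it are zero and the window is zero-padded at the edges.
smooth_ma <- function(y, window) {
  half <- (window - 1L) %/% 2L
  n <- length(y)
  padded <- c(rep(0, half), y, rep(0, half))
  vapply(seq_len(n), function(i) mean(padded[i:(i + 2L * half)]), numeric(1))
}

#' Find peaks in an r-beta profile
#'
#' Local maxima of the moving-average-smoothed proportion vector whose
#' topographic prominence (height above the higher of the two saddle
#' minima separating it from taller terrain or the profile boundary) is at
#' least `min_prominence`. Multiple peaks signal split methylation; the
#' defaults (5-bin window, prominence 0.01) are package choices, calibrated
#' so that Beta-mixture component peaks at the package's default component
#' spread (prominence ~0.02 and up, even for components near the grid edge)
#' clear the cut while multinomial sampling ripple (prominence below 0.001
#' at a few hundred samples) does not, and cross-checked against the
#' cluster counts of [select_k()] on well-separated mixtures.
#'
#' @param p a [rbeta_profile()] result.
#' @param min_prominence minimum prominence of a reported peak.
#' @param smooth_window odd moving-average window in grid bins.
#' @return data frame with columns `grid_point` and `height` (smoothed),
#'   sorted by grid point.
#' @export
profile_peaks <- function(p, min_prominence = 0.01, smooth_window = 5L) {
  stopifnot(inherits(p, "methylation_profile"))
  if (smooth_window %% 2 == 0 || smooth_window < 1)
    stop("smooth_window must be an odd positive integer", call. = FALSE)
  y <- smooth_ma(p$proportions, as.integer(smooth_window))
  n <- length(y)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i == 1) -Inf else y[i - 1]
    right <- if (i == n) -Inf else y[i + 1]
    # plateau rule: first index of a flat top counts, later ones do not
    is_max[i] <- y[i] > left && y[i] >= right && y[i] > 0
  }
  idx <- which(is_max)
  keep <- logical(length(idx))
  prom <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    higher_l <- which(y[seq_len(i - 1)] > y[i])
    base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):(i - 1)])
              else if (i > 1) min(y[seq_len(i - 1)]) else y[i]
    higher_r <- which(y[(i + 1):n] > y[i]) + i
    base_r <- if (i == n) y[i]
              else if (length(higher_r)) min(y[(i + 1):(min(higher_r) - 1)])
              else min(y[(i + 1):n])
    prom[j] <- y[i] - max(base_l, base_r)
    keep[j] <- prom[j] >= min_prominence
  }
  data.frame(grid_point = p$grid[idx[keep]], height = y[idx[keep]])
}

#' Gaussian kernel density of beta values
#'
#' Thin wrapper over [stats::density()] with the support fixed to
#' \[-0.05, 1.05\] and 512 evaluation points, for display of beta-value
#' frequency distributions. Bandwidth defaults to Silverman's
#' rule-of-thumb (`nrd0`); for a degenerate constant input, where the
#' rule collapses to zero, a sharp fixed bandwidth of 0.005 is used so a
#' single spike at the value is still rendered.
#'
#' @param values numeric beta values (`NA` dropped); at least 2 required.
#' @param bandwidth optional positive bandwidth override.
#' @return list with `grid`, `density` and `bandwidth`.
#' @export
kde_density <- function(values, bandwidth = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2)
    stop("kde_density needs at least 2 values", call. = FALSE)
  bw <- if (!is.null(bandwidth)) {
    if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
    bandwidth
  } else if (stats::sd(values) == 0) 0.005 else stats::bw.nrd0(values)
  d <- stats::density(values, bw = bw, from = -0.05, to = 1.05, n = 512)
  list(grid = d$x, density = d$y, bandwidth = d$bw)
}

#' Serialize profiles
#'
#' `profile_to_json` emits `{site, dataset, n, proportions:[101]}`;
#' `profiles_to_tsv` writes long-format rows (SITE, GRID, PROPORTION) for
#' one or more profiles.
#'
#' @param p a [rbeta_profile()].
#' @return `profile_to_json`: a JSON string.
#' @export
profile_to_json <- function(p) {
  stopifnot(inherits(p, "methylation_profile"))
  jsonlite::toJSON(list(site = p$site_id, dataset = p$dataset_id,
                        n = p$n_samples, proportions = p$proportions),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname profile_to_json
#' @param profiles a list of [rbeta_profile()] objects.
#' @param path destination TSV.
#' @export
profiles_to_tsv <- function(profiles, path) {
  if (inherits(profiles, "methylation_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(SITE = p$site_id, DATASET = p$dataset_id, GRID = p$grid,
               PROPORTION = p$proportions)))
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE)
  invisible(path)
}
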