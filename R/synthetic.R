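SITE_KINDS <- c("MTS_like", "UTS_like", "NTS_like", "split_hwe", "split_sex")

#' Specify one synthetic methylation site
#'
#' A site is a mixture of 1-3 Beta-distributed components. Component
#' noise is parameterized by (mean, concentration kappa): shape
#' parameters are `mean * kappa` and `(1 - mean) * kappa`, so kappa = 50
#' gives a realistic per-component spread of roughly 0.05-0.07 on the
#' beta scale. Kinds:
#' * `MTS_like`, `UTS_like`, `NTS_like`: one component (mean above,
#'   below, at 0.5).
#' * `split_hwe`: three components at Hardy-Weinberg genotype proportions
#'   q^2 / 2q(1-q) / (1-q)^2 (ascending means = TT unmethylated, CT
#'   partially methylated, CC methylated; `allele_freq` is the frequency
#'   q of the methylation-abolishing allele).
#' * `split_sex`: two components, `component_means = c(female, male)`,
#'   drawn by each sample's sex.
#'
#' @param site_id site identifier.
#' @param kind one of `r paste(SITE_KINDS, collapse=", ")`.
#' @param component_means 1-3 means in (0, 1), sorted ascending for
#'   `split_hwe`.
#' @param concentration Beta precision kappa (> 0), default 50.
#' @param allele_freq required for `split_hwe`: q in (0, 1).
#' @return a `site_spec` list.
#' @export
site_spec <- function(site_id, kind, component_means, concentration = 50,
                      allele_freq = NULL) {
  if (!(kind %in% SITE_KINDS))
    stop("unknown site kind '", kind, "'", call. = FALSE)
  component_means <- as.numeric(component_means)
  if (any(component_means <= 0 | component_means >= 1))
    stop("component means must lie strictly in (0, 1)", call. = FALSE)
  n_comp <- length(component_means)
  if (kind == "split_hwe") {
    if (n_comp != 3)
      stop("split_hwe requires exactly 3 component means", call. = FALSE)
    if (is.null(allele_freq) || allele_freq <= 0 || allele_freq >= 1)
      stop("split_hwe requires allele_freq in (0, 1)", call. = FALSE)
    if (is.unsorted(component_means, strictly = TRUE))
      stop("split_hwe component means must be strictly ascending",
           call. = FALSE)
  } else if (kind == "split_sex") {
    if (n_comp != 2)
      stop("split_sex requires exactly 2 component means (female, male)",
           call. = FALSE)
  } else if (n_comp != 1) {
    stop(kind, " requires exactly 1 component mean", call. = FALSE)
  }
  if (concentration <= 0)
    stop("concentration must be positive", call. = FALSE)
  structure(list(site_id = as.character(site_id), kind = kind,
                 component_means = component_means,
                 concentration = concentration,
                 allele_freq = allele_freq),
            class = "site_spec")
}

#' Generate a synthetic beta matrix with truth labels
#'
#' Emulates the statistical structure real methylome matrices show:
#' genome-wide bimodality (most sites near 0 or 1), tendency structure,
#' genotype-driven trimodal split sites at Hardy-Weinberg proportions and
#' sex-linked bimodal sites. Per sample and site, a mixture component is
#' drawn according to the site kind, then the beta value is drawn from
#' that component's Beta distribution; draws at exactly 0 or 1 are nudged
#' into \[1e-6, 1 - 1e-6\] to avoid degenerate bins. Fully reproducible:
#' identical `(specs, n_samples, seed, sex_ratio)` give identical output.
#'
#' @param specs list of [site_spec()] objects.
#' @param n_samples number of samples (>= 4).
#' @param seed RNG seed (integer).
#' @param sex_ratio probability that a sample is female.
#' @param dataset_id dataset label for the matrix and sheet.
#' @param sample_prefix prefix for generated sample IDs.
#' @param condition condition label recorded in the sample sheet.
#' @return list with `beta` (a [beta_matrix()]), `samples` (a
#'   [sample_sheet()]) and `truth` (list: `sites` data frame with
#'   `site_id`, `kind`, `n_components`, `allele_freq`; `assignments`
#'   integer matrix of per-sample component indices).
#' @export
generate <- function(specs, n_samples, seed, sex_ratio = 0.5,
                     dataset_id = "SIM", sample_prefix = "S",
                     condition = "A") {
  if (inherits(specs, "site_spec")) specs <- list(specs)
  if (!all(vapply(specs, inherits, logical(1), "site_spec")))
    stop("specs must be a list of site_spec objects", call. = FALSE)
  if (n_samples < 4) stop("n_samples must be at least 4", call. = FALSE)
  set.seed(as.integer(seed))
  ids <- sprintf("%s%04d", sample_prefix, seq_len(n_samples))
  sex <- ifelse(stats::runif(n_samples) < sex_ratio, "F", "M")
  sheet <- sample_sheet(ids, dataset_id, tissue = "synthetic",
                        cell_type = "synthetic", condition = condition,
                        sex = sex)
  n_sites <- length(specs)
  values <- matrix(NA_real_, n_sites, n_samples)
  assign <- matrix(NA_integer_, n_sites, n_samples)
  for (i in seq_len(n_sites)) {
    sp <- specs[[i]]
    comp <- switch(sp$kind,
      split_hwe = {
        q <- sp$allele_freq
        sample.int(3L, n_samples, replace = TRUE,
                   prob = c(q^2, 2 * q * (1 - q), (1 - q)^2))
      },
      split_sex = ifelse(sex == "F", 1L, 2L),
      rep(1L, n_samples))
    mu <- sp$component_means[comp]
    v <- stats::rbeta(n_samples, mu * sp$concentration,
                      (1 - mu) * sp$concentration)
    values[i, ] <- pmin(pmax(v, 1e-6), 1 - 1e-6)
    assign[i, ] <- comp
  }
  site_id <- vapply(specs, `[[`, character(1), "site_id")
  rownames(values) <- site_id; colnames(values) <- ids
  rownames(assign) <- site_id; colnames(assign) <- ids
  truth_sites <- data.frame(
    site_id = site_id,
    kind = vapply(specs, `[[`, character(1), "kind"),
    n_components = vapply(specs, function(s) length(s$component_means),
                          integer(1)),
    allele_freq = vapply(specs, function(s)
      if (is.null(s$allele_freq)) NA_real_ else s$allele_freq, numeric(1)),
    stringsAsFactors = FALSE)
  list(beta = beta_matrix(values, dataset_id = dataset_id),
       samples = sheet,
       truth = list(sites = truth_sites, assignments = assign))
}

#' Preset benchmark corpus
#'
#' A fixed, fully reproducible bundle for validating the whole pipeline
#' offline: 1000 sites across 200 samples in two balanced condition
#' groups. Site composition: 60% methylation-tendency-like (component
#' means 0.70-0.92), 35% unmethylation-tendency-like (0.08-0.30), 3%
#' nonbiased (mean 0.50), 1.5% Hardy-Weinberg trimodal split sites
#' (means 0.04/0.45/0.89, allele frequency 0.5) and 0.5% sex-linked
#' bimodal sites (means 0.54/0.82). Fifty engineered differential sites
#' (25 methylated-side, 25 unmethylated-side) shift their mean by 0.30
#' between the condition groups while both group means stay on the same
#' side of 0.5, so every non-split site keeps a well-defined tendency
#' truth label. Component concentration is kappa = 50 throughout.
#'
#' @param seed RNG seed; every random choice (base means, sexes,
#'   genotypes, beta draws) derives from it.
#' @return list with `beta` (1000 x 200 [beta_matrix()]), `samples`
#'   ([sample_sheet()] with `condition` `groupA`/`groupB`), and `truth`
#'   (list: `sites` data frame with `site_id`, `kind`, `true_k`,
#'   `expected_label`, `is_differential`, `allele_freq`; `assignments`
#'   component-index matrix).
#' @export
preset_corpus <- function(seed = 1) {
  seed <- as.integer(seed)
  n_per_group <- 100L
  counts <- c(MTS_like = 600L, UTS_like = 350L, NTS_like = 30L,
              split_hwe = 15L, split_sex = 5L)
  set.seed(seed)
  mts_means <- stats::runif(counts["MTS_like"], 0.70, 0.92)
  uts_means <- stats::runif(counts["UTS_like"], 0.08, 0.30)
  # differential sites: first 25 of each tendency block; the shifted mean
  # keeps a >= 0.05 margin from 0.5 so the pooled tendency label survives
  diff_mts <- 1:25
  diff_uts <- 1:25
  mts_means[diff_mts] <- stats::runif(25, 0.85, 0.92)
  uts_means[diff_uts] <- stats::runif(25, 0.08, 0.15)
  mts_means_b <- mts_means; mts_means_b[diff_mts] <- mts_means[diff_mts] - 0.30
  uts_means_b <- uts_means; uts_means_b[diff_uts] <- uts_means[diff_uts] + 0.30
  ids <- sprintf("cg%06d", seq_len(sum(counts)))
  kind <- rep(names(counts), counts)
  build_specs <- function(mm, um) {
    idx <- 0L
    specs <- vector("list", sum(counts))
    means_list <- c(as.list(mm), as.list(um),
                    rep(list(0.5), counts["NTS_like"]),
                    rep(list(c(0.04, 0.45, 0.89)), counts["split_hwe"]),
                    rep(list(c(0.54, 0.82)), counts["split_sex"]))
    for (i in seq_along(specs)) {
      specs[[i]] <- site_spec(ids[i], kind[i], means_list[[i]],
                              concentration = 50,
                              allele_freq = if (kind[i] == "split_hwe") 0.5
                                            else NULL)
    }
    specs
  }
  bundle_a <- generate(build_specs(mts_means, uts_means), n_per_group,
                       seed = seed + 1L, dataset_id = "SIM",
                       sample_prefix = "A", condition = "groupA")
  bundle_b <- generate(build_specs(mts_means_b, uts_means_b), n_per_group,
                       seed = seed + 2L, dataset_id = "SIM",
                       sample_prefix = "B", condition = "groupB")
  values <- cbind(bundle_a$beta$values, bundle_b$beta$values)
  sheet <- rbind(bundle_a$samples, bundle_b$samples)
  class(sheet) <- c("sample_sheet", "data.frame")
  is_diff <- logical(sum(counts))
  is_diff[diff_mts] <- TRUE
  is_diff[counts["MTS_like"] + diff_uts] <- TRUE
  true_k <- ifelse(kind == "split_hwe", 3L,
                   ifelse(kind == "split_sex", 2L, ifelse(is_diff, 2L, 1L)))
  expected_label <- c(MTS_like = "MTS", UTS_like = "UTS", NTS_like = "NTS",
                      split_hwe = NA, split_sex = NA)[kind]
  truth_sites <- data.frame(site_id = ids, kind = kind, true_k = true_k,
                            expected_label = unname(expected_label),
                            is_differential = is_diff,
                            allele_freq = ifelse(kind == "split_hwe", 0.5,
                                                 NA_real_),
                            stringsAsFactors = FALSE)
  list(beta = beta_matrix(values, dataset_id = "SIM"),
       samples = sheet,
       truth = list(sites = truth_sites,
                    assignments = cbind(bundle_a$truth$assignments,
                                        bundle_b$truth$assignments)))
}
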