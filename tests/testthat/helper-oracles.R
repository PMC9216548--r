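# Independent oracles used across the suite. These are deliberately naive
# (sort + interpolate, exhaustive enumeration) and share no code with the
# implementation paths they check.

# Type-7 quantile by hand: linear interpolation of sorted order statistics.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Two-pass sample variance.
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Exhaustive k-medoid search: minimum total absolute cost over all
# C(n, k) medoid subsets (medoids are data points).
oracle_pam_cost <- function(values, k) {
  idx <- utils::combn(length(values), k)
  costs <- apply(idx, 2, function(ii) {
    meds <- values[ii]
    sum(vapply(values, function(v) min(abs(v - meds)), numeric(1)))
  })
  min(costs)
}

# Exact Mann-Whitney two-sided p by full enumeration of labelings.
oracle_mw_exact <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  labelings <- utils::combn(n_a + n_b, n_a)
  u_all <- apply(labelings, 2, function(ii)
    sum(r[ii]) - n_a * (n_a + 1) / 2)
  m <- n_a * n_b
  u_lo <- min(u_obs, m - u_obs); u_hi <- m - u_lo
  min(1, mean(u_all <= u_lo) + mean(u_all >= u_hi))
}

# Hand-rolled Bonferroni and BH step-up adjustments.
oracle_bonferroni <- function(p) pmin(1, p * length(p))
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# Small beta_matrix fixture with controllable content.
fixture_matrix <- function(values, sites = NULL, samples = NULL,
                           dataset_id = NULL) {
  values <- as.matrix(values)
  if (is.null(sites)) sites <- sprintf("cg%04d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(ncol(values)))
  beta_matrix(values, sites, samples, dataset_id = dataset_id)
}

# One unimodal Beta-noise site, mean mu, concentration kappa.
beta_site <- function(n, mu, kappa = 50) {
  stats::rbeta(n, mu * kappa, (1 - mu) * kappa)
}
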