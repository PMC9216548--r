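test_that("pam_1d solves small instances exactly", {
  p <- pam_1d(c(0.1, 0.1, 0.9, 0.9), 2)
  expect_equal(p$medoids, c(0.1, 0.9))
  expect_equal(p$total_cost, 0)
  expect_equal(p$assignments, c(1L, 1L, 2L, 2L))

  # k = 1: the medoid is a median element (minimizer of total |.| deviation)
  set.seed(61)
  v <- runif(9)
  p1 <- pam_1d(v, 1)
  expect_equal(p1$medoids, sort(v)[5])
  expect_equal(p1$total_cost, sum(abs(v - p1$medoids)))

  # oracle equivalence: cost matches exhaustive medoid search, n <= 10
  for (i in 1:15) {
    n <- sample(5:10, 1)
    k <- sample(2:3, 1)
    v <- round(runif(n), 3)
    if (length(unique(v)) < k + 1) next
    p <- pam_1d(v, k)
    expect_equal(p$total_cost, oracle_pam_cost(v, k), tolerance = 1e-12)
    expect_true(!is.unsorted(p$medoids, strictly = TRUE))
    expect_setequal(unique(p$assignments), seq_len(k))
  }
  expect_error(pam_1d(c(0.5, 0.5, 0.5), 2), "distinct")
})

test_that("pam_1d is invariant to input order and keeps NA positions", {
  set.seed(62)
  v <- c(runif(20, 0, 0.2), runif(20, 0.8, 1))
  p <- pam_1d(v, 2)
  perm <- sample(length(v))
  pp <- pam_1d(v[perm], 2)
  expect_equal(pp$medoids, p$medoids)
  expect_equal(pp$assignments, p$assignments[perm])
  vna <- c(v[1:10], NA, v[11:40])
  pn <- pam_1d(vna, 2)
  expect_true(is.na(pn$assignments[11]))
  expect_equal(pn$medoids, p$medoids)
})

test_that("Duda-Hart separates engineered splits from single components", {
  # fully separated bimodal: within-SS of the 2-split is 0
  dh <- duda_hart(c(rep(0.05, 50), rep(0.95, 50)))
  expect_equal(dh$dh_ratio, 0)
  expect_false(dh$homogeneous)
  # critical value formula, p = 1, alpha = 0.001, n = 100
  expect_equal(dh$dh_critical,
               1 - 2 / pi - qnorm(0.999) * sqrt(2 * (1 - 8 / pi^2) / 100),
               tolerance = 1e-12)

  expect_message(dhc <- duda_hart(rep(0.4, 10)), "identical")
  expect_true(dhc$homogeneous)

  set.seed(63)
  dhn <- duda_hart(rnorm(200, 0.5, 0.02))
  expect_true(dhn$homogeneous)
  expect_error(duda_hart(c(0.1, 0.9)), "at least 4")
})

test_that("cluster-number selection recovers constructed mixtures", {
  set.seed(64)
  # bimodal 50/50: k = 2, assignments match components exactly
  comp <- rep(1:2, each = 50)
  v <- ifelse(comp == 1, beta_site(100, 0.05, 200), beta_site(100, 0.95, 200))
  sk <- select_k(v)
  expect_false(sk$homogeneous)
  expect_equal(sk$k, 2L)
  expect_equal(sk$assignments, comp)
  expect_gt(sk$avg_silhouette, 0.8)

  # trimodal at the canonical split-site means 0.04 / 0.45 / 0.89
  comp3 <- sample(1:3, 600, TRUE, prob = c(0.35, 0.30, 0.35))
  mu <- c(0.04, 0.45, 0.89)[comp3]
  v3 <- rbeta(600, mu * 50, (1 - mu) * 50)
  sk3 <- select_k(v3)
  expect_equal(sk3$k, 3L)
  expect_equal(order(sk3$medoids), 1:3)
  expect_gt(mean(sk3$assignments == comp3), 0.95)

  # unimodal: homogeneous, k = 1
  sku <- select_k(beta_site(200, 0.5))
  expect_true(sku$homogeneous)
  expect_equal(sku$k, 1L)
  expect_true(is.na(sku$avg_silhouette))
})

test_that("cluster selection is equivariant under affine rescaling", {
  set.seed(65)
  v <- c(beta_site(60, 0.1, 100), beta_site(60, 0.8, 100))
  a <- select_k(v)
  b <- select_k(v * 0.5 + 0.2)
  expect_equal(b$k, a$k)
  expect_equal(b$assignments, a$assignments)
})

test_that("split detection flags exactly the engineered multi-cluster site", {
  set.seed(66)
  v <- t(vapply(1:12, function(i) beta_site(60, 0.75, 80), numeric(60)))
  v[5, ] <- c(beta_site(30, 0.1, 100), beta_site(30, 0.9, 100))
  m <- fixture_matrix(v)
  res <- suppressWarnings(detect_split_sites(m))
  expect_equal(res$table$SITE[res$table$K >= 2], "cg0005")
  expect_equal(res$table$K[res$table$SITE == "cg0005"], 2L)
  expect_true(all(res$table$HOMOGENEOUS[res$table$SITE != "cg0005"]))

  # all-unimodal matrix: no split sites
  res2 <- detect_split_sites(fixture_matrix(v[-5, , drop = FALSE]))
  expect_equal(sum(res2$table$K >= 2), 0L)

  # sparse sites are skipped with a warning
  v3 <- v; v3[1, -c(1, 2)] <- NA
  expect_warning(res3 <- detect_split_sites(fixture_matrix(v3)), "skipped")
  expect_false("cg0001" %in% res3$table$SITE)
})

test_that("HWE split sites yield clusters at genotype proportions", {
  set.seed(67)
  sp <- site_spec("cgHWE", "split_hwe", c(0.04, 0.45, 0.89),
                  allele_freq = 0.5)
  sim <- generate(list(sp), 2000, seed = 99)
  v <- sim$beta$values[1, ]
  p3 <- pam_1d(v, 3)
  prop <- tabulate(p3$assignments, 3) / 2000
  # binomial sampling error at n = 2000: 3 * sqrt(p q / n) < 0.034
  expect_lt(abs(prop[1] - 0.25), 0.034)
  expect_lt(abs(prop[2] - 0.50), 0.034)
  expect_lt(abs(prop[3] - 0.25), 0.034)
  # clusters track the true genotype components
  expect_gt(mean(p3$assignments == sim$truth$assignments[1, ]), 0.97)
})

test_that("stratification combines split sites combinatorially", {
  set.seed(68)
  n <- 80
  g1 <- sample(1:2, n, TRUE); g2 <- sample(1:2, n, TRUE)
  g3 <- sample(1:2, n, TRUE)
  mk <- function(g) ifelse(g == 1, beta_site(n, 0.1, 300),
                           beta_site(n, 0.9, 300))
  v <- rbind(mk(g1), mk(g2), mk(g3), beta_site(n, 0.5, 100))
  m <- fixture_matrix(v, sites = c("sA", "sB", "sC", "sD"))

  one <- stratify(m, "sA")
  expect_equal(one$group_count, 2L)

  three <- stratify(m, c("sA", "sB", "sC"))
  expect_equal(three$group_count, 8L)  # all combinations present
  expect_lte(three$group_count, 2L * 2L * 2L)
  expect_true(!is.unsorted(rev(three$group_sizes)))
  expect_equal(sum(three$group_sizes), n)

  # two perfectly correlated sites collapse to 2 of the 4 combinations
  vdup <- rbind(mk(g1), mk(g1))
  mdup <- fixture_matrix(vdup, sites = c("sA", "sB"))
  corr <- stratify(mdup, c("sA", "sB"))
  expect_equal(corr$group_count, 2L)

  # a homogeneous site cannot stratify
  expect_error(stratify(m, "sD"), "k = 1")
  expect_error(stratify(m, "missing_site"), "not in matrix")
})
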