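test_that("Mann-Whitney agrees with full enumeration on small samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p_value, 0.1)  # 2/20 labelings as extreme

  # identical multisets: p = 1
  expect_equal(mann_whitney(c(0.2, 0.4, 0.8), c(0.2, 0.4, 0.8))$p_value, 1)

  set.seed(71)
  for (i in 1:12) {
    a <- round(runif(sample(3:8, 1)), 3)
    b <- round(runif(sample(3:8, 1)), 3)
    if (anyDuplicated(c(a, b))) next
    mw <- mann_whitney(a, b, mode = "exact")
    expect_equal(mw$p_value, oracle_mw_exact(a, b), tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "at least one")
})

test_that("exact and normal modes agree near the switchover size", {
  set.seed(72)
  a <- runif(30); b <- runif(30)
  pe <- mann_whitney(a, b, mode = "exact")$p_value
  pn <- mann_whitney(a, b, mode = "normal")$p_value
  expect_lt(abs(pe - pn), 0.005)
})

test_that("group swap preserves p and reflects U", {
  set.seed(73)
  a <- runif(18); b <- runif(22, 0.2, 1)
  m1 <- mann_whitney(a, b)
  m2 <- mann_whitney(b, a)
  expect_equal(m1$p_value, m2$p_value)
  expect_equal(m1$u, length(a) * length(b) - m2$u)
})

test_that("Bonferroni threshold scales the alpha level", {
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  # at 450k array scale the threshold lands just above 1e-7
  expect_equal(bonferroni_threshold(0.05, 485512), 0.05 / 485512)
  expect_lt(abs(bonferroni_threshold(0.05, 485512) - 1.0299e-7), 1e-11)
  expect_error(bonferroni_threshold(1.2, 10), "\\(0, 1\\]")
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
})

test_that("p-value adjustment matches the hand formulas", {
  set.seed(74)
  p <- runif(10)
  expect_equal(adjust_pvalues(p, "bonferroni"), oracle_bonferroni(p))
  expect_equal(adjust_pvalues(p, "bh"), oracle_bh(p))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(numeric(0), "bh"), numeric(0))
  expect_error(adjust_pvalues(c(0.5, 1.3), "bh"), "\\[0, 1\\]")
  # bonferroni caps at 1; BH is monotone along the sorted raw p
  big <- runif(50, 0.5, 1)
  expect_true(all(adjust_pvalues(big, "bonferroni") <= 1))
  bh <- adjust_pvalues(big, "bh")
  expect_true(!is.unsorted(bh[order(big)]))
  expect_true(all(bh >= big))
})

test_that("differential tables detect strong shifts and flag inversions", {
  set.seed(75)
  n <- 50
  va <- rbind(beta_site(n, 0.2, 300), beta_site(n, 0.5, 80),
              beta_site(n, 0.8, 300))
  vb <- rbind(beta_site(n, 0.8, 300), beta_site(n, 0.5, 80),
              beta_site(n, 0.8, 300))
  m <- fixture_matrix(cbind(va, vb),
                      samples = c(sprintf("A%02d", 1:n), sprintf("B%02d", 1:n)))
  tab <- differential_table(m, sprintf("A%02d", 1:n), sprintf("B%02d", 1:n))
  row1 <- tab[tab$SITE == "cg0001", ]
  expect_lt(row1$P_BH, 1e-7)
  expect_true(row1$INVERTED)
  expect_gt(row1$MEDIAN_DIFF, 0.5)
  row3 <- tab[tab$SITE == "cg0003", ]
  expect_false(row3$INVERTED)
  expect_gt(row3$P, 0.001)
  # the shifted site sorts first
  expect_equal(tab$SITE[1], "cg0001")
})

test_that("label swap negates the median difference, p unchanged", {
  set.seed(76)
  v <- matrix(rbeta(5 * 40, 2, 2), 5, 40)
  m <- fixture_matrix(v)
  ga <- sample_ids(m)[1:20]; gb <- sample_ids(m)[21:40]
  t1 <- differential_table(m, ga, gb)
  t2 <- differential_table(m, gb, ga)
  ord <- match(t1$SITE, t2$SITE)
  expect_equal(t2$P[ord], t1$P)
  expect_equal(t2$MEDIAN_DIFF[ord], -t1$MEDIAN_DIFF)
})

test_that("null comparisons are calibrated at the nominal level", {
  set.seed(77)
  n_sites <- 400
  v <- matrix(rbeta(n_sites * 80, 5, 5), n_sites, 80)
  m <- fixture_matrix(v)
  perm <- sample(sample_ids(m))
  tab <- differential_table(m, perm[1:40], perm[41:80])
  frac <- mean(tab$P <= 0.05)
  # binomial band around 0.05 at 400 sites (3 sigma ~ 0.033)
  expect_gt(frac, 0.017)
  expect_lt(frac, 0.083)
})

test_that("degenerate group specifications are rejected", {
  m <- fixture_matrix(matrix(runif(40), 4, 10))
  expect_error(differential_table(m, c("S001", "SX"), c("S003")), "not in")
  expect_error(differential_table(m, c("S001"), c("S001", "S002")),
               "overlap")
  one <- fixture_matrix(matrix(runif(10), 1, 10))
  tab <- differential_table(one, sample_ids(one)[1:5], sample_ids(one)[6:10])
  expect_equal(nrow(tab), 1L)
})
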