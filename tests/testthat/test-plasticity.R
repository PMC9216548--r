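test_that("site summaries match order-statistics oracles", {
  # n = 5: fivenum is the sorted vector itself
  s <- summarize_site(c(0.5, 0, 1, 0.75, 0.25))
  expect_equal(unlist(s[c("min", "q1", "median", "q3", "max")]),
               c(min = 0, q1 = 0.25, median = 0.5, q3 = 0.75, max = 1))
  expect_equal(s$range, 1)

  # constant vector: all spreads zero
  sc <- summarize_site(rep(0.7, 20))
  expect_equal(sc$sd, 0)
  expect_equal(sc$iqr, 0)
  expect_equal(sc$q95_q5, 0)
  expect_equal(sc$range, 0)

  # engineered bimodal: type-7 quartiles at the component values
  sb <- summarize_site(c(rep(0.1, 50), rep(0.9, 50)))
  expect_equal(sb$iqr, 0.8)
  expect_equal(sb$range, 0.8)

  # random vectors against brute-force sort-and-interpolate oracle
  set.seed(41)
  for (n in c(4, 11, 37, 200)) {
    v <- runif(n)
    s <- summarize_site(v)
    expect_equal(s$iqr, oracle_quantile(v, 0.75) - oracle_quantile(v, 0.25),
                 tolerance = 1e-12)
    expect_equal(s$q95_q5, oracle_quantile(v, 0.95) - oracle_quantile(v, 0.05),
                 tolerance = 1e-12)
    expect_equal(s$sd, oracle_sd(v), tolerance = 1e-12)
    expect_equal(s$min, min(v))
    expect_equal(s$max, max(v))
  }
  expect_error(summarize_site(NA_real_), "non-missing")
})

test_that("MPL scores honor the method argument and spread ordering", {
  expect_equal(mpl_score(rep(0.3, 10), "iqr"), 0)
  expect_equal(mpl_score(rep(0.3, 10), "sd"), 0)
  expect_equal(mpl_score(rep(0.3, 10), "range"), 0)
  expect_equal(mpl_score(c(rep(0, 50), rep(1, 50)), "range"), 1)
  set.seed(42)
  v <- runif(100)
  expect_equal(mpl_score(v, "sd"), oracle_sd(v), tolerance = 1e-12)
  expect_error(mpl_score(v, "mad"), "unknown MPL method")
  expect_error(mpl_score(0.5), "at least 2")

  # iqr <= q95_q5 <= range on random sites; all measures invariant under
  # sample permutation and under the mirror transform v -> 1 - v
  for (i in 1:20) {
    x <- rbeta(sample(5:60, 1), runif(1, 0.5, 5), runif(1, 0.5, 5))
    sc <- vapply(c("iqr", "q95_q5", "range"), mpl_score, numeric(1),
                 values = x)
    expect_true(sc["iqr"] <= sc["q95_q5"] + 1e-12)
    expect_true(sc["q95_q5"] <= sc["range"] + 1e-12)
    for (meth in c("iqr", "q95_q5", "sd", "range")) {
      expect_equal(mpl_score(sample(x), meth), mpl_score(x, meth))
      expect_equal(mpl_score(1 - x, meth), mpl_score(x, meth),
                   tolerance = 1e-12)
    }
  }
})

test_that("high-plasticity ranking finds engineered split sites", {
  set.seed(43)
  v <- rbind(matrix(rep(beta_site(40, 0.8, 80), 9), nrow = 9, byrow = TRUE),
             c(rep(0.05, 20), rep(0.95, 20)))
  m <- fixture_matrix(v)
  hits <- high_plasticity_sites(m, threshold = 0.5)
  expect_equal(hits$site_id, "cg0010")
  expect_gte(hits$score, 0.5)

  # threshold 0 returns every scorable site, sorted by descending score
  all_sites <- high_plasticity_sites(m, threshold = 0)
  expect_equal(nrow(all_sites), 10L)
  expect_true(!is.unsorted(rev(all_sites$score)))

  empty <- fixture_matrix(matrix(numeric(0), 0, 4))
  expect_equal(nrow(high_plasticity_sites(empty, 0.5)), 0L)
  expect_error(high_plasticity_sites(m, threshold = 1.5), "\\[0, 1\\]")

  # sites with n < 2 are excluded with a message
  v2 <- v; v2[1, -1] <- NA
  expect_message(h2 <- high_plasticity_sites(fixture_matrix(v2), 0),
                 "excluded")
  expect_false("cg0001" %in% h2$site_id)
})

test_that("measure correlation matches the textbook Pearson formula", {
  set.seed(44)
  v <- matrix(rbeta(500 * 30, 2, 2), nrow = 500)
  m <- fixture_matrix(v)
  r <- measure_correlation(m, "iqr", "sd")
  a <- apply(v, 1, mpl_score, method = "iqr")
  b <- apply(v, 1, mpl_score, method = "sd")
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r, r_oracle, tolerance = 1e-12)
  expect_equal(measure_correlation(m, "iqr", "iqr"), 1)

  const <- fixture_matrix(matrix(0.5, 5, 10))
  expect_warning(rc <- measure_correlation(const, "iqr", "sd"), "undefined")
  expect_true(is.na(rc))
})

test_that("plasticity tables cover every site with consistent scores", {
  set.seed(45)
  m <- fixture_matrix(matrix(runif(60), 6, 10))
  tab <- plasticity_table(m)
  expect_equal(tab$site_id, site_ids(m))
  expect_equal(tab$score, tab$iqr)
  expect_true(all(tab$min <= tab$q1 & tab$q1 <= tab$median &
                  tab$median <= tab$q3 & tab$q3 <= tab$max))
})
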