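test_that("site specs enforce kind-specific structure", {
  expect_error(site_spec("s", "split_hwe", c(0.1, 0.9), allele_freq = 0.5),
               "exactly 3")
  expect_error(site_spec("s", "split_hwe", c(0.1, 0.5, 0.9)), "allele_freq")
  expect_error(site_spec("s", "split_hwe", c(0.9, 0.5, 0.1),
                         allele_freq = 0.3), "ascending")
  expect_error(site_spec("s", "split_sex", 0.5), "exactly 2")
  expect_error(site_spec("s", "MTS_like", c(0.7, 0.9)), "exactly 1")
  expect_error(site_spec("s", "MTS_like", 1.2), "strictly in")
  expect_error(site_spec("s", "odd_kind", 0.5), "unknown site kind")
  expect_error(site_spec("s", "MTS_like", 0.8, concentration = 0),
               "positive")
})

test_that("generation is deterministic and respects the seed contract", {
  specs <- list(site_spec("a", "MTS_like", 0.8),
                site_spec("b", "split_sex", c(0.54, 0.82)))
  g1 <- generate(specs, 50, seed = 123)
  g2 <- generate(specs, 50, seed = 123)
  expect_identical(g1$beta$values, g2$beta$values)
  expect_identical(g1$samples, g2$samples)
  expect_identical(g1$truth$assignments, g2$truth$assignments)
  g3 <- generate(specs, 50, seed = 124)
  expect_false(identical(g1$beta$values, g3$beta$values))
  expect_error(generate(specs, 3, seed = 1), "at least 4")
})

test_that("HWE genotype components appear at p2/2pq/q2 proportions", {
  sp <- site_spec("hwe", "split_hwe", c(0.04, 0.45, 0.89), allele_freq = 0.5)
  sim <- generate(list(sp), 10000, seed = 5)
  prop <- tabulate(sim$truth$assignments[1, ], 3) / 10000
  expect_lt(abs(prop[1] - 0.25), 0.02)
  expect_lt(abs(prop[2] - 0.50), 0.02)
  expect_lt(abs(prop[3] - 0.25), 0.02)
  # the r-beta profile of the site carries three peaks near the means
  pk <- profile_peaks(rbeta_profile(sim$beta$values[1, ]))
  expect_equal(nrow(pk), 3L)
  expect_lt(max(abs(sort(pk$grid_point) - c(0.04, 0.45, 0.89))), 0.03)
})

test_that("sex-linked sites follow the sample sheet sexes", {
  sp <- site_spec("x1", "split_sex", c(0.54, 0.82))
  sim <- generate(list(sp), 3000, seed = 6, sex_ratio = 0.5)
  v <- sim$beta$values[1, ]
  f <- sim$samples$sex == "F"
  expect_lt(abs(median(v[f]) - 0.54), 0.02)
  expect_lt(abs(median(v[!f]) - 0.82), 0.02)
  expect_lt(abs(mean(f) - 0.5), 0.05)
})

test_that("marginal means track the mixed component means", {
  set.seed(7)
  specs <- list(site_spec("m1", "MTS_like", 0.8),
                site_spec("u1", "UTS_like", 0.15),
                site_spec("h1", "split_hwe", c(0.04, 0.45, 0.89),
                          allele_freq = 0.5))
  sim <- generate(specs, 4000, seed = 7)
  # 3-standard-error bands; per-component sd <= 0.5 on the beta scale
  expect_lt(abs(mean(sim$beta$values["m1", ]) - 0.8), 3 * 0.5 / sqrt(4000))
  expect_lt(abs(mean(sim$beta$values["u1", ]) - 0.15), 3 * 0.5 / sqrt(4000))
  hwe_mean <- 0.25 * 0.04 + 0.5 * 0.45 + 0.25 * 0.89
  expect_lt(abs(mean(sim$beta$values["h1", ]) - hwe_mean),
            3 * 0.5 / sqrt(4000))
  expect_true(all(sim$beta$values > 0 & sim$beta$values < 1))
})

test_that("mirrored specs produce exactly swapped tendency labels", {
  means <- c(0.85, 0.7, 0.2, 0.35)
  fwd <- lapply(seq_along(means), function(i)
    site_spec(paste0("s", i), if (means[i] > 0.5) "MTS_like" else "UTS_like",
              means[i]))
  mir <- lapply(seq_along(means), function(i)
    site_spec(paste0("s", i), if (means[i] > 0.5) "UTS_like" else "MTS_like",
              1 - means[i]))
  a <- generate(fwd, 150, seed = 8)
  b <- generate(mir, 150, seed = 8)
  la <- vapply(seq_along(means), function(i)
    classify_tendency(a$beta$values[i, ])$label, character(1))
  lb <- vapply(seq_along(means), function(i)
    classify_tendency(b$beta$values[i, ])$label, character(1))
  swap <- c(MTS = "UTS", UTS = "MTS", NTS = "NTS")
  expect_equal(lb, unname(swap[la]))
})

test_that("the preset corpus has the documented composition", {
  corpus <- preset_corpus(3)
  expect_equal(dim(corpus$beta), c(1000L, 200L))
  expect_equal(nrow(corpus$samples), 200L)
  expect_equal(table(corpus$samples$condition)[["groupA"]], 100L)
  kinds <- table(corpus$truth$sites$kind)
  expect_equal(kinds[["MTS_like"]], 600L)
  expect_equal(kinds[["UTS_like"]], 350L)
  expect_equal(kinds[["NTS_like"]], 30L)
  expect_equal(kinds[["split_hwe"]], 15L)
  expect_equal(kinds[["split_sex"]], 5L)
  expect_equal(sum(corpus$truth$sites$is_differential), 50L)
  # reproducible from the seed
  expect_identical(corpus$beta$values, preset_corpus(3)$beta$values)
})
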