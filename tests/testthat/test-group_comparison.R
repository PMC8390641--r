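test_that("Welch test agrees with the closed-form computation to 1e-10", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  y <- c(0.5, 0.6, 0.7, 0.8)
  w <- welch_t_test(x, y)
  o <- welch_oracle(x, y)
  expect_equal(w$t_statistic, o$t, tolerance = 1e-10)
  expect_equal(w$p_value, o$p, tolerance = 1e-10)
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(3:40, 1), mean = runif(1), sd = runif(1, 0.1, 2))
    b <- rnorm(sample(3:40, 1), mean = runif(1), sd = runif(1, 0.1, 2))
    w <- welch_t_test(a, b)
    o <- welch_oracle(a, b)
    expect_equal(w$t_statistic, o$t, tolerance = 1e-10)
    expect_equal(w$df, o$df, tolerance = 1e-10)
    expect_equal(w$p_value, o$p, tolerance = 1e-10)
    # symmetry: swapping groups negates t, preserves p
    ws <- welch_t_test(b, a)
    expect_equal(ws$t_statistic, -w$t_statistic, tolerance = 1e-12)
    expect_equal(ws$p_value, w$p_value, tolerance = 1e-12)
  }
})

test_that("Welch degenerate cases follow the documented conventions", {
  w <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t_statistic, 0)
  expect_equal(w$p_value, 1)
  both_const_eq <- welch_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(both_const_eq$p_value, 1)
  both_const_ne <- welch_t_test(c(2, 2, 2), c(3, 3))
  expect_equal(both_const_ne$p_value, 0)
  expect_true(both_const_ne$degenerate)
  expect_error(welch_t_test(1, c(1, 2)), "at least 2")
})

test_that("paired test agrees with the closed-form computation to 1e-10", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    pt <- paired_t_test(a, b)
    o <- paired_oracle(a, b)
    expect_equal(pt$t_statistic, o$t, tolerance = 1e-10)
    expect_equal(pt$p_value, o$p, tolerance = 1e-10)
  }
  # identical pairs: t = 0, p = 1
  eq <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
  # constant nonzero differences: p -> 0 limit
  const <- paired_t_test(c(1, 2, 3), c(0, 1, 2))
  expect_equal(const$p_value, 0)
  expect_true(const$degenerate)
  # pairs with missing members are dropped first
  miss <- paired_t_test(c(1, 2, NA, 4), c(0.5, 2.5, 3, 3))
  expect_identical(miss$n_pairs, 3L)
  expect_error(paired_t_test(c(1, NA), c(1, 2)), "at least 2")
})

test_that("Bonferroni-adjusted levels reproduce the published arithmetic", {
  expect_equal(signif(bonferroni_alpha(0.05, 79)$adjusted_alpha, 3), 6.33e-4)
  expect_equal(signif(bonferroni_alpha(0.05, 76)$adjusted_alpha, 3), 6.58e-4)
  expect_equal(bonferroni_alpha(0.05, 10)$adjusted_alpha, 0.005)
  expect_equal(bonferroni_alpha(0.05, 1)$adjusted_alpha, 0.05)
  corr <- bonferroni_alpha(0.05, 79)
  expect_identical(corr$adjusted_alpha * corr$m_tests, corr$family_alpha)
  expect_error(bonferroni_alpha(0.05, 0), "positive integer")
})

test_that("group summaries compute mean/median over non-missing, sorted by median", {
  loc <- make_toy_locus(seed = 5)
  catalog <- derive_junctions(loc$model)
  fr <- data.frame(sample_id = sprintf("s%d", 1:7),
                   cterm_fraction = c(0.042, 0.042, 0.042, 0, 0, 0.03, NA))
  ann <- data.frame(sample_id = sprintf("s%d", 1:7),
                    stratum = c("Sp", "Sp", "Sp", "Th", "Th", "Th", "Em"))
  gs <- group_summaries(fr, ann)
  expect_identical(gs$group, c("Sp", "Th"))   # Em has no non-missing values
  expect_equal(gs$median_fraction, c(0.042, 0))
  expect_equal(gs$mean_fraction, c(0.042, 0.01))
  expect_identical(gs$n, c(3L, 3L))
  expect_identical(attr(gs, "omitted"), "Em")
  # invariant to sample order
  perm <- sample(7)
  gs2 <- group_summaries(fr[perm, ], ann[perm, ])
  expect_equal(gs2, gs, ignore_attr = TRUE)
})

test_that("the comparison suite detects an injected group effect at the Bonferroni level", {
  loc <- make_toy_locus(seed = 5)
  catalog <- derive_junctions(loc$model)
  sim <- simulate_cohort(catalog, strata = "TT", n_per_group = 50L,
                         baseline_fraction = 0.01,
                         group_effect = c(truncating = 0.02),
                         depth = 5000L, seed = 17)
  fr <- fractions_table(sim$counts, catalog)
  cl <- classify_samples(sim$annotations)
  out <- run_comparison_suite(fr, cl, contrasts = c("missense", "truncating"))
  expect_identical(nrow(out$results), 2L)
  expect_identical(out$correction$m_tests, 2L)
  tr <- out$results[out$results$contrast == "truncating", ]
  expect_true(tr$significant)
  expect_true(tr$p_value <= out$correction$adjusted_alpha)
  mi <- out$results[out$results$contrast == "missense", ]
  expect_false(mi$significant)
  # fixed family-size override
  fixed <- run_comparison_suite(fr, cl, contrasts = c("missense", "truncating"),
                                fixed_m = 79)
  expect_equal(fixed$correction$adjusted_alpha, 0.05 / 79)
})

test_that("per-class truncating contrasts run inside eligible strata", {
  loc <- make_toy_locus(seed = 5)
  catalog <- derive_junctions(loc$model)
  sim <- simulate_cohort(catalog, strata = "TT", n_per_group = 30L,
                         baseline_fraction = 0.02, depth = 2000L, seed = 23)
  fr <- fractions_table(sim$counts, catalog)
  cl <- classify_samples(sim$annotations)
  out <- run_comparison_suite(fr, cl)
  expect_true(all(c("missense", "truncating") %in% out$results$contrast))
  by_class <- intersect(out$results$contrast,
                        c("nonsense", "frameshift", "splice_site"))
  expect_true(length(by_class) >= 1L)
  expect_identical(out$correction$m_tests, nrow(out$results))
})

test_that("empty cohorts give an empty result with no correction", {
  loc <- make_toy_locus(seed = 5)
  catalog <- derive_junctions(loc$model)
  sim <- simulate_cohort(catalog, strata = "TT", n_per_group = 3L, seed = 3)
  fr <- fractions_table(sim$counts, catalog)
  cl <- classify_samples(sim$annotations)
  out <- run_comparison_suite(fr, cl)
  expect_identical(nrow(out$results), 0L)
  expect_null(out$correction)
})

test_that("paired tumor-normal comparison uses matched fractions", {
  loc <- make_toy_locus(seed = 5)
  catalog <- derive_junctions(loc$model)
  sim <- simulate_cohort(catalog, strata = "TT", n_per_group = 20L,
                         groups = "WT", baseline_fraction = 0.02,
                         paired = TRUE, normal_effect = 0.01,
                         depth = 5000L, seed = 29)
  fr <- fractions_table(sim$counts, catalog)
  cl <- classify_samples(sim$annotations)
  pairs <- build_pairs(cl, status_filter = "WT")
  expect_identical(nrow(pairs), 20L)
  pc <- paired_comparison(fr, pairs)
  expect_identical(pc$test_kind, "paired_two_tailed")
  expect_true(pc$mean_b > pc$mean_a)   # normals simulated higher
  # hand check against the oracle
  o <- paired_oracle(fr$cterm_fraction[match(pairs$tumor_id, fr$sample_id)],
                     fr$cterm_fraction[match(pairs$normal_id, fr$sample_id)])
  expect_equal(pc$p_value, o$p, tolerance = 1e-10)
})

test_that("bundled GTEx table matches its published shape", {
  tab <- gtex_table1()
  expect_identical(nrow(tab), 53L)
  sp <- tab[tab$tissue == "Spleen", ]
  expect_equal(sp$median_fraction, 0.042)
  expect_equal(sp$mean_fraction, 0.0539)
  expect_identical(sp$n, 118L)
})
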