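# FFMQ scoring, t-tests, correlations, adjustment, and the relationship
# battery.

test_that("FFMQ scoring sums with reverse keying", {
  expect_identical(score_ffmq(rep(3, 39)), 117L)
  expect_identical(score_ffmq(rep(3, 39), reverse_set = c(4, 7, 9)), 117L)
  expect_identical(score_ffmq(rep(5, 39)), 195L)

  set.seed(50)
  items <- sample(1:5, 39, replace = TRUE)
  rev_set <- sample(39, 12)
  oracle <- 0L
  for (i in 1:39) {
    oracle <- oracle + if (i %in% rev_set) 6L - items[i] else items[i]
  }
  expect_identical(score_ffmq(items, rev_set), oracle)

  expect_error(score_ffmq(rep(3, 38)), class = "dfc_invalid_argument")
  expect_error(score_ffmq(c(rep(3, 38), 6)), class = "dfc_invalid_argument")
})

test_that("paired t-test matches the hand oracle and stats::t.test", {
  res <- paired_ttest(c(2, 3, 5), c(1, 2, 3))
  expect_equal(res$estimate, 4)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-4, 2), tolerance = 1e-12)

  set.seed(51)
  x <- rnorm(15); y <- rnorm(15)
  mine <- paired_ttest(x, y)
  ref <- t.test(x - y)  # one-sample on differences is the same test
  expect_equal(mine$estimate, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)

  flipped <- paired_ttest(y, x)
  expect_equal(flipped$estimate, -mine$estimate)
  expect_equal(flipped$p, mine$p)

  same <- paired_ttest(x, x + rnorm(15, sd = 1e-8))
  expect_lt(abs(same$estimate), 5)  # finite, not degenerate
  expect_error(paired_ttest(x, x), class = "dfc_degenerate_input")
  expect_error(paired_ttest(1:2, 2:3), class = "dfc_invalid_argument")
})

test_that("pearson correlation matches the covariance-formula oracle", {
  x <- 1:10
  expect_equal(pearson_corr(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_corr(x, -x)$estimate, -1)

  set.seed(52)
  a <- rnorm(20); b <- rnorm(20)
  res <- pearson_corr(a, b)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$estimate, oracle, tolerance = 1e-12)
  expect_identical(res$n, 20L)
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), class = "dfc_degenerate_input")
})

test_that("spearman correlation is rank pearson, agreeing with cor.test", {
  set.seed(53)
  x <- rnorm(15)
  expect_equal(spearman_corr(x, exp(x))$estimate, 1)
  expect_equal(spearman_corr(x, -x)$estimate, -1)

  # ties handled by average ranks
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 7)
  mine <- spearman_corr(xt, yt)
  expect_equal(mine$estimate, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman"))
  expect_equal(mine$estimate, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_corr(rep(2, 5), rnorm(5)), class = "dfc_degenerate_input")
})

test_that("p-value adjustment follows Holm and Bonferroni", {
  expect_equal(adjust_pvalues(0.03), 0.03)
  expect_equal(adjust_pvalues(0.01, method = "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(rep(0.01, 6), method = "bonferroni")[1], 0.06)

  p <- c(0.01, 0.02, 0.04)
  # Holm step-down by hand: 3*0.01, max(0.03, 2*0.02), max(0.04, 0.04)
  expect_equal(adjust_pvalues(p, "holm"), c(0.03, 0.04, 0.04))

  set.seed(54)
  pr <- runif(8)
  holm <- adjust_pvalues(pr, "holm")
  bonf <- adjust_pvalues(pr, "bonferroni")
  expect_true(all(holm <= bonf))
  expect_true(all(holm >= pr))
  expect_true(all(bonf <= 1))
  expect_error(adjust_pvalues(c(0.1, 1.2)), class = "dfc_invalid_argument")
})

test_that("the analysis table recovers an injected trait effect", {
  spec <- cohort_spec(n_subjects = 200, r_trait = 0.6, seed = 60)
  coh <- generate_cohort(spec)
  tab <- analysis_table(coh$subjects, coh$occupancy)
  row <- tab[tab$variable_a == "ffmq_total" & tab$variable_b == "delta_TRS", ]
  expect_identical(nrow(row), 1L)
  expect_gte(row$estimate, 0.45)
  expect_lte(row$estimate, 0.72)
  expect_identical(row$family, "mindfulness")
  # families carry adjusted p >= raw p
  expect_true(all(tab$p_adjusted >= tab$p - 1e-15))
  expect_identical(sum(tab$family == "cortisol"), 6L)
  expect_identical(sum(tab$family == "mindfulness"), 3L)
})

test_that("the analysis table is invariant to subject ordering", {
  spec <- cohort_spec(n_subjects = 25, seed = 61)
  coh <- generate_cohort(spec)
  tab1 <- analysis_table(coh$subjects, coh$occupancy)
  set.seed(62)
  shuffle <- sample(nrow(coh$subjects))
  occ_shuffle <- coh$occupancy[sample(nrow(coh$occupancy)), ]
  tab2 <- analysis_table(coh$subjects[shuffle, ], occ_shuffle)
  expect_equal(tab1$estimate, tab2$estimate, tolerance = 1e-12)
  expect_equal(tab1$p, tab2$p, tolerance = 1e-12)
})

test_that("tiny cohorts skip tests instead of failing", {
  spec <- cohort_spec(n_subjects = 2, seed = 63)
  coh <- generate_cohort(spec)
  tab <- analysis_table(coh$subjects, coh$occupancy)
  expect_identical(nrow(tab), 0L)
  expect_gt(length(attr(tab, "skipped")), 0)
})

test_that("stressed cohorts show the designated-state occupancy drop", {
  spec <- cohort_spec(n_subjects = 40, seed = 64)
  coh <- generate_cohort(spec)
  tab <- analysis_table(coh$subjects, coh$occupancy)
  drop <- tab[tab$variable_a == "TRS_RS2" & tab$variable_b == "TRS_RS1", ]
  expect_lt(drop$estimate, 0)   # RS2 lower than RS1
  expect_lt(drop$p, 0.01)
  recover <- tab[tab$variable_a == "TRS_RS3" & tab$variable_b == "TRS_RS2", ]
  expect_gt(recover$p, 0.001)   # no built-in RS2 -> RS3 group change
})
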