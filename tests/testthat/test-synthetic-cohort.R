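# Synthetic cohort generators: determinism, distributional contracts,
# ground-truth structure.

test_that("generated centroids are valid correlation-structured matrices", {
  cs <- generate_centroids(k = 1, n_roi = 4, seed = 0)
  m <- cs$matrices[[1]]
  expect_identical(dim(m), c(4L, 4L))
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 4))

  cs5 <- generate_centroids(k = 5, n_roi = 114, seed = 7)
  for (m in cs5$matrices) {
    expect_identical(dim(m), c(114L, 114L))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
    expect_lte(max(abs(m[lower.tri(m)])), 1)
  }
  # pairwise distinct off-diagonal patterns
  vecs <- lapply(cs5$matrices, vectorize_upper)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_lt(cor(rank(vecs[[i]]), rank(vecs[[j]])), 0.95)
    }
  }
})

test_that("centroid generation is deterministic and validates arguments", {
  a <- generate_centroids(k = 2, n_roi = 10, seed = 3)
  b <- generate_centroids(k = 2, n_roi = 10, seed = 3)
  expect_identical(a, b)
  expect_error(generate_centroids(k = 0, n_roi = 10), class = "dfc_invalid_argument")
  expect_error(generate_centroids(k = 2, n_roi = 2), class = "dfc_invalid_argument")
})

test_that("state sequences hit their target occupancy", {
  one <- generate_state_sequence(100, 1.0, mean_dwell = 5, seed = 1)
  expect_true(all(one$labels == 1L))

  long <- generate_state_sequence(20000, c(0.5, 0.5), mean_dwell = 10, seed = 2)
  frac1 <- mean(long$labels == 1L)
  expect_gte(frac1, 0.48)
  expect_lte(frac1, 0.52)

  short <- generate_state_sequence(10, c(0.3, 0.7), mean_dwell = 3, seed = 4)
  expect_length(short$labels, 10L)
  expect_true(all(short$labels %in% 1:2))

  expect_error(generate_state_sequence(10, c(0.5, 0.4)),
               class = "dfc_invalid_argument")
})

test_that("exact-quota sequences realise the target exactly", {
  for (seed in 1:5) {
    sq <- generate_state_sequence(292, c(0.24, 0.18, 0.20, 0.19, 0.19),
                                  mean_dwell = 12, seed = seed, exact = TRUE)
    counts <- tabulate(sq$labels, 5)
    expect_identical(sum(counts), 292L)
    expect_true(all(abs(counts / 292 - c(0.24, 0.18, 0.20, 0.19, 0.19)) <= 1 / 292 + 1e-12))
  }
})

test_that("covariance-switching BOLD realises the active state's correlations", {
  ident <- centroid_set(list(diag(4)))
  sq <- generate_state_sequence(5000, 1.0, mean_dwell = 10, seed = 5)
  ts <- generate_bold_run(sq, ident, noise_sd = 0.1, seed = 5)
  cc <- cor(ts$values)
  expect_lt(max(abs(cc[lower.tri(cc)])), 0.05)

  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.8
  cs <- centroid_set(list(m))
  ts2 <- generate_bold_run(sq, cs, noise_sd = 0.01, seed = 6)
  r12 <- cor(ts2$values[, 1], ts2$values[, 2])
  expect_gte(r12, 0.70)
  expect_lte(r12, 0.88)
})

test_that("BOLD runs have the contracted shape and are seed-deterministic", {
  cs <- generate_centroids(k = 2, n_roi = 114, seed = 9)
  sq <- generate_state_sequence(300, c(0.5, 0.5), mean_dwell = 50, seed = 9)
  ts <- generate_bold_run(sq, cs, seed = 9)
  expect_identical(dim(ts$values), c(300L, 114L))
  ts_again <- generate_bold_run(sq, cs, seed = 9)
  expect_identical(ts$values, ts_again$values)

  # valid coupling range but indefinite (eigenvalue -0.8): rejected
  bad_m <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  bad <- centroid_set(list(bad_m))
  sq2 <- generate_state_sequence(10, 1.0, seed = 1)
  expect_error(generate_bold_run(sq2, bad), class = "dfc_invalid_argument")
})

test_that("cortisol series rise after onset and are deterministic", {
  flat <- generate_cortisol_series(5, 0, noise_sd = 0, seed = 1)
  expect_equal(flat$concentrations, rep(5, 5))

  resp <- generate_cortisol_series(5, 10, noise_sd = 0, seed = 1)
  expect_gt(resp$timepoints[which.max(resp$concentrations)], 0)

  a <- generate_cortisol_series(5, 10, noise_sd = 0.1, seed = 42)
  b <- generate_cortisol_series(5, 10, noise_sd = 0.1, seed = 42)
  expect_identical(a$concentrations, b$concentrations)
  expect_true(all(a$concentrations > 0))

  expect_error(generate_cortisol_series(5, 1, timepoints = c(0, 0, 10)),
               class = "dfc_invalid_argument")
})

test_that("motion traces carry FD spikes at roughly the requested rate", {
  mp <- generate_motion_params(5000, spike_rate = 0.02, seed = 3)
  expect_identical(dim(mp), c(5000L, 6L))
  fd <- framewise_displacement(mp)
  rate <- mean(fd > 0.2)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.05)
})

test_that("cohorts have the contracted cardinality and determinism", {
  spec <- cohort_spec(n_subjects = 2, n_roi = 8, volumes_per_run = 60,
                      mean_dwell = 10, seed = 5)
  coh <- generate_cohort(spec, include_bold = TRUE)
  expect_identical(nrow(coh$subjects), 2L)
  expect_identical(length(coh$runs), 2L)
  expect_identical(length(coh$runs[[1]]), 3L)
  expect_identical(nrow(coh$occupancy), 2L * 3L * 5L)

  coh2 <- generate_cohort(spec, include_bold = TRUE)
  expect_identical(coh$subjects, coh2$subjects)
  expect_identical(coh$runs[[1]][[1]]$values, coh2$runs[[1]][[1]]$values)
})

test_that("ground-truth trait coupling matches the injected effect size", {
  spec <- cohort_spec(n_subjects = 200, r_trait = 0.6, seed = 21)
  coh <- generate_cohort(spec)
  gt <- merge(coh$ground_truth$latent_delta, coh$subjects)
  r <- cor(gt$ffmq_total, gt$latent_delta)
  expect_gte(r, 0.5)
  expect_lte(r, 0.7)
})

test_that("a null cohort has zero mean designated-state change", {
  spec <- cohort_spec(n_subjects = 150, occupancy_post = c(0.30, 0.16, 0.18, 0.18, 0.18),
                      r_trait = 0, r_cortisol = 0, seed = 8)
  coh <- generate_cohort(spec)
  ld <- coh$ground_truth$latent_delta$latent_delta
  expect_lt(abs(mean(ld)), 3 * sd(ld) / sqrt(length(ld)))
})
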