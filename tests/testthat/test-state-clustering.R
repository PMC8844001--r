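# Cityblock k-means state detection and centroid matching, checked against
# exhaustive-enumeration oracles.

l1_cost <- function(x, labels) {
  # within-cluster cityblock cost under the optimal (median) centroids
  sum(vapply(unique(labels), function(j) {
    xs <- x[labels == j, , drop = FALSE]
    med <- apply(xs, 2, median)
    sum(abs(sweep(xs, 2, med)))
  }, numeric(1)))
}

test_that("k = 1 recovers the component-wise median", {
  set.seed(20)
  x <- matrix(rnorm(40), 10, 4)
  m <- fit_states(x, k = 1, n_restarts = 2, seed = 1)
  expect_equal(as.numeric(m$centroids), apply(x, 2, median))
  expect_true(all(m$labels == 1L))
})

test_that("two-cloud partition matches the exhaustive L1-optimal partition", {
  set.seed(21)
  x <- rbind(matrix(rnorm(6, 0, 0.3), 3, 2),
             matrix(rnorm(6, 5, 0.3), 3, 2))
  m <- fit_states(x, k = 2, n_restarts = 5, seed = 2)
  # brute force over all 2-partitions of 6 points (both clusters nonempty)
  best <- Inf
  best_lab <- NULL
  for (code in 1:(2^6 - 2)) {
    lab <- as.integer(intToBits(code)[1:6]) + 1L
    if (length(unique(lab)) < 2) next
    cost <- l1_cost(x, lab)
    if (cost < best) { best <- cost; best_lab <- lab }
  }
  expect_equal(m$inertia, best, tolerance = 1e-10)
  agree <- max(mean(m$labels == best_lab), mean(m$labels == 3L - best_lab))
  expect_equal(agree, 1)
})

test_that("duplicating every vector doubles inertia and keeps centroids", {
  set.seed(22)
  x <- rbind(matrix(rnorm(20, 0, 0.5), 10, 2),
             matrix(rnorm(20, 4, 0.5), 10, 2))
  m1 <- fit_states(x, k = 2, n_restarts = 5, seed = 3)
  m2 <- fit_states(rbind(x, x), k = 2, n_restarts = 5, seed = 3)
  ord1 <- order(m1$centroids[, 1])
  ord2 <- order(m2$centroids[, 1])
  expect_equal(m1$centroids[ord1, ], m2$centroids[ord2, ], tolerance = 1e-12)
  expect_equal(2 * m1$inertia, m2$inertia, tolerance = 1e-10)
})

test_that("fitting is deterministic under a fixed seed", {
  set.seed(23)
  x <- matrix(rnorm(200), 50, 4)
  a <- fit_states(x, k = 3, n_restarts = 4, seed = 9)
  b <- fit_states(x, k = 3, n_restarts = 4, seed = 9)
  expect_identical(a$labels, b$labels)
  expect_identical(a$centroids, b$centroids)
  expect_error(fit_states(x[1:2, ], k = 3), class = "dfc_invalid_argument")
})

test_that("label assignment matches brute-force nearest search with tie-break", {
  set.seed(24)
  cent <- matrix(rnorm(15), 3, 5)
  x <- matrix(rnorm(100), 20, 5)
  lab <- assign_labels(x, cent)
  brute <- apply(x, 1, function(v) {
    which.min(colSums(abs(t(cent) - v)))
  })
  expect_identical(lab, as.integer(brute))

  expect_identical(assign_labels(cent[3, , drop = FALSE], cent), 3L)
  # exact tie between centroids 1 and 2 -> lowest index
  tie_cent <- rbind(c(0, 0), c(2, 2), c(9, 9))
  expect_identical(assign_labels(matrix(c(1, 1), 1), tie_cent), 1L)
  expect_error(assign_labels(matrix(0, 1, 3), cent),
               class = "dfc_invalid_argument")
})

test_that("labels are permutation-equivariant in centroid order", {
  set.seed(25)
  cent <- matrix(rnorm(20), 4, 5)
  x <- matrix(rnorm(150), 30, 5)
  perm <- c(3L, 1L, 4L, 2L)       # row r of new = row perm[r] of old
  lab_old <- assign_labels(x, cent)
  lab_new <- assign_labels(x, cent[perm, ])
  expect_identical(perm[lab_new], lab_old)
})

test_that("centroid matching recovers permutations and reports ambiguity", {
  set.seed(26)
  a <- matrix(rnorm(5 * 40), 5, 40)
  perm <- sample(5)
  b <- a[perm, ]
  mm <- match_centroids(a, b)
  expect_identical(mm$mapping$b[order(mm$mapping$a)], order(perm))
  expect_equal(mm$mapping$rho, rep(1, 5), tolerance = 1e-12)
  expect_length(mm$unmatched$a, 0)

  # small noise keeps the mapping, rho stays high; verify optimality against
  # exhaustive assignment on total rho
  bn <- b + matrix(rnorm(200, sd = 0.05), 5, 40)
  mm2 <- match_centroids(a, bn)
  expect_identical(mm2$mapping$b[order(mm2$mapping$a)], order(perm))
  expect_true(all(mm2$mapping$rho > 0.9))
  rho <- mm2$rho_matrix
  perms <- dfcstates:::injective_maps(5, 5)
  totals <- apply(perms, 1, function(mp) sum(rho[cbind(1:5, mp)]))
  expect_equal(sum(mm2$mapping$rho), max(totals), tolerance = 1e-12)

  mm3 <- match_centroids(a[1:2, ], a[c(2, 1, 3), ] + 0.01 * matrix(rnorm(120), 3, 40))
  expect_identical(nrow(mm3$mapping), 2L)
  expect_identical(mm3$unmatched$b, 3L)
})

test_that("a constant centroid yields a missing rho, flagged unmatched", {
  a <- rbind(rep(1, 10), rnorm(10))
  b <- rbind(rnorm(10), rnorm(10))
  expect_warning(mm <- match_centroids(a, b), "undefined")
  expect_true(any(is.na(mm$mapping$rho)))
  expect_true(1L %in% mm$unmatched$a)
})

test_that("clustering recovers well-separated generating states", {
  # vectors drawn around 5 separated centroids: >= 95% label agreement
  set.seed(27)
  cent <- matrix(rnorm(5 * 20, sd = 2), 5, 20)
  truth <- sample(1:5, 2000, replace = TRUE)
  x <- cent[truth, ] + matrix(rnorm(2000 * 20, sd = 0.5), 2000, 20)
  m <- fit_states(x, k = 5, n_restarts = 5, seed = 4)
  al <- align_labels(m$labels, truth, 5)
  expect_gte(al$agreement, 0.95)
})
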