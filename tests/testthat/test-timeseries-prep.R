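# Motion QC: framewise displacement, DVARS, marking, interpolation,
# frame discarding, run exclusion.

test_that("framewise displacement matches hand-computed values", {
  mp <- matrix(0, 6, 6)
  expect_equal(framewise_displacement(mp), rep(0, 6))

  mp_step <- matrix(0, 6, 6)
  mp_step[3:6, 1] <- 0.1  # +0.1 mm translation step at volume 3
  fd <- framewise_displacement(mp_step, sphere_radius_mm = 50)
  expect_equal(fd, c(0, 0, 0.1, 0, 0, 0))

  mp_rot <- matrix(0, 4, 6)
  mp_rot[3:4, 5] <- 0.002  # 0.002 rad step -> arc 0.002 * 50 = 0.1 mm
  fd_rot <- framewise_displacement(mp_rot, sphere_radius_mm = 50)
  expect_equal(fd_rot, c(0, 0, 0.1, 0))

  expect_error(framewise_displacement(matrix(0, 5, 5)),
               class = "dfc_invalid_argument")
})

test_that("framewise displacement is invariant to constant offsets", {
  set.seed(1)
  mp <- matrix(rnorm(60, sd = 0.05), 10, 6)
  shifted <- sweep(mp, 2, c(3, -2, 1, 0.1, -0.1, 0.2), "+")
  expect_equal(framewise_displacement(mp), framewise_displacement(shifted))
})

test_that("DVARS matches the hand RMS oracle and is scale invariant", {
  const <- make_ts(matrix(7, 10, 3))
  expect_equal(dvars_series(const), rep(0, 10))

  # two ROIs, uniform +1 step, run global mean exactly 100 -> 1% at the step
  v <- matrix(c(99.5, 99.5, 100.5, 100.5), 4, 2)
  ts <- make_ts(v)
  expect_equal(mean(ts$values), 100)
  expect_equal(dvars_series(ts), c(0, 0, 1, 0))

  ts2 <- make_ts(2 * v)
  expect_equal(dvars_series(ts2), dvars_series(ts))

  zero_mean <- make_ts(matrix(c(-1, 1, -1, 1), 4, 2))
  expect_error(dvars_series(zero_mean), class = "dfc_degenerate_input")
})

test_that("high-motion marking extends one back and two forward", {
  expect_equal(mark_high_motion(rep(0, 6), rep(0, 6)), rep(FALSE, 6))

  fd <- c(0, 0, 0.3, 0, 0, 0)
  mask <- mark_high_motion(fd, rep(0, 6))
  expect_identical(which(mask), 2:5)

  mask_first <- mark_high_motion(c(0.5, 0, 0, 0, 0), rep(0, 5))
  expect_identical(which(mask_first), 1:3)

  # boundary values are NOT marked (strict inequality)
  expect_false(any(mark_high_motion(c(0, 0.2, 0), c(0, 5, 0))))
  expect_error(mark_high_motion(c(0, 1), c(0, 1), fd_threshold = -1),
               class = "dfc_invalid_argument")
})

test_that("marking is monotone in both thresholds", {
  set.seed(2)
  fd <- abs(rnorm(50, 0.1, 0.1))
  dv <- abs(rnorm(50, 2, 2))
  base <- mark_high_motion(fd, dv)
  lower_fd <- mark_high_motion(fd, dv, fd_threshold = 0.1)
  lower_dv <- mark_high_motion(fd, dv, dvars_threshold = 2.5)
  expect_true(all(base <= lower_fd))
  expect_true(all(base <= lower_dv))
})

test_that("interpolation repairs marked volumes from unmarked neighbours", {
  ts <- make_ts(matrix(c(0, 99, 2), 3, 1))
  out <- interpolate_marked(ts, c(FALSE, TRUE, FALSE))
  expect_equal(out$values[, 1], c(0, 1, 2))

  # empty mask: identity
  expect_identical(interpolate_marked(ts, rep(FALSE, 3))$values, ts$values)

  # multi-ROI 3-frame marked block: per-ROI linear between flanking values
  set.seed(3)
  v <- matrix(rnorm(21), 7, 3)
  mask <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE)
  out2 <- interpolate_marked(make_ts(v), mask)
  for (j in 1:3) {
    expected <- v[2, j] + (v[6, j] - v[2, j]) * (1:3) / 4
    expect_equal(out2$values[3:5, j], expected)
  }
  # unmarked volumes bit-identical
  expect_identical(unname(out2$values[!mask, ]), v[!mask, ])
  # leading marked volumes take nearest unmarked value
  out3 <- interpolate_marked(make_ts(v), c(TRUE, TRUE, rep(FALSE, 5)))
  expect_equal(unname(out3$values[1, ]), v[3, ])
  expect_equal(unname(out3$values[2, ]), v[3, ])
  expect_error(interpolate_marked(ts, rep(TRUE, 3)),
               class = "dfc_degenerate_input")
})

test_that("interpolation is idempotent for a fixed mask", {
  set.seed(4)
  v <- matrix(rnorm(40), 10, 4)
  mask <- rep(c(FALSE, TRUE, FALSE, FALSE, FALSE), 2)
  once <- interpolate_marked(make_ts(v), mask)
  twice <- interpolate_marked(once, mask)
  expect_identical(once$values, twice$values)
})

test_that("initial-frame discarding preserves order and validates bounds", {
  set.seed(5)
  ts <- make_ts(matrix(rnorm(300 * 3), 300, 3))
  out <- discard_initial_frames(ts, 4)
  expect_identical(nrow(out$values), 296L)
  expect_identical(out$values, ts$values[5:300, ])
  expect_identical(discard_initial_frames(ts, 0)$values, ts$values)

  small <- make_ts(matrix(1:10, 5, 2))
  expect_identical(nrow(discard_initial_frames(small, 4)$values), 1L)
  expect_error(discard_initial_frames(small, 5), class = "dfc_invalid_argument")
})

test_that("run exclusion triggers strictly above half the volumes", {
  expect_true(qc_exclusion(rep(FALSE, 296))$pass)
  expect_equal(qc_exclusion(rep(FALSE, 296))$fraction_marked, 0)

  m149 <- c(rep(TRUE, 149), rep(FALSE, 147))
  res <- qc_exclusion(m149)
  expect_false(res$pass)
  expect_equal(res$fraction_marked, 149 / 296)

  m148 <- c(rep(TRUE, 148), rep(FALSE, 148))
  expect_true(qc_exclusion(m148)$pass)  # exactly 50% is retained
})

test_that("prepare_run chains discard, FD/DVARS, marking and interpolation", {
  cs <- generate_centroids(k = 1, n_roi = 5, seed = 2)
  sq <- generate_state_sequence(60, 1.0, seed = 2)
  ts <- generate_bold_run(sq, cs, seed = 2)
  mp <- matrix(0, 60, 6)
  mp[30:60, 2] <- 0.4  # one big translation step at volume 30
  pr <- prepare_run(ts, mp, discard_frames = 4)
  expect_identical(nrow(pr$ts$values), 56L)
  expect_identical(which(pr$mask), 25:28)  # volume 30 - 4 discarded = 26, +/- rule
  expect_true(pr$pass)
  expect_false(any(is.na(pr$ts$values)))
})
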