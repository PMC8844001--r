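# Shared fixtures, built in code at test time.

make_ts <- function(values, tr = 2, ...) {
  roi_timeseries(as.matrix(values), tr_seconds = tr, ...)
}

random_symmetric <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

# Naive triple-loop MTD reference: independent oracle for the vectorised
# implementation (small inputs only).
mtd_reference <- function(values, w) {
  t_n <- nrow(values)
  p <- ncol(values)
  dx <- matrix(0, t_n - 1, p)
  for (t in seq_len(t_n - 1)) {
    for (i in seq_len(p)) dx[t, i] <- values[t + 1, i] - values[t, i]
  }
  sigma <- numeric(p)
  for (i in seq_len(p)) {
    mu <- mean(dx[, i])
    sigma[i] <- sqrt(sum((dx[, i] - mu)^2) / (t_n - 1))
  }
  raw <- array(0, dim = c(t_n - 1, p, p))
  for (t in seq_len(t_n - 1)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        raw[t, i, j] <- dx[t, i] * dx[t, j] / (sigma[i] * sigma[j])
      }
    }
  }
  n_win <- (t_n - 1) - w
  sm <- array(0, dim = c(n_win, p, p))
  for (win in seq_len(n_win)) {
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        sm[win, i, j] <- mean(raw[(win + 1):(win + w), i, j])
      }
    }
  }
  list(dx = dx, sigma = sigma, raw = raw, smoothed = sm)
}

# Heavy shared fixture for the recovery checks: a bold cohort with >= 20,000
# windows pushed through motion-free MTD + clustering. Cached so the
# clustering- and occupancy-recovery tests share one computation.
.acc_env <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (!is.null(.acc_env$fix)) return(.acc_env$fix)
  spec <- cohort_spec(n_subjects = 23, n_roi = 30, seed = 11)
  coh <- generate_cohort(spec, include_bold = TRUE)
  vecs <- list()
  truth <- list()
  for (sid in names(coh$runs)) {
    for (run in names(coh$runs[[sid]])) {
      cw <- mtd_windows(coh$runs[[sid]][[run]], 7)
      vecs[[paste(sid, run)]] <- coupling_vectors(cw)
      truth[[paste(sid, run)]] <- coh$ground_truth$window_labels[[sid]][[run]]
    }
  }
  x <- do.call(rbind, vecs)
  model <- fit_states(x, k = 5, n_restarts = 10, seed = 7)
  aligned <- align_labels(model$labels, unlist(truth), 5)
  .acc_env$fix <- list(cohort = coh, x = x, truth = truth, model = model,
                       aligned = aligned)
  .acc_env$fix
}
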