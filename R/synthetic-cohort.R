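# Synthetic cohorts with the statistical structure the analysis assumes:
# covariance-switching BOLD whose window-level connectivity alternates among
# k centroid patterns, a pre-to-post occupancy shift in one state, and
# subject-level coupling of that shift with trait mindfulness and cortisol
# output. Every generator is a pure function of its seed.

#' Construct a centroid set from explicit matrices
#'
#' Validates and bundles user-supplied connectivity-state matrices (each
#' symmetric with unit diagonal and off-diagonal couplings in [-1, 1]).
#'
#' @param matrices list of symmetric n_roi x n_roi matrices.
#' @param names optional state labels.
#' @return object of class `centroid_set`.
#' @export
centroid_set <- function(matrices, names = NULL) {
  if (!is.list(matrices) || !length(matrices)) {
    stop_invalid("matrices must be a nonempty list")
  }
  k <- length(matrices)
  n_roi <- nrow(matrices[[1]])
  if (is.null(names)) names <- sprintf("state_%d", seq_len(k))
  if (length(names) != k) stop_invalid("need ", k, " state names")
  for (i in seq_len(k)) {
    m <- as.matrix(matrices[[i]])
    if (nrow(m) != n_roi || ncol(m) != n_roi) stop_invalid("matrices must share one square dimension")
    if (max(abs(m - t(m))) > 1e-8) stop_invalid("matrix ", i, " is not symmetric")
    if (max(abs(diag(m) - 1)) > 1e-8) stop_invalid("matrix ", i, " must have unit diagonal")
    if (max(abs(m[lower.tri(m)])) > 1 + 1e-12) {
      stop_invalid("matrix ", i, " has couplings outside [-1, 1]")
    }
    matrices[[i]] <- m
  }
  structure(list(k = k, n_roi = n_roi, matrices = matrices,
                 names = as.character(names)),
            class = "centroid_set")
}

#' Generate a set of distinct connectivity-state centroids
#'
#' Each state is a correlation matrix built from a low-rank factor model:
#' ROIs are randomly assigned to modules with signed loadings, giving
#' block-structured positive and negative couplings (the qualitative
#' signature of empirical connectivity states), plus a dense low-amplitude
#' background factor pair so that every ROI pair carries a small distinct
#' coupling (empirical coupling matrices have no exact zeros). Diagonal is
#' unit. The construction is positive semidefinite by design; a nearest-PSD
#' repair (Matrix::nearPD) is applied only if numerical checks fail. States
#' are redrawn until all pairwise Spearman correlations of their
#' off-diagonal couplings are below 0.95 (pairwise distinct).
#'
#' @param k number of states (>= 1).
#' @param n_roi number of regions (>= 4).
#' @param seed integer seed; same seed, same centroids.
#' @param n_factors modules per state (default 3).
#' @param strength_range range of absolute factor loadings (default
#'   c(0.55, 0.85), giving within-module couplings of roughly +/- 0.3-0.7).
#' @param names optional state labels.
#' @return object of class `centroid_set`: list with `k`, `n_roi`,
#'   `matrices` (list of k symmetric n_roi x n_roi matrices, unit diagonal),
#'   `names`.
#' @export
generate_centroids <- function(k, n_roi, seed = 1L, n_factors = 3L,
                               strength_range = c(0.55, 0.85), names = NULL) {
  k <- assert_count(k, "k", min = 1L)
  n_roi <- assert_count(n_roi, "n_roi", min = 4L)
  n_factors <- assert_count(n_factors, "n_factors", min = 1L)
  if (is.null(names)) names <- sprintf("state_%d", seq_len(k))
  if (length(names) != k) stop_invalid("need ", k, " state names")
  mats <- with_seed(seed, {
    one_state <- function() {
      module <- sample.int(n_factors, n_roi, replace = TRUE)
      amp <- stats::runif(n_roi, strength_range[1], strength_range[2])
      sgn <- sample(c(-1, 1), n_roi, replace = TRUE)
      load <- matrix(0, n_roi, n_factors)
      load[cbind(seq_len(n_roi), module)] <- amp * sgn
      # dense background: two extra factors with small signed loadings give
      # every pair a distinct nonzero coupling of magnitude ~0.01-0.1
      bg <- matrix(stats::runif(n_roi * 2, 0.1, 0.3) *
                     sample(c(-1, 1), n_roi * 2, replace = TRUE),
                   n_roi, 2)
      m <- tcrossprod(cbind(load, bg))
      diag(m) <- 1
      m
    }
    for (attempt in seq_len(20L)) {
      out <- replicate(k, one_state(), simplify = FALSE)
      if (k == 1L || centroids_distinct(out)) break
    }
    out
  })
  for (i in seq_len(k)) {
    ev <- eigen(mats[[i]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      if (!requireNamespace("Matrix", quietly = TRUE)) {
        stop("centroid not PSD and Matrix not available for repair")
      }
      mats[[i]] <- as.matrix(Matrix::nearPD(mats[[i]], corr = TRUE)$mat)
    }
  }
  structure(list(k = k, n_roi = n_roi, matrices = mats, names = names),
            class = "centroid_set")
}

centroids_distinct <- function(mats, limit = 0.95) {
  k <- length(mats)
  if (k < 2L) return(TRUE)
  vecs <- lapply(mats, function(m) m[lower.tri(m)])
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      rho <- spearman_rho(vecs[[i]], vecs[[j]])
      if (!is.na(rho) && rho >= limit) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.centroid_set <- function(x, ...) {
  cat(sprintf("<centroid_set> %d states x %d ROIs (%s)\n",
              x$k, x$n_roi, paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Generate a blockwise state sequence
#'
#' States persist over multi-sample blocks with geometric dwell lengths
#' (mean `mean_dwell` samples); block states are drawn with probability
#' proportional to the target occupancy. In `exact` mode the per-state
#' sample counts are fixed in advance by largest-remainder apportionment of
#' `target_occupancy * n`, so the empirical occupancy matches the target
#' exactly (up to the integer grid) — a noiseless occupancy readout for
#' effect-recovery designs.
#'
#' @param n sequence length (windows or volumes).
#' @param target_occupancy per-state fractions summing to 1.
#' @param mean_dwell mean block length in samples (>= 1).
#' @param seed integer seed.
#' @param exact force empirical occupancy to equal the target (default
#'   FALSE).
#' @return object of class `state_sequence`: `labels` (integer vector in
#'   1..k), `dwell_lengths`, `target_occupancy`.
#' @export
generate_state_sequence <- function(n, target_occupancy, mean_dwell = 10,
                                    seed = 1L, exact = FALSE) {
  n <- assert_count(n, "n", min = 1L)
  target_occupancy <- as.numeric(target_occupancy)
  if (any(target_occupancy < 0)) stop_invalid("occupancies must be non-negative")
  if (abs(sum(target_occupancy) - 1) > 1e-9) {
    stop_invalid("target_occupancy must sum to 1 (got ", sum(target_occupancy), ")")
  }
  assert_scalar(mean_dwell, "mean_dwell", lower = 1)
  k <- length(target_occupancy)
  labels <- with_seed(seed, {
    if (exact) {
      quota <- floor(target_occupancy * n)
      rem <- n - sum(quota)
      if (rem > 0) {
        frac <- target_occupancy * n - quota
        give <- order(frac, seq_len(k), decreasing = c(TRUE, FALSE), method = "radix")[seq_len(rem)]
        quota[give] <- quota[give] + 1L
      }
      out <- integer(0)
      while (sum(quota) > 0) {
        s <- sample.int(k, 1L, prob = quota)
        dwell <- 1L + stats::rgeom(1L, prob = 1 / mean_dwell)
        dwell <- min(dwell, quota[s])
        out <- c(out, rep.int(s, dwell))
        quota[s] <- quota[s] - dwell
      }
      out
    } else {
      out <- integer(0)
      while (length(out) < n) {
        s <- sample.int(k, 1L, prob = target_occupancy)
        dwell <- 1L + stats::rgeom(1L, prob = 1 / mean_dwell)
        out <- c(out, rep.int(s, dwell))
      }
      out[seq_len(n)]
    }
  })
  structure(list(labels = labels, dwell_lengths = rle(labels)$lengths,
                 target_occupancy = target_occupancy),
            class = "state_sequence")
}

#' Generate one run of covariance-switching BOLD
#'
#' Each volume is drawn from a zero-mean multivariate normal whose
#' correlation matrix is the active state's centroid, plus independent
#' Gaussian sensor noise of standard deviation `noise_sd`. Samples are
#' i.i.d. within a state (no autocorrelation model), which keeps windowed
#' coupling recovery interpretable.
#'
#' @param sequence a [generate_state_sequence()] result; one label per
#'   volume.
#' @param centroids a [generate_centroids()] result covering all states in
#'   the sequence.
#' @param noise_sd independent noise sd (> 0).
#' @param seed integer seed.
#' @param tr_seconds sampling interval (default 2).
#' @param baseline constant signal offset added to every ROI (default 1000,
#'   the order of magnitude of scanner BOLD units); differencing removes it
#'   from coupling, but percent-normalised DVARS needs a realistic positive
#'   global mean.
#' @param subject_id,run_id identifiers for the output container.
#' @return a [roi_timeseries()] of dim length(sequence) x n_roi.
#' @export
generate_bold_run <- function(sequence, centroids, noise_sd = 0.1, seed = 1L,
                              tr_seconds = 2, baseline = 1000,
                              subject_id = NA_character_,
                              run_id = NA_character_) {
  stopifnot(inherits(sequence, "state_sequence"),
            inherits(centroids, "centroid_set"))
  assert_scalar(noise_sd, "noise_sd", lower = 1e-12)
  labels <- sequence$labels
  if (max(labels) > centroids$k) {
    stop_invalid("sequence uses state ", max(labels), " but only ",
                 centroids$k, " centroids provided")
  }
  chols <- lapply(centroids$matrices, function(m) {
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop_invalid("centroid is not positive semidefinite")
    chol(m + diag(1e-10, nrow(m)))
  })
  t_n <- length(labels)
  p <- centroids$n_roi
  values <- with_seed(seed, {
    z <- matrix(stats::rnorm(t_n * p), t_n, p)
    eps <- matrix(stats::rnorm(t_n * p, sd = noise_sd), t_n, p)
    out <- matrix(0, t_n, p)
    for (s in unique(labels)) {
      idx <- which(labels == s)
      out[idx, ] <- z[idx, , drop = FALSE] %*% chols[[s]]
    }
    out + eps + baseline
  })
  roi_timeseries(values, tr_seconds = tr_seconds,
                 subject_id = subject_id, run_id = run_id)
}

#' Generate a rigid-body motion trace with occasional spikes
#'
#' Six realignment parameters (3 translations mm, 3 rotations rad) evolve as
#' independent random walks with small steps, producing framewise
#' displacement around the 0.05 mm typical of compliant subjects; at rate
#' `spike_rate` per volume a translation jump of `spike_mm` is injected,
#' producing an FD spike that the marking rule should catch.
#'
#' @param volumes number of volumes.
#' @param spike_rate per-volume spike probability (default 0.02).
#' @param seed integer seed.
#' @param step_sd random-walk step sd (mm or rad; default 0.008).
#' @param spike_mm spike displacement in mm (default 0.35).
#' @return volumes x 6 numeric matrix.
#' @export
generate_motion_params <- function(volumes, spike_rate = 0.02, seed = 1L,
                                   step_sd = 0.008, spike_mm = 0.35) {
  volumes <- assert_count(volumes, "volumes", min = 1L)
  assert_scalar(spike_rate, "spike_rate", lower = 0, upper = 1)
  with_seed(seed, {
    steps <- matrix(stats::rnorm(volumes * 6, sd = step_sd), volumes, 6)
    steps[, 4:6] <- steps[, 4:6] / 50  # rotations scaled to comparable arc
    steps[1, ] <- 0
    spikes <- which(stats::runif(volumes) < spike_rate)
    spikes <- spikes[spikes > 1L]
    if (length(spikes)) {
      axis <- sample.int(3L, length(spikes), replace = TRUE)
      steps[cbind(spikes, axis)] <- steps[cbind(spikes, axis)] +
        spike_mm * sample(c(-1, 1), length(spikes), replace = TRUE)
    }
    apply(steps, 2, cumsum)
  })
}

#' Generate a salivary cortisol series
#'
#' Concentration follows a rise-and-decay response: flat at `baseline`
#' before stress onset, linear rise to `baseline + peak_delta` at
#' `peak_minute`, then exponential decay back toward baseline with time
#' constant `decay_minutes`; multiplicative log-normal noise is applied per
#' sample. Only the AUC functionals of this curve matter downstream; the
#' shape is a conventional stress-response template.
#'
#' @param baseline pre-stress concentration (ug/dL, > 0).
#' @param peak_delta peak rise above baseline (>= 0).
#' @param timepoints sampling minutes relative to stress onset (strictly
#'   increasing; default c(-30, 0, 20, 60, 90)).
#' @param noise_sd sd of the log-normal sample noise (default 0.05).
#' @param seed integer seed.
#' @param peak_minute time of peak (default 20).
#' @param decay_minutes decay time constant (default 45).
#' @param subject_id identifier.
#' @return a [cortisol_series()] on the raw scale.
#' @export
generate_cortisol_series <- function(baseline, peak_delta,
                                     timepoints = c(-30, 0, 20, 60, 90),
                                     noise_sd = 0.05, seed = 1L,
                                     peak_minute = 20, decay_minutes = 45,
                                     subject_id = NA_character_) {
  assert_scalar(baseline, "baseline", lower = 1e-12)
  assert_scalar(peak_delta, "peak_delta", lower = 0)
  assert_scalar(noise_sd, "noise_sd", lower = 0)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 1L || any(diff(timepoints) <= 0)) {
    stop_invalid("timepoints must be strictly increasing")
  }
  shape <- cortisol_shape(timepoints, peak_minute, decay_minutes)
  conc <- with_seed(seed, {
    (baseline + peak_delta * shape) * exp(stats::rnorm(length(timepoints), sd = noise_sd))
  })
  cortisol_series(timepoints, conc, subject_id = subject_id)
}

cortisol_shape <- function(t, peak_minute, decay_minutes) {
  s <- numeric(length(t))
  rising <- t > 0 & t <= peak_minute
  s[rising] <- t[rising] / peak_minute
  late <- t > peak_minute
  s[late] <- exp(-(t[late] - peak_minute) / decay_minutes)
  s
}

#' Cohort-generation settings
#'
#' Defaults emulate the study design the package targets: 40 subjects, three
#' 300-volume resting runs at TR 2 s (RS1 pre-stress, RS2/RS3 post-stress),
#' 114 ROIs, five connectivity states of which the task-ready state (TRS)
#' loses occupancy after stress, subject-level coupling of that drop with
#' trait mindfulness (r = 0.32) and total cortisol output (r = -0.33), and
#' occasional motion spikes.
#'
#' @param n_subjects number of subjects (default 40).
#' @param runs_per_subject resting runs per subject (default 3).
#' @param volumes_per_run volumes per run (default 300).
#' @param tr_seconds repetition time (default 2).
#' @param n_roi regions (default 114).
#' @param k states (default 5).
#' @param state_names state labels; first three are the named TRS/HAS/LAS.
#' @param occupancy_pre,occupancy_post per-state target occupancy before and
#'   after stress (each sums to 1).
#' @param designated_state state whose occupancy change carries the
#'   subject-level effects (default "TRS").
#' @param r_trait correlation of the designated state's occupancy change
#'   with the trait score, in (-1, 1).
#' @param r_cortisol correlation with cortisol output, in (-1, 1).
#' @param run_sd per-run, per-state sd of subject-level occupancy
#'   perturbations (default 0.057, giving sd(delta) ~ 0.08 across runs).
#' @param noise_sd BOLD sensor-noise sd (default 0.1).
#' @param mean_dwell mean state dwell in samples (default 60).
#' @param spike_rate motion-spike probability per volume (default 0.02).
#' @param window MTD smoothing window in TRs (default 7); sets the readout
#'   sequence length volumes - 1 - window.
#' @param exact_occupancy use exact-quota sequences (default TRUE) so the
#'   realised occupancy equals each subject's target.
#' @param ffmq_mean,ffmq_sd trait-score population moments (defaults 130, 15
#'   on the 39-195 full-scale range).
#' @param cortisol_baseline,cortisol_peak_mean,cortisol_noise_sd cortisol
#'   curve parameters (ug/dL; defaults 0.15, 0.20, 0.05).
#' @param seed master seed.
#' @return object of class `cohort_spec` (validated list).
#' @export
cohort_spec <- function(n_subjects = 40L, runs_per_subject = 3L,
                        volumes_per_run = 300L, tr_seconds = 2,
                        n_roi = 114L, k = 5L,
                        state_names = c("TRS", "HAS", "LAS", "S4", "S5"),
                        occupancy_pre = c(0.30, 0.16, 0.18, 0.18, 0.18),
                        occupancy_post = c(0.24, 0.18, 0.20, 0.19, 0.19),
                        designated_state = "TRS",
                        r_trait = 0.32, r_cortisol = -0.33,
                        run_sd = 0.057, noise_sd = 0.1, mean_dwell = 60,
                        spike_rate = 0.02, window = 7L,
                        exact_occupancy = TRUE,
                        ffmq_mean = 130, ffmq_sd = 15,
                        cortisol_baseline = 0.15, cortisol_peak_mean = 0.20,
                        cortisol_noise_sd = 0.05,
                        seed = 1L) {
  spec <- list(
    n_subjects = assert_count(n_subjects, "n_subjects"),
    runs_per_subject = assert_count(runs_per_subject, "runs_per_subject"),
    volumes_per_run = assert_count(volumes_per_run, "volumes_per_run", min = 10L),
    tr_seconds = assert_scalar(tr_seconds, "tr_seconds", lower = 1e-9),
    n_roi = assert_count(n_roi, "n_roi", min = 4L),
    k = assert_count(k, "k", min = 2L),
    state_names = as.character(state_names),
    occupancy_pre = as.numeric(occupancy_pre),
    occupancy_post = as.numeric(occupancy_post),
    designated_state = as.character(designated_state),
    r_trait = assert_scalar(r_trait, "r_trait", lower = -1, upper = 1),
    r_cortisol = assert_scalar(r_cortisol, "r_cortisol", lower = -1, upper = 1),
    run_sd = assert_scalar(run_sd, "run_sd", lower = 0),
    noise_sd = assert_scalar(noise_sd, "noise_sd", lower = 1e-12),
    mean_dwell = assert_scalar(mean_dwell, "mean_dwell", lower = 1),
    spike_rate = assert_scalar(spike_rate, "spike_rate", lower = 0, upper = 1),
    window = assert_count(window, "window"),
    exact_occupancy = isTRUE(exact_occupancy),
    ffmq_mean = assert_scalar(ffmq_mean, "ffmq_mean", lower = 39, upper = 195),
    ffmq_sd = assert_scalar(ffmq_sd, "ffmq_sd", lower = 0),
    cortisol_baseline = assert_scalar(cortisol_baseline, "cortisol_baseline", lower = 1e-9),
    cortisol_peak_mean = assert_scalar(cortisol_peak_mean, "cortisol_peak_mean", lower = 0),
    cortisol_noise_sd = assert_scalar(cortisol_noise_sd, "cortisol_noise_sd", lower = 0),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (length(spec$state_names) != spec$k) stop_invalid("need k state names")
  if (length(spec$occupancy_pre) != spec$k || length(spec$occupancy_post) != spec$k) {
    stop_invalid("occupancy_pre/occupancy_post must have k entries")
  }
  if (abs(sum(spec$occupancy_pre) - 1) > 1e-9 ||
      abs(sum(spec$occupancy_post) - 1) > 1e-9) {
    stop_invalid("occupancies must sum to 1 per run")
  }
  if (abs(spec$r_trait) >= 1 || abs(spec$r_cortisol) >= 1) {
    stop_invalid("effect-size correlations must lie strictly inside (-1, 1)")
  }
  if (!spec$designated_state %in% spec$state_names) {
    stop_invalid("designated_state must be one of the state names")
  }
  if (spec$window >= spec$volumes_per_run - 1L) {
    stop_invalid("window must be smaller than volumes_per_run - 1")
  }
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects x %d runs x %d volumes, %d ROIs, k = %d (seed %d)\n",
              x$n_subjects, x$runs_per_subject, x$volumes_per_run, x$n_roi,
              x$k, x$seed))
  invisible(x)
}

clip_simplex <- function(p, lo = 0.02, hi = 0.95) {
  p <- pmin(pmax(p, lo), hi)
  p / sum(p)
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject, per-run occupancy targets (group-level pre/post shift
#' plus subject-level perturbations renormalised onto the simplex), derives
#' each subject's latent occupancy change in the designated state, and
#' generates trait scores and cortisol responses with the specified
#' correlations to that latent change. State sequences realise the targets
#' (exactly, in the default quota mode); with `include_bold = TRUE` each run
#' additionally gets covariance-switching BOLD and a motion trace, and
#' ground-truth window labels are derived from the per-volume sequence by
#' majority over each window's span.
#'
#' @param spec a [cohort_spec()].
#' @param include_bold also generate ROI BOLD and motion traces (default
#'   FALSE; occupancy-readout mode generates window-level sequences only).
#' @return object of class `dfc_cohort`: `subjects` (data.frame: subject,
#'   ffmq_total, stress_change, alertness_change, aucg, auci, qc_pass),
#'   `cortisol` (long data.frame), `occupancy` (realised ground-truth
#'   occupancy table), `runs` / `motion` (named lists, bold mode only),
#'   `ground_truth` (latent deltas, occupancy targets, window labels,
#'   sequences), `centroids`, `spec`.
#' @export
generate_cohort <- function(spec, include_bold = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  k <- spec$k
  runs <- paste0("RS", seq_len(spec$runs_per_subject))
  s0 <- match(spec$designated_state, spec$state_names)
  seeds <- derive_seeds(spec$seed, 10L + n * (4L * spec$runs_per_subject + 4L))
  next_seed <- local({i <- 0L; function() {i <<- i + 1L; seeds[i]}})

  centroids <- generate_centroids(k, spec$n_roi, seed = next_seed(),
                                  names = spec$state_names)

  # per-subject, per-run occupancy targets
  targets <- array(0, dim = c(n, spec$runs_per_subject, k))
  for (i in seq_len(n)) {
    for (r in seq_len(spec$runs_per_subject)) {
      base <- if (r == 1L) spec$occupancy_pre else spec$occupancy_post
      eps <- with_seed(next_seed(), stats::rnorm(k, sd = spec$run_sd))
      targets[i, r, ] <- clip_simplex(base + eps)
    }
  }
  latent_delta <- targets[, 2L, s0] - targets[, 1L, s0]
  sd_ld <- stats::sd(latent_delta)
  ld_std <- if (is.na(sd_ld) || sd_ld < 1e-12) rep(0, n) else
    (latent_delta - mean(latent_delta)) / sd_ld

  mix <- function(r, z, seed) {
    noise <- with_seed(seed, stats::rnorm(n))
    r * z + sqrt(1 - r^2) * noise
  }
  trait_latent <- mix(spec$r_trait, ld_std, next_seed())
  ffmq_total <- pmin(195, pmax(39, round(spec$ffmq_mean + spec$ffmq_sd * trait_latent)))
  cort_latent <- mix(spec$r_cortisol, ld_std, next_seed())
  peak_delta <- spec$cortisol_peak_mean * exp(0.4 * cort_latent)
  ratings <- with_seed(next_seed(), {
    data.frame(stress_change = round(stats::rnorm(n, 2, 1.2)),
               alertness_change = round(stats::rnorm(n, 0, 1.2)))
  })

  subj_ids <- sprintf("sub%03d", seq_len(n))
  n_windows <- spec$volumes_per_run - 1L - spec$window
  sequences <- list()
  window_labels <- list()
  bold <- if (include_bold) list() else NULL
  motion <- if (include_bold) list() else NULL
  cort_rows <- list()
  subj_rows <- list()

  for (i in seq_len(n)) {
    sid <- subj_ids[i]
    sequences[[sid]] <- list()
    window_labels[[sid]] <- list()
    if (include_bold) {
      bold[[sid]] <- list()
      motion[[sid]] <- list()
    }
    for (r in seq_len(spec$runs_per_subject)) {
      run <- runs[r]
      seq_len_r <- if (include_bold) spec$volumes_per_run else n_windows
      sq <- generate_state_sequence(seq_len_r, targets[i, r, ],
                                    mean_dwell = spec$mean_dwell,
                                    seed = next_seed(),
                                    exact = spec$exact_occupancy)
      sequences[[sid]][[run]] <- sq
      if (include_bold) {
        bold[[sid]][[run]] <- generate_bold_run(
          sq, centroids, noise_sd = spec$noise_sd, seed = next_seed(),
          tr_seconds = spec$tr_seconds, subject_id = sid, run_id = run)
        motion[[sid]][[run]] <- generate_motion_params(
          spec$volumes_per_run, spike_rate = spec$spike_rate, seed = next_seed())
        window_labels[[sid]][[run]] <-
          majority_window_labels(sq$labels, spec$window)
      } else {
        next_seed(); next_seed()  # keep the seed stream aligned across modes
        window_labels[[sid]][[run]] <- sq$labels
      }
    }
    cs <- generate_cortisol_series(spec$cortisol_baseline, peak_delta[i],
                                   noise_sd = spec$cortisol_noise_sd,
                                   seed = next_seed(), subject_id = sid)
    summ <- cortisol_summary(cs, log_scale = TRUE)
    cort_rows[[i]] <- data.frame(subject = sid, timepoint_min = cs$timepoints,
                                 concentration_ug_dl = cs$concentrations,
                                 stringsAsFactors = FALSE)
    subj_rows[[i]] <- data.frame(
      subject = sid, ffmq_total = ffmq_total[i],
      stress_change = ratings$stress_change[i],
      alertness_change = ratings$alertness_change[i],
      aucg = summ$aucg, auci = summ$auci, qc_pass = TRUE,
      stringsAsFactors = FALSE)
  }

  occupancy <- occupancy_table(window_labels, k, spec$state_names)
  target_rows <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(seq_len(spec$runs_per_subject), function(r) {
      data.frame(subject = subj_ids[i], run = runs[r],
                 state = spec$state_names, proportion = targets[i, r, ],
                 stringsAsFactors = FALSE)
    }))
  }))

  structure(list(
    subjects = do.call(rbind, subj_rows),
    cortisol = do.call(rbind, cort_rows),
    occupancy = occupancy,
    runs = bold,
    motion = motion,
    ground_truth = list(
      latent_delta = data.frame(subject = subj_ids, latent_delta = latent_delta,
                                stringsAsFactors = FALSE),
      occupancy_target = target_rows,
      window_labels = window_labels,
      sequences = sequences
    ),
    centroids = centroids,
    spec = spec
  ), class = "dfc_cohort")
}

# Ground-truth label of window j (which averages derivative samples
# j+1..j+w, i.e. volumes j+1..j+w+1): the state occupying the majority of
# those volumes; ties go to the centre volume's state.
majority_window_labels <- function(volume_labels, w) {
  t_n <- length(volume_labels)
  n_win <- t_n - 1L - w
  out <- integer(n_win)
  for (j in seq_len(n_win)) {
    span <- volume_labels[(j + 1L):(j + w + 1L)]
    counts <- tabulate(span, nbins = max(volume_labels))
    top <- which(counts == max(counts))
    out[j] <- if (length(top) == 1L) top else span[ceiling((w + 2L) / 2)]
  }
  out
}

#' @export
print.dfc_cohort <- function(x, ...) {
  cat(sprintf("<dfc_cohort> %d subjects x %d runs (%s BOLD), k = %d states\n",
              x$spec$n_subjects, x$spec$runs_per_subject,
              if (is.null(x$runs)) "without" else "with", x$spec$k))
  invisible(x)
}
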