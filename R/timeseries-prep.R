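#' ROI BOLD time series container
#'
#' Bundles one run's T x n_roi matrix of region-averaged BOLD signal with its
#' sampling interval and identifiers. All downstream stages (motion QC, MTD
#' coupling) operate on this container.
#'
#' @param values numeric matrix, T rows (volumes) x n_roi columns (regions).
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param roi_names optional character vector of region labels; defaults to
#'   `ROI_001` style names.
#' @param subject_id,run_id optional identifiers carried through outputs.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr_seconds = 2, roi_names = NULL,
                           subject_id = NA_character_, run_id = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_invalid("values must be a numeric matrix")
  if (nrow(values) < 2L) stop_invalid("a run needs at least 2 volumes, got ", nrow(values))
  if (any(!is.finite(values))) stop_invalid("values must be finite")
  assert_scalar(tr_seconds, "tr_seconds", lower = 1e-9)
  if (is.null(roi_names)) {
    roi_names <- colnames(values)
    if (is.null(roi_names)) roi_names <- sprintf("ROI_%03d", seq_len(ncol(values)))
  }
  if (length(roi_names) != ncol(values)) {
    stop_invalid("roi_names length (", length(roi_names),
                 ") must match column count (", ncol(values), ")")
  }
  colnames(values) <- roi_names
  structure(
    list(values = values, tr_seconds = as.numeric(tr_seconds),
         roi_names = as.character(roi_names),
         subject_id = as.character(subject_id), run_id = as.character(run_id)),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d volumes x %d ROIs, TR = %gs (subject %s, run %s)\n",
              nrow(x$values), ncol(x$values), x$tr_seconds, x$subject_id, x$run_id))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

#' Framewise displacement from rigid-body motion parameters
#'
#' FD at volume t is the sum of absolute backward differences of the six
#' rigid-body realignment parameters, with the three rotations converted to
#' arc length on a sphere (default radius 50 mm, the field-standard
#' approximation of the cortical distance from the head centre). The first
#' volume has no predecessor and is defined to have FD 0.
#'
#' @param motion_params numeric T x 6 matrix: columns 1-3 translations in mm,
#'   columns 4-6 rotations in radians.
#' @param sphere_radius_mm radius used to convert rotations to mm of arc.
#' @return numeric vector of length T, in mm; first element 0.
#' @export
framewise_displacement <- function(motion_params, sphere_radius_mm = 50) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6L) {
    stop_invalid("motion_params must have 6 columns (3 translations mm, 3 rotations rad), got ",
                 ncol(motion_params))
  }
  assert_scalar(sphere_radius_mm, "sphere_radius_mm", lower = 1e-9)
  t_n <- nrow(motion_params)
  if (t_n < 1L) stop_invalid("motion_params must have at least one row")
  if (t_n == 1L) return(0)
  d <- abs(diff(motion_params))
  d[, 4:6] <- d[, 4:6] * sphere_radius_mm
  c(0, rowSums(d))
}

#' DVARS signal-change series
#'
#' DVARS at volume t is the root-mean-square over ROIs of the backward signal
#' difference, expressed as a percentage of the run's global mean signal
#' (mean over all volumes and ROIs). The first volume is defined as 0. The
#' percent normalisation makes the measure invariant to overall signal scale.
#'
#' @param ts a [roi_timeseries()].
#' @return numeric vector of length T (percent); first element 0.
#' @export
dvars_series <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- ts$values
  if (nrow(x) < 2L) stop_invalid("DVARS needs at least 2 volumes")
  g <- mean(x)
  if (abs(g) < .Machine$double.eps * 100) {
    stop_degenerate("run global mean signal is zero; percent DVARS undefined")
  }
  d <- diff(x)
  rms <- sqrt(rowMeans(d^2))
  c(0, 100 * rms / g)
}

#' Mark high-motion volumes
#'
#' A volume is marked when FD exceeds `fd_threshold` (mm) or DVARS exceeds
#' `dvars_threshold` (percent); both comparisons are strict. Each marked
#' volume additionally marks `extend_before` predecessors and `extend_after`
#' successors (clipped at run boundaries), so that motion-contaminated
#' windows on either side of a spike are caught.
#'
#' @param fd,dvars equal-length numeric series from
#'   [framewise_displacement()] and [dvars_series()].
#' @param fd_threshold FD threshold in mm (default 0.2).
#' @param dvars_threshold DVARS threshold in percent (default 5).
#' @param extend_before,extend_after number of neighbouring volumes marked
#'   around each spike (defaults 1 and 2).
#' @return logical vector: `TRUE` where a volume is treated as high motion.
#' @export
mark_high_motion <- function(fd, dvars, fd_threshold = 0.2, dvars_threshold = 5,
                             extend_before = 1L, extend_after = 2L) {
  if (length(fd) != length(dvars)) {
    stop_invalid("fd and dvars must have the same length (", length(fd),
                 " vs ", length(dvars), ")")
  }
  assert_scalar(fd_threshold, "fd_threshold", lower = 0)
  assert_scalar(dvars_threshold, "dvars_threshold", lower = 0)
  extend_before <- assert_count(extend_before, "extend_before", min = 0L)
  extend_after <- assert_count(extend_after, "extend_after", min = 0L)
  t_n <- length(fd)
  spikes <- which(fd > fd_threshold | dvars > dvars_threshold)
  mask <- logical(t_n)
  for (s in spikes) {
    lo <- max(1L, s - extend_before)
    hi <- min(t_n, s + extend_after)
    mask[lo:hi] <- TRUE
  }
  mask
}

#' Interpolate marked volumes from surrounding data
#'
#' Replaces each marked volume, per ROI, by linear interpolation between the
#' nearest unmarked volumes; marked volumes at the start or end of the run
#' take the nearest unmarked value. Unmarked volumes pass through untouched
#' (bit-identical). Marked frames are repaired rather than removed so the
#' temporal structure needed by windowed coupling stays intact.
#'
#' @param ts a [roi_timeseries()].
#' @param mask logical vector of length T from [mark_high_motion()].
#' @return a [roi_timeseries()] with marked volumes replaced.
#' @export
interpolate_marked <- function(ts, mask) {
  stopifnot(inherits(ts, "roi_timeseries"))
  mask <- as.logical(mask)
  t_n <- nrow(ts$values)
  if (length(mask) != t_n) {
    stop_invalid("mask length (", length(mask), ") must equal run length (", t_n, ")")
  }
  if (all(mask)) stop_degenerate("all volumes marked; nothing to interpolate from")
  if (!any(mask)) return(ts)
  keep <- which(!mask)
  out <- ts$values
  bad <- which(mask)
  for (j in seq_len(ncol(out))) {
    out[bad, j] <- stats::approx(x = keep, y = ts$values[keep, j], xout = bad,
                                 method = "linear", rule = 2)$y
  }
  ts$values <- out
  ts
}

#' Discard initial volumes of a run
#'
#' Drops the first `n` volumes (default 4), the frames acquired before the
#' longitudinal magnetisation reaches steady state.
#'
#' @param ts a [roi_timeseries()].
#' @param n number of leading volumes to drop.
#' @return a [roi_timeseries()] with T - n volumes, order preserved.
#' @export
discard_initial_frames <- function(ts, n = 4L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  n <- assert_count(n, "n", min = 0L)
  t_n <- nrow(ts$values)
  if (n >= t_n) stop_invalid("cannot discard ", n, " of ", t_n, " volumes")
  if (n == 0L) return(ts)
  ts$values <- ts$values[-seq_len(n), , drop = FALSE]
  ts
}

#' Run-level motion exclusion rule
#'
#' A run fails QC when strictly more than `max_fraction` of its volumes are
#' marked as high motion.
#'
#' @param mask logical high-motion mask for the run.
#' @param max_fraction exclusion threshold on the marked fraction
#'   (default 0.5).
#' @return list with `pass` (logical) and `fraction_marked`.
#' @export
qc_exclusion <- function(mask, max_fraction = 0.5) {
  mask <- as.logical(mask)
  if (length(mask) == 0L) stop_invalid("mask must be nonempty")
  assert_scalar(max_fraction, "max_fraction", lower = 0, upper = 1)
  frac <- mean(mask)
  list(pass = frac <= max_fraction, fraction_marked = frac)
}

#' Motion QC in one step
#'
#' Convenience wrapper: discard initial frames, compute FD/DVARS, mark high
#' motion, interpolate marked volumes, apply the exclusion rule. The initial
#' frames are dropped from both signal and motion trace before FD/DVARS are
#' computed, so marking indices align with the retained volumes.
#'
#' @param ts a [roi_timeseries()].
#' @param motion_params T x 6 motion trace aligned to `ts` (before discard).
#' @param discard_frames leading volumes to drop (default 4).
#' @inheritParams mark_high_motion
#' @param max_fraction exclusion threshold (default 0.5).
#' @return list: `ts` (cleaned series), `fd`, `dvars`, `mask`,
#'   `fraction_marked`, `pass`.
#' @export
prepare_run <- function(ts, motion_params, discard_frames = 4L,
                        fd_threshold = 0.2, dvars_threshold = 5,
                        extend_before = 1L, extend_after = 2L,
                        max_fraction = 0.5) {
  stopifnot(inherits(ts, "roi_timeseries"))
  motion_params <- as.matrix(motion_params)
  if (nrow(motion_params) != nrow(ts$values)) {
    stop_invalid("motion trace rows (", nrow(motion_params),
                 ") must equal run volumes (", nrow(ts$values), ")")
  }
  discard_frames <- assert_count(discard_frames, "discard_frames", min = 0L)
  ts2 <- discard_initial_frames(ts, discard_frames)
  mp2 <- if (discard_frames > 0L) motion_params[-seq_len(discard_frames), , drop = FALSE] else motion_params
  fd <- framewise_displacement(mp2)
  dv <- dvars_series(ts2)
  mask <- mark_high_motion(fd, dv, fd_threshold, dvars_threshold,
                           extend_before, extend_after)
  qc <- qc_exclusion(mask, max_fraction)
  clean <- if (qc$fraction_marked < 1) interpolate_marked(ts2, mask) else ts2
  list(ts = clean, fd = fd, dvars = dv, mask = mask,
       fraction_marked = qc$fraction_marked, pass = qc$pass)
}
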