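# Salivary cortisol: log transform and trapezoidal AUC summaries
# (with-respect-to-ground and increase-above-baseline).

#' Cortisol sample series
#'
#' Concentrations at sampling timepoints stated in minutes relative to
#' stress onset (the standard design samples at -30, 0, +20, +60, +90 min).
#'
#' @param timepoints strictly increasing numeric vector of minutes.
#' @param concentrations positive concentrations (ug/dL), same length.
#' @param subject_id optional identifier.
#' @param log_scale logical: are the values already log-transformed?
#' @return object of class `cortisol_series`.
#' @export
cortisol_series <- function(timepoints, concentrations,
                            subject_id = NA_character_, log_scale = FALSE) {
  timepoints <- as.numeric(timepoints)
  concentrations <- as.numeric(concentrations)
  if (length(timepoints) != length(concentrations)) {
    stop_invalid("timepoints and concentrations must have equal length")
  }
  if (length(timepoints) < 1L) stop_invalid("series must be nonempty")
  if (any(diff(timepoints) <= 0)) {
    stop_invalid("timepoints must be strictly increasing")
  }
  if (!log_scale && any(concentrations <= 0)) {
    bad <- which(concentrations <= 0)[1]
    stop_invalid("non-positive concentration at timepoint ", timepoints[bad],
                 " min (sample ", bad, ")")
  }
  structure(list(timepoints = timepoints, concentrations = concentrations,
                 subject_id = as.character(subject_id),
                 log_scale = isTRUE(log_scale)),
            class = "cortisol_series")
}

#' @export
print.cortisol_series <- function(x, ...) {
  cat(sprintf("<cortisol_series> %d samples (%s scale), t = %s min\n",
              length(x$timepoints), if (x$log_scale) "log" else "raw",
              paste(x$timepoints, collapse = ", ")))
  invisible(x)
}

#' Natural-log transform of a cortisol series
#'
#' Cortisol concentrations are positively skewed; analyses run on the
#' natural-log scale. Timepoints are unchanged.
#'
#' @param series a [cortisol_series()] on the raw scale.
#' @return a [cortisol_series()] with `log_scale = TRUE`.
#' @export
log_transform_cortisol <- function(series) {
  stopifnot(inherits(series, "cortisol_series"))
  if (series$log_scale) return(series)
  if (any(series$concentrations <= 0)) {
    bad <- which(series$concentrations <= 0)[1]
    stop_invalid("cannot log-transform non-positive concentration at timepoint ",
                 series$timepoints[bad], " min (sample ", bad, ")")
  }
  cortisol_series(series$timepoints, log(series$concentrations),
                  series$subject_id, log_scale = TRUE)
}

#' Area under the cortisol curve with respect to ground (AUCg)
#'
#' Trapezoidal integration over all samples: total output over the span of
#' the experiment, `sum((c_i + c_{i+1})/2 * (t_{i+1} - t_i))`.
#'
#' @param series a [cortisol_series()] with at least 2 samples.
#' @return AUCg in concentration-units x minutes.
#' @export
auc_ground <- function(series) {
  stopifnot(inherits(series, "cortisol_series"))
  t <- series$timepoints
  c_ <- series$concentrations
  if (length(t) < 2L) stop_invalid("AUC needs at least 2 samples")
  sum((c_[-length(c_)] + c_[-1]) / 2 * diff(t))
}

#' Area under the cortisol curve with respect to increase (AUCi)
#'
#' Output attributable to the stress response: AUCg minus baseline
#' production, where baseline production is the first sample held constant
#' over the full span, `auci = aucg - c_1 * (t_last - t_first)`. Negative
#' values indicate a net decrease from baseline.
#'
#' @param series a [cortisol_series()] with at least 2 samples.
#' @return AUCi in concentration-units x minutes.
#' @export
auc_increase <- function(series) {
  stopifnot(inherits(series, "cortisol_series"))
  t <- series$timepoints
  if (length(t) < 2L) stop_invalid("AUC needs at least 2 samples")
  auc_ground(series) - series$concentrations[1] * (t[length(t)] - t[1])
}

#' Cortisol AUC summary for one subject
#'
#' Convenience wrapper computing AUCg and AUCi, by default on the
#' natural-log scale (the scale the statistical analyses use; set
#' `log_scale = FALSE` for raw-scale AUCs).
#'
#' @param series a [cortisol_series()] on the raw scale.
#' @param log_scale transform before integration (default TRUE).
#' @return list: `aucg`, `auci`, `log_scale`, `subject_id`.
#' @export
cortisol_summary <- function(series, log_scale = TRUE) {
  stopifnot(inherits(series, "cortisol_series"))
  s <- if (log_scale) log_transform_cortisol(series) else series
  list(aucg = auc_ground(s), auci = auc_increase(s),
       log_scale = log_scale, subject_id = series$subject_id)
}
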