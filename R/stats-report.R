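# Pre-planned inferential battery: paired t-tests across resting runs,
# Pearson/Spearman correlations among occupancy changes, cortisol output,
# trait mindfulness and subjective ratings, with family-wise adjustment.

stat_result <- function(test, variable_a, variable_b, estimate, df, n, p,
                        family = NA_character_) {
  data.frame(test = test, variable_a = variable_a, variable_b = variable_b,
             estimate = estimate, df = df, n = n, p = p,
             p_adjusted = NA_real_, family = family,
             stringsAsFactors = FALSE)
}

#' Score the Five Facet Mindfulness Questionnaire (FFMQ)
#'
#' 39 items rated 1 ("never or very rarely true") to 5 ("very often or always
#' true"). Items in `reverse_set` (the Non-Judging and Acting-with-Awareness
#' keying) are reverse-scored as `6 - x` before summing, giving a full-scale
#' total in 39..195.
#'
#' @param items integer vector of exactly 39 responses in 1..5.
#' @param reverse_set indices of reverse-keyed items (may be empty).
#' @return integer full-scale score.
#' @export
score_ffmq <- function(items, reverse_set = integer(0)) {
  if (length(items) != 39L) {
    stop_invalid("FFMQ has 39 items; got ", length(items))
  }
  items <- as.numeric(items)
  if (any(!is.finite(items)) || any(items < 1 | items > 5) ||
      any(items != round(items))) {
    stop_invalid("FFMQ responses must be integers in 1..5")
  }
  reverse_set <- as.integer(reverse_set)
  if (length(reverse_set) && (any(reverse_set < 1L) || any(reverse_set > 39L))) {
    stop_invalid("reverse_set indices must lie in 1..39")
  }
  items[reverse_set] <- 6 - items[reverse_set]
  as.integer(sum(items))
}

#' Paired-samples t-test as a tidy result row
#'
#' Two-sided paired t-test (t on the within-subject differences with n - 1
#' degrees of freedom), via [stats::t.test()].
#'
#' @param x,y equal-length paired numeric samples (n >= 3, no missing pairs).
#' @param variable_a,variable_b labels for the report row.
#' @param family comparison-family label for later adjustment.
#' @return one-row data.frame (test, variable_a, variable_b, estimate = t,
#'   df, n, p, p_adjusted, family).
#' @export
paired_ttest <- function(x, y, variable_a = "x", variable_b = "y",
                         family = NA_character_) {
  if (length(x) != length(y)) stop_invalid("paired samples must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_invalid("paired t-test needs at least 3 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0) stop_degenerate("zero variance of paired differences")
  fit <- stats::t.test(x, y, paired = TRUE)
  stat_result("paired_t", variable_a, variable_b,
              unname(fit$statistic), unname(fit$parameter), length(x),
              fit$p.value, family)
}

#' Pearson correlation as a tidy result row
#'
#' Sample Pearson correlation with two-sided p from the t transform on
#' n - 2 degrees of freedom, via [stats::cor.test()]. Pairs with missing
#' values are dropped (pairwise-complete).
#'
#' @inheritParams paired_ttest
#' @return one-row data.frame with estimate = r.
#' @export
pearson_corr <- function(x, y, variable_a = "x", variable_b = "y",
                         family = NA_character_) {
  if (length(x) != length(y)) stop_invalid("samples must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_invalid("correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_degenerate("zero variance in a correlation input")
  }
  fit <- stats::cor.test(x, y, method = "pearson")
  stat_result("pearson_r", variable_a, variable_b,
              unname(fit$estimate), unname(fit$parameter), length(x),
              fit$p.value, family)
}

#' Spearman rank correlation as a tidy result row
#'
#' rho is the Pearson correlation of average ranks (ties share their mean
#' rank); the two-sided p comes from the t transform on n - 2 degrees of
#' freedom applied to rho.
#'
#' @inheritParams paired_ttest
#' @return one-row data.frame with estimate = rho.
#' @export
spearman_corr <- function(x, y, variable_a = "x", variable_b = "y",
                          family = NA_character_) {
  if (length(x) != length(y)) stop_invalid("samples must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("correlation needs at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_degenerate("all-tied vector: rank correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  stat_result("spearman_rho", variable_a, variable_b, rho, n - 2, n, p, family)
}

#' Family-wise p-value adjustment
#'
#' Bonferroni or Holm step-down adjustment within one comparison family, via
#' [stats::p.adjust()]. Adjusted values are monotone in the raw values and
#' capped at 1.
#'
#' @param p numeric vector of raw p-values in 0..1.
#' @param method `"holm"` (default) or `"bonferroni"`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = method)
}

#' Pre-planned relationship table across the cohort
#'
#' Runs the full battery linking occupancy dynamics, cortisol output, trait
#' mindfulness and subjective ratings:
#'
#' * paired t-tests on each named state's occupancy, RS1 vs RS2 (stress) and
#'   RS2 vs RS3 (recovery) — family `"state_change"`;
#' * Pearson correlations of the stress change scores of the arousal states
#'   with subjective stress and alertness change — family `"ratings"`;
#' * AUCg and AUCi against the three states' stress change scores — family
#'   `"cortisol"` (six tests);
#' * FFMQ against the three states' stress change scores — family
#'   `"mindfulness"` (three tests) — and against baseline (RS1) occupancy of
#'   the task-ready state — family `"baseline"`;
#' * the pairwise couplings among the three states' change scores — family
#'   `"state_coupling"` (these are differences of simplex coordinates and so
#'   are structurally inter-dependent; they describe, not test, the data).
#'
#' p-values are adjusted within family. Tests whose inputs are missing or
#' have fewer than 3 complete pairs are skipped with a message.
#'
#' @param subjects data.frame with columns `subject`, and any of
#'   `ffmq_total`, `aucg`, `auci`, `stress_change`, `alertness_change`,
#'   `qc_pass` (subjects with `qc_pass == FALSE` are dropped).
#' @param occupancy data.frame from [occupancy_table()].
#' @param states named character vector mapping roles
#'   `c(task_ready =, high_arousal =, low_arousal =)` to state names in
#'   `occupancy$state`.
#' @param runs the three run names in temporal order.
#' @param adjust_method `"holm"` (default) or `"bonferroni"`.
#' @return data.frame of result rows (see [paired_ttest()]) with adjusted
#'   p-values, plus attribute `"skipped"` listing skipped tests and reasons.
#' @export
analysis_table <- function(subjects, occupancy,
                           states = c(task_ready = "TRS",
                                      high_arousal = "HAS",
                                      low_arousal = "LAS"),
                           runs = c("RS1", "RS2", "RS3"),
                           adjust_method = c("holm", "bonferroni")) {
  adjust_method <- match.arg(adjust_method)
  stopifnot(is.data.frame(subjects), "subject" %in% names(subjects))
  if (!all(c("task_ready", "high_arousal", "low_arousal") %in% names(states))) {
    stop_invalid("states must name task_ready, high_arousal and low_arousal")
  }
  if ("qc_pass" %in% names(subjects)) {
    subjects <- subjects[is.na(subjects$qc_pass) | subjects$qc_pass, , drop = FALSE]
  }
  occupancy <- occupancy[occupancy$subject %in% subjects$subject, , drop = FALSE]
  deltas <- change_scores(occupancy, runs = runs)

  subj_ids <- sort(unique(subjects$subject))
  col_of <- function(df, value_col, filter) {
    # align a per-subject value onto subj_ids (NA where absent)
    sub <- df[filter, , drop = FALSE]
    out <- rep(NA_real_, length(subj_ids))
    idx <- match(sub$subject, subj_ids)
    ok <- !is.na(idx)
    out[idx[ok]] <- sub[[value_col]][ok]
    out
  }
  occ_run_state <- function(run, state) {
    col_of(occupancy, "proportion", occupancy$run == run & occupancy$state == state)
  }
  delta_state <- function(state, col = "delta_21") {
    col_of(deltas, col, deltas$state == state)
  }
  subj_var <- function(name) {
    if (!name %in% names(subjects)) return(NULL)
    col_of(subjects, name, rep(TRUE, nrow(subjects)))
  }

  rows <- list()
  skipped <- list()
  add <- function(fun, x, y, a, b, family) {
    if (is.null(x) || is.null(y)) {
      skipped[[length(skipped) + 1L]] <<- paste0(a, " ~ ", b, ": variable missing")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(x, y, a, b, family),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <<- paste0(a, " ~ ", b, ": ", res)
    } else {
      rows[[length(rows) + 1L]] <<- res
    }
    invisible(NULL)
  }

  trs <- states[["task_ready"]]; has <- states[["high_arousal"]]; las <- states[["low_arousal"]]
  for (st in c(trs, has, las)) {
    add(paired_ttest, occ_run_state(runs[2], st), occ_run_state(runs[1], st),
        paste0(st, "_", runs[2]), paste0(st, "_", runs[1]), "state_change")
    add(paired_ttest, occ_run_state(runs[3], st), occ_run_state(runs[2], st),
        paste0(st, "_", runs[3]), paste0(st, "_", runs[2]), "state_change")
  }
  for (st in c(has, las)) {
    add(pearson_corr, delta_state(st), subj_var("stress_change"),
        paste0("delta_", st), "stress_change", "ratings")
    add(pearson_corr, delta_state(st), subj_var("alertness_change"),
        paste0("delta_", st), "alertness_change", "ratings")
  }
  for (auc in c("aucg", "auci")) {
    for (st in c(trs, has, las)) {
      add(pearson_corr, subj_var(auc), delta_state(st),
          auc, paste0("delta_", st), "cortisol")
    }
  }
  for (st in c(trs, has, las)) {
    add(pearson_corr, subj_var("ffmq_total"), delta_state(st),
        "ffmq_total", paste0("delta_", st), "mindfulness")
  }
  add(pearson_corr, subj_var("ffmq_total"), occ_run_state(runs[1], trs),
      "ffmq_total", paste0(trs, "_", runs[1]), "baseline")
  pairs <- list(c(has, las), c(has, trs), c(las, trs))
  for (pr in pairs) {
    add(pearson_corr, delta_state(pr[1]), delta_state(pr[2]),
        paste0("delta_", pr[1]), paste0("delta_", pr[2]), "state_coupling")
  }

  if (!length(rows)) {
    out <- data.frame(test = character(0), variable_a = character(0),
                      variable_b = character(0), estimate = numeric(0),
                      df = numeric(0), n = numeric(0), p = numeric(0),
                      p_adjusted = numeric(0), family = character(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    for (fam in unique(out$family)) {
      idx <- which(out$family == fam)
      out$p_adjusted[idx] <- adjust_pvalues(out$p[idx], adjust_method)
    }
  }
  attr(out, "skipped") <- unlist(skipped)
  attr(out, "adjust_method") <- adjust_method
  out
}
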