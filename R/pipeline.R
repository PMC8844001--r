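# End-to-end orchestration: simulate (or load) -> motion QC -> MTD windows
# -> state clustering -> occupancy -> cortisol -> statistical battery, with
# one master seed and provenance headers on every artifact.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline in one validated, serialisable
#' object. Defaults follow the analysis conventions the package implements:
#' 7-TR MTD window, k = 5 states, 4 discarded initial frames, FD > 0.2 mm /
#' DVARS > 5% marking extended 1 back and 2 forward, 50% exclusion, AUCs on
#' the natural-log scale, Holm adjustment.
#'
#' @param window MTD smoothing window in TRs.
#' @param k number of connectivity states.
#' @param n_restarts k-means restarts.
#' @param seed master seed for every stochastic stage.
#' @param discard_frames initial volumes dropped per run.
#' @param fd_threshold,dvars_threshold,extend_before,extend_after,max_fraction
#'   motion-QC settings (see [mark_high_motion()], [qc_exclusion()]).
#' @param auc_log_scale compute cortisol AUCs on the log scale (default
#'   TRUE).
#' @param adjust_method `"holm"` or `"bonferroni"`.
#' @param simulate generate the cohort with [generate_cohort()] (default
#'   TRUE); otherwise read inputs from `input_dir`.
#' @param cohort list of [cohort_spec()] arguments for the simulate stage
#'   (empty list = study-scale defaults).
#' @param input_dir directory of input TSVs when `simulate = FALSE`.
#' @param reference_centroids optional path to a k x p reference centroid
#'   matrix ([read_centroids()] format); fitted states are named by Spearman
#'   concordance with it. In simulate mode the generating centroids serve as
#'   the reference automatically.
#' @param reference_names state names of the reference centroids, in row
#'   order.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(window = 7L, k = 5L, n_restarts = 10L, seed = 1L,
                            discard_frames = 4L, fd_threshold = 0.2,
                            dvars_threshold = 5, extend_before = 1L,
                            extend_after = 2L, max_fraction = 0.5,
                            auc_log_scale = TRUE,
                            adjust_method = c("holm", "bonferroni"),
                            simulate = TRUE, cohort = list(),
                            input_dir = NULL, reference_centroids = NULL,
                            reference_names = NULL) {
  adjust_method <- match.arg(adjust_method)
  cfg <- list(
    window = assert_count(window, "window"),
    k = assert_count(k, "k"),
    n_restarts = assert_count(n_restarts, "n_restarts"),
    seed = assert_count(seed, "seed", min = 0L),
    discard_frames = assert_count(discard_frames, "discard_frames", min = 0L),
    fd_threshold = assert_scalar(fd_threshold, "fd_threshold", lower = 0),
    dvars_threshold = assert_scalar(dvars_threshold, "dvars_threshold", lower = 0),
    extend_before = assert_count(extend_before, "extend_before", min = 0L),
    extend_after = assert_count(extend_after, "extend_after", min = 0L),
    max_fraction = assert_scalar(max_fraction, "max_fraction", lower = 0, upper = 1),
    auc_log_scale = isTRUE(auc_log_scale),
    adjust_method = adjust_method,
    simulate = isTRUE(simulate),
    cohort = cohort,
    input_dir = input_dir,
    reference_centroids = reference_centroids,
    reference_names = reference_names
  )
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat(sprintf("<analysis_config> w = %d, k = %d, restarts = %d, seed = %d (%s)\n",
              x$window, x$k, x$n_restarts, x$seed,
              if (x$simulate) "simulate" else paste("inputs:", x$input_dir)))
  invisible(x)
}

#' Read / write an analysis configuration as YAML
#'
#' The YAML round-trip is lossless: `read_config(write_config(cfg, path))`
#' reproduces `cfg`.
#'
#' @param config an [analysis_config()].
#' @param path YAML file path.
#' @return `write_config`: the path, invisibly; `read_config`: an
#'   [analysis_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(analysis_config, raw)
}

load_cohort_inputs <- function(input_dir, tr_seconds = 2) {
  subj_path <- file.path(input_dir, "subjects.tsv")
  if (!file.exists(subj_path)) stop_invalid("missing ", subj_path)
  subjects <- read_table_tsv(subj_path)
  cort_path <- file.path(input_dir, "cortisol.tsv")
  cortisol <- if (file.exists(cort_path)) read_table_tsv(cort_path) else NULL
  runs <- list()
  motion <- list()
  for (sid in subjects$subject) {
    bold_files <- sort(list.files(input_dir, sprintf("^%s_RS\\d+_bold\\.tsv$", sid)))
    if (!length(bold_files)) stop_invalid("no BOLD TSVs for subject ", sid)
    runs[[sid]] <- list()
    motion[[sid]] <- list()
    for (bf in bold_files) {
      run <- sub(sprintf("^%s_(RS\\d+)_bold\\.tsv$", sid), "\\1", bf)
      runs[[sid]][[run]] <- read_roi_tsv(file.path(input_dir, bf),
                                         tr_seconds = tr_seconds,
                                         subject_id = sid, run_id = run)
      mf <- file.path(input_dir, sprintf("%s_%s_motion.tsv", sid, run))
      if (!file.exists(mf)) stop_invalid("missing motion trace ", mf)
      motion[[sid]][[run]] <- read_motion_tsv(mf)
    }
  }
  list(subjects = subjects, cortisol = cortisol, runs = runs, motion = motion)
}

#' Run the full analysis pipeline
#'
#' Executes, in fixed order: simulate (or load) -> motion QC -> MTD windowed
#' coupling -> cityblock k-means state fitting -> fractional occupancy and
#' change scores -> cortisol AUC summaries -> the pre-planned statistical
#' battery. All tables are written to `out_dir` with a provenance header
#' (config hash and seed); re-running with the same configuration reproduces
#' every output bit-identically.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages (default FALSE).
#' @return list (invisibly): `qc`, `occupancy`, `deltas`, `subjects`,
#'   `model`, `labels`, `stats`, `config`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  say <- function(...) if (!quiet) message("[dfcstates] ", ...)
  if (!config$simulate) {
    if (is.null(config$input_dir) || !dir.exists(config$input_dir)) {
      stop_invalid("input_dir does not exist: ",
                   if (is.null(config$input_dir)) "<NULL>" else config$input_dir)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- list(config_hash = content_hash(unclass(config)),
               seed = config$seed, package = "dfcstates")

  # stage 1: inputs
  if (config$simulate) {
    say("simulate: generating cohort")
    spec <- do.call(cohort_spec, c(config$cohort, list(seed = config$seed)))
    cohort <- generate_cohort(spec, include_bold = TRUE)
    subjects <- cohort$subjects
    cortisol <- cohort$cortisol
    runs <- cohort$runs
    motion <- cohort$motion
  } else {
    say("load: reading inputs from ", config$input_dir)
    inp <- load_cohort_inputs(config$input_dir)
    subjects <- inp$subjects
    cortisol <- inp$cortisol
    runs <- inp$runs
    motion <- inp$motion
  }

  # stage 2: motion QC
  say("prep: motion QC over ", length(runs), " subjects")
  qc_rows <- list()
  clean <- list()
  for (sid in names(runs)) {
    clean[[sid]] <- list()
    for (run in names(runs[[sid]])) {
      pr <- prepare_run(runs[[sid]][[run]], motion[[sid]][[run]],
                        discard_frames = config$discard_frames,
                        fd_threshold = config$fd_threshold,
                        dvars_threshold = config$dvars_threshold,
                        extend_before = config$extend_before,
                        extend_after = config$extend_after,
                        max_fraction = config$max_fraction)
      clean[[sid]][[run]] <- pr$ts
      qc_rows[[length(qc_rows) + 1L]] <- data.frame(
        subject = sid, run = run, fraction_marked = pr$fraction_marked,
        pass = pr$pass, stringsAsFactors = FALSE)
    }
  }
  qc <- do.call(rbind, qc_rows)
  qc_fail <- unique(qc$subject[!qc$pass])
  if (length(qc_fail)) say("prep: excluding ", length(qc_fail), " subject(s) on motion QC")
  subjects$qc_pass <- !(subjects$subject %in% qc_fail)

  # stage 3: MTD windowed coupling
  say("mtd: windowed coupling (w = ", config$window, ")")
  vec_blocks <- list()
  index_rows <- list()
  for (sid in names(clean)) {
    if (sid %in% qc_fail) next
    for (run in names(clean[[sid]])) {
      cw <- mtd_windows(clean[[sid]][[run]], w = config$window)
      v <- coupling_vectors(cw)
      vec_blocks[[length(vec_blocks) + 1L]] <- v
      index_rows[[length(index_rows) + 1L]] <- data.frame(
        subject = sid, run = run, window_index = seq_len(nrow(v)),
        stringsAsFactors = FALSE)
    }
  }
  vectors <- do.call(rbind, vec_blocks)
  index <- do.call(rbind, index_rows)

  # stage 4: state clustering
  say("fit-states: k = ", config$k, ", ", nrow(vectors), " windows")
  model <- fit_states(vectors, k = config$k, n_restarts = config$n_restarts,
                      seed = config$seed)
  labels <- cbind(index, state = model$labels)

  # stage 4b: name fitted states by concordance with reference centroids
  ref_vectors <- NULL
  ref_names <- NULL
  if (config$simulate) {
    ref_vectors <- do.call(rbind, lapply(cohort$centroids$matrices, vectorize_upper))
    ref_names <- cohort$centroids$names
  } else if (!is.null(config$reference_centroids)) {
    ref_vectors <- read_centroids(config$reference_centroids)
    ref_names <- config$reference_names
    if (is.null(ref_names)) ref_names <- sprintf("ref_%d", nrow(ref_vectors))
  }
  state_names <- sprintf("state_%d", seq_len(config$k))
  if (!is.null(ref_vectors)) {
    mm <- match_centroids(model, ref_vectors)
    ok <- !is.na(mm$mapping$rho)
    state_names[mm$mapping$a[ok]] <- ref_names[mm$mapping$b[ok]]
    say("fit-states: named states ", paste(state_names, collapse = ", "),
        " (min rho ", sprintf("%.2f", min(mm$mapping$rho, na.rm = TRUE)), ")")
  }

  # stage 5: occupancy
  say("occupancy: fractional occupancy and change scores")
  labels_by_run <- lapply(split(labels, labels$subject), function(df) {
    lapply(split(df, df$run), function(d) d$state[order(d$window_index)])
  })
  occupancy <- occupancy_table(labels_by_run, config$k, state_names)
  deltas <- change_scores(occupancy,
                          runs = intersect(c("RS1", "RS2", "RS3"),
                                           unique(occupancy$run)))

  # stage 6: cortisol summaries
  if (!is.null(cortisol)) {
    say("cortisol: AUC summaries (", if (config$auc_log_scale) "log" else "raw",
        " scale)")
    sums <- lapply(split(cortisol, cortisol$subject), function(df) {
      df <- df[order(df$timepoint_min), , drop = FALSE]
      cs <- cortisol_series(df$timepoint_min, df$concentration_ug_dl,
                            subject_id = df$subject[1])
      cortisol_summary(cs, log_scale = config$auc_log_scale)
    })
    auc_df <- data.frame(subject = names(sums),
                         aucg = vapply(sums, `[[`, numeric(1), "aucg"),
                         auci = vapply(sums, `[[`, numeric(1), "auci"),
                         stringsAsFactors = FALSE)
    subjects$aucg <- auc_df$aucg[match(subjects$subject, auc_df$subject)]
    subjects$auci <- auc_df$auci[match(subjects$subject, auc_df$subject)]
  }

  # stage 7: statistical battery on the three named states (or the first
  # three states when no reference naming is available)
  say("stats: pre-planned battery (", config$adjust_method, " adjustment)")
  role_names <- c("TRS", "HAS", "LAS")
  if (!all(role_names %in% state_names)) role_names <- state_names[1:3]
  state_roles <- c(task_ready = role_names[1], high_arousal = role_names[2],
                   low_arousal = role_names[3])
  stats_tab <- analysis_table(subjects, occupancy, states = state_roles,
                              adjust_method = config$adjust_method)

  write_table_tsv(qc, file.path(out_dir, "qc.tsv"), prov)
  write_table_tsv(occupancy, file.path(out_dir, "occupancy.tsv"), prov)
  write_table_tsv(deltas, file.path(out_dir, "deltas.tsv"), prov)
  write_table_tsv(subjects, file.path(out_dir, "subjects.tsv"), prov)
  write_table_tsv(labels, file.path(out_dir, "labels.tsv"), prov)
  write_table_tsv(stats_tab, file.path(out_dir, "stats.tsv"), prov)
  write_centroids(model, file.path(out_dir, "centroids.tsv"))
  write_config(config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    list(provenance = prov,
         edges = stats_tab[, c("variable_a", "variable_b", "test", "estimate",
                               "p", "p_adjusted", "family")]),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  say("done: outputs in ", out_dir)

  invisible(list(qc = qc, occupancy = occupancy, deltas = deltas,
                 subjects = subjects, model = model, labels = labels,
                 stats = stats_tab, config = config, out_dir = out_dir))
}
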