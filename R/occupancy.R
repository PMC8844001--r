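# Fractional occupancy of connectivity states and pre/post change scores.

#' Fractional occupancy of states within a run
#'
#' Proportion of the run's windows assigned to each state:
#' `count(labels == s) / length(labels)`. States never visited get exactly 0.
#'
#' @param labels integer window labels in 1..k.
#' @param k number of states.
#' @return numeric vector of length k summing to 1.
#' @export
fractional_occupancy <- function(labels, k) {
  k <- assert_count(k, "k", min = 1L)
  if (length(labels) == 0L) stop_invalid("label sequence must be nonempty")
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > k)) {
    stop_invalid("labels must lie in 1..", k)
  }
  tabulate(labels, nbins = k) / length(labels)
}

#' Build a tidy occupancy table
#'
#' One row per subject x run x state with the run's fractional occupancy.
#' Run identifiers are expected to follow the RS1/RS2/RS3 scheme (one
#' pre-stress and two post-stress resting runs).
#'
#' @param labels_by_run named list: `labels_by_run[[subject]][[run]]` is that
#'   run's integer window-label sequence.
#' @param k number of states.
#' @param state_names optional state labels (default `state_1` ...).
#' @return data.frame with columns subject, run, state, proportion.
#' @export
occupancy_table <- function(labels_by_run, k, state_names = NULL) {
  k <- assert_count(k, "k", min = 1L)
  if (is.null(state_names)) state_names <- sprintf("state_%d", seq_len(k))
  if (length(state_names) != k) stop_invalid("need ", k, " state names")
  rows <- list()
  for (subj in names(labels_by_run)) {
    runs <- labels_by_run[[subj]]
    for (run in names(runs)) {
      occ <- fractional_occupancy(runs[[run]], k)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subj, run = run, state = state_names,
        proportion = occ, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pre/post change scores of state occupancy
#'
#' For each subject and state, computes the stress change score
#' `delta_21 = RS2 - RS1` (effect of the stress induction) and the recovery
#' change score `delta_32 = RS3 - RS2` as simple differences of proportions.
#' Subjects missing any of the three runs are excluded from the change table
#' with a message (missing runs propagate as missing, never as zeros).
#'
#' @param occ data.frame from [occupancy_table()] (columns subject, run,
#'   state, proportion) with runs named `RS1`, `RS2`, `RS3`.
#' @param runs character vector of the three run names, in temporal order.
#' @return data.frame with columns subject, state, delta_21, delta_32.
#' @export
change_scores <- function(occ, runs = c("RS1", "RS2", "RS3")) {
  stopifnot(is.data.frame(occ),
            all(c("subject", "run", "state", "proportion") %in% names(occ)))
  if (length(runs) != 3L) stop_invalid("exactly three ordered runs are required")
  keep <- occ$run %in% runs
  occ <- occ[keep, , drop = FALSE]
  complete <- vapply(split(occ$run, occ$subject),
                     function(r) all(runs %in% r), logical(1))
  missing_subj <- names(complete)[!complete]
  if (length(missing_subj)) {
    message("excluding subject(s) with missing runs from change scores: ",
            paste(missing_subj, collapse = ", "))
    occ <- occ[!(occ$subject %in% missing_subj), , drop = FALSE]
  }
  if (nrow(occ) == 0L) {
    return(data.frame(subject = character(0), state = character(0),
                      delta_21 = numeric(0), delta_32 = numeric(0)))
  }
  wide <- stats::reshape(occ, idvar = c("subject", "state"), timevar = "run",
                         direction = "wide")
  p1 <- wide[[paste0("proportion.", runs[1])]]
  p2 <- wide[[paste0("proportion.", runs[2])]]
  p3 <- wide[[paste0("proportion.", runs[3])]]
  out <- data.frame(subject = wide$subject, state = wide$state,
                    delta_21 = p2 - p1, delta_32 = p3 - p2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject, out$state), , drop = FALSE]
  rownames(out) <- NULL
  out
}
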