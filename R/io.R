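# Delimited-file adapters. One dialect everywhere: tab separator, "NA"
# missing token, '#'-prefixed provenance header lines, '.' decimal mark.

write_provenance <- function(con, provenance) {
  if (is.null(provenance)) return(invisible(NULL))
  for (key in names(provenance)) {
    writeLines(sprintf("# %s: %s", key, provenance[[key]]), con)
  }
}

#' Write / read an ROI time-series TSV
#'
#' T rows x n_roi columns with a header row of ROI names; optional
#' provenance lines (`# key: value`) precede the header.
#'
#' @param ts a [roi_timeseries()].
#' @param path output path.
#' @param provenance optional named list written as `# key: value` lines.
#' @return `write_roi_tsv`: the path, invisibly.
#' @export
write_roi_tsv <- function(ts, path, provenance = NULL) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  write_provenance(con, provenance)
  utils::write.table(ts$values, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

check_numeric_cells <- function(df, path, skip_cols = character(0)) {
  for (j in setdiff(names(df), skip_cols)) {
    v <- df[[j]]
    if (is.character(v) || is.factor(v)) {
      suppressWarnings(num <- as.numeric(as.character(v)))
      bad <- which(is.na(num) & !is.na(v) & as.character(v) != "NA")
      if (length(bad)) {
        stop_invalid("non-numeric cell in ", path, " at data row ", bad[1],
                     ", column '", j, "' (value '", v[bad[1]], "')")
      }
      df[[j]] <- num
    }
  }
  df
}

#' @rdname write_roi_tsv
#' @param tr_seconds,subject_id,run_id metadata for the rebuilt container.
#' @return `read_roi_tsv`: a [roi_timeseries()].
#' @export
read_roi_tsv <- function(path, tr_seconds = 2, subject_id = NA_character_,
                         run_id = NA_character_) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  df <- check_numeric_cells(df, path)
  roi_timeseries(as.matrix(df), tr_seconds = tr_seconds,
                 roi_names = names(df), subject_id = subject_id,
                 run_id = run_id)
}

#' Write / read a 6-column rigid-body motion TSV
#'
#' Columns `trans_x trans_y trans_z rot_x rot_y rot_z` (mm, mm, mm, rad,
#' rad, rad), one row per volume.
#'
#' @param motion_params T x 6 numeric matrix.
#' @param path file path.
#' @param provenance optional named list of header lines.
#' @return `write_motion_tsv`: the path, invisibly; `read_motion_tsv`: the
#'   T x 6 matrix.
#' @export
write_motion_tsv <- function(motion_params, path, provenance = NULL) {
  motion_params <- as.matrix(motion_params)
  if (ncol(motion_params) != 6L) stop_invalid("motion trace must have 6 columns")
  colnames(motion_params) <- c("trans_x", "trans_y", "trans_z",
                               "rot_x", "rot_y", "rot_z")
  con <- file(path, "w")
  on.exit(close(con))
  write_provenance(con, provenance)
  utils::write.table(motion_params, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) != 6L) stop_invalid("motion TSV must have 6 columns, got ", ncol(df))
  df <- check_numeric_cells(df, path)
  as.matrix(df)
}

#' Write / read a centroid matrix
#'
#' Plain k x p delimited matrix (tab-separated, no header): one centroid
#' vector of n_roi(n_roi-1)/2 couplings per row — the interchange format for
#' reference (canonical) centroid resources.
#'
#' @param centroids k x p numeric matrix or a `state_model`.
#' @param path file path.
#' @return `write_centroids`: the path, invisibly; `read_centroids`: the
#'   k x p matrix.
#' @export
write_centroids <- function(centroids, path) {
  if (inherits(centroids, "state_model")) centroids <- centroids$centroids
  utils::write.table(as.matrix(centroids), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character")
  as.matrix(check_numeric_cells(df, path))
}

#' Write / read a tidy table TSV
#'
#' Tab-separated with header, `NA` missing token, optional `# key: value`
#' provenance lines before the header.
#'
#' @param df data.frame.
#' @param path file path.
#' @param provenance optional named list of header lines.
#' @return `write_table_tsv`: the path, invisibly; `read_table_tsv`: the
#'   data.frame.
#' @export
write_table_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  write_provenance(con, provenance)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    na.strings = "NA", stringsAsFactors = FALSE)
}
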