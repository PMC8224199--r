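#' Read a feature table from TSV
#'
#' Expects a tab-separated file whose first column is named `feature_id` and
#' whose remaining column names are sample IDs; cells are non-negative
#' numbers. Lines starting with `#` are header comments and are skipped.
#' Count status is inferred: the table is flagged as counts iff every value
#' is integral.
#'
#' @param path file path.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "feature_id")
    stop(sprintf("'%s': first column must be 'feature_id', found '%s'",
                 path, names(df)[1L]))
  fid <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop(sprintf("'%s': non-numeric cell at feature '%s', sample '%s'",
                 path, fid[bad[1L, 1L]], colnames(df)[-1L][bad[1L, 2L]]))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("'%s': missing/non-numeric cell at feature '%s', sample '%s'",
                 path, fid[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- fid
  feature_table(m)
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]: features as rows, a `feature_id` first
#' column, one column per sample, with a `#` comment line carrying the
#' package version.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature_id = feature_ids(table), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_result_tsv(df, path)
}

#' Read sample metadata from TSV
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `study_id`,
#'   `timepoint_months` (months since surgery; 0 = pre-surgery baseline).
#' @return a [sample_metadata()].
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  tp <- suppressWarnings(as.numeric(df$timepoint_months))
  if (!is.null(df$timepoint_months) && anyNA(tp))
    stop(sprintf("'%s': non-numeric timepoint for sample '%s'", path,
                 df$sample_id[which(is.na(tp))[1L]]))
  sample_metadata(df)
}

#' @rdname read_metadata
#' @param meta a [sample_metadata()].
#' @param path output file path.
#' @export
write_metadata <- function(meta, path) {
  write_result_tsv(as.data.frame(meta), path)
}
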