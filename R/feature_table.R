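#' Feature-by-sample abundance table
#'
#' The basic container of the package: a non-negative numeric matrix with
#' features (taxa, species, or metabolic pathways) as rows and samples as
#' columns, plus a flag saying whether the values are raw sequence counts or
#' continuous abundances (e.g. pathway copies-per-million).
#'
#' @param values numeric matrix, features x samples, with unique non-empty
#'   rownames (feature IDs) and colnames (sample IDs); no negative values, no
#'   missing values (absence must be encoded as 0).
#' @param is_count logical; `NULL` (default) infers `TRUE` iff every value is
#'   integral.
#' @return an object of class `feature_table`: a list with elements `values`,
#'   `is_count`.
#' @export
feature_table <- function(values, is_count = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  ft <- structure(list(values = values, is_count = FALSE),
                  class = "feature_table")
  if (is.null(is_count)) {
    is_count <- all(values == round(values))
  }
  ft$is_count <- isTRUE(is_count)
  validate_feature_table(ft)
  ft
}

validate_feature_table <- function(ft) {
  v <- ft$values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    stop("feature table must have feature IDs (rownames) and sample IDs (colnames)")
  if (anyDuplicated(rownames(v)))
    stop("duplicate feature IDs: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (anyNA(v))
    stop("feature table contains missing values; encode absence as 0")
  if (any(v < 0)) {
    idx <- which(v < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative value for feature '%s' in sample '%s'",
                 rownames(v)[idx[1L]], colnames(v)[idx[2L]]))
  }
  invisible(ft)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<%s> %d features x %d samples (%s)\n",
              class(x)[1L], nrow(x$values), ncol(x$values),
              if (x$is_count) "counts" else "continuous"))
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_table
#' @export
sample_ids <- function(x) colnames(x$values)

# subset (and reorder) a feature table by feature and/or sample IDs or indices
subset_table <- function(x, features = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  out <- x
  out$values <- v
  if (inherits(x, "normalized_table") && !is.null(samples)) {
    out$depths <- x$depths[colnames(v)]
  }
  out
}

#' Per-sample metadata for a longitudinal multi-study design
#'
#' @param df data.frame with columns `sample_id`, `subject_id`, `study_id`,
#'   `timepoint_months`. Timepoint 0 is the pre-surgery baseline; post-surgery
#'   timepoints are positive months.
#' @return a `sample_metadata` object (a validated data.frame).
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "subject_id", "study_id", "timepoint_months")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  df$sample_id <- as.character(df$sample_id)
  df$subject_id <- as.character(df$subject_id)
  df$study_id <- as.character(df$study_id)
  df$timepoint_months <- as.numeric(df$timepoint_months)
  class(df) <- c("sample_metadata", "data.frame")
  validate_sample_metadata(df)
  df
}

validate_sample_metadata <- function(md) {
  if (anyNA(md$timepoint_months))
    stop("non-numeric timepoint in metadata")
  if (any(md$timepoint_months < 0))
    stop("negative timepoint for sample(s): ",
         paste(md$sample_id[md$timepoint_months < 0], collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  studies_per_subject <- tapply(md$study_id, md$subject_id,
                                function(s) length(unique(s)))
  bad <- names(studies_per_subject)[studies_per_subject > 1L]
  if (length(bad))
    stop("subject(s) appear in more than one study: ",
         paste(bad, collapse = ", "))
  key <- paste(md$subject_id, md$timepoint_months, sep = "\r")
  if (anyDuplicated(key)) {
    d <- md[duplicated(key), , drop = FALSE]
    stop(sprintf("more than one sample for subject '%s' at timepoint %s",
                 d$subject_id[1L], d$timepoint_months[1L]))
  }
  invisible(md)
}

#' Align a feature table and sample metadata on their shared samples
#'
#' Restricts both objects to the intersection of their sample IDs, in the
#' same order. Dropped IDs are reported via a warning; an empty intersection
#' is an error.
#'
#' @param table a [feature_table()] (or normalized table).
#' @param meta a [sample_metadata()].
#' @return list with elements `table` and `meta`.
#' @export
align_samples <- function(table, meta) {
  ids_t <- sample_ids(table)
  ids_m <- meta$sample_id
  shared <- intersect(ids_t, ids_m)
  if (!length(shared))
    stop("feature table and metadata share no sample IDs")
  dropped <- c(setdiff(ids_t, shared), setdiff(ids_m, shared))
  if (length(dropped))
    warning(sprintf("dropped %d sample(s) absent from one side: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  table <- subset_table(table, samples = shared)
  meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(table = table, meta = meta)
}
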