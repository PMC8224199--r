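#' Enumerate between- and within-study comparison pairs
#'
#' Given each study's set of post-surgery timepoints, lists every pairwise
#' comparison of "timepoint-vs-baseline" contrasts: all cross-study
#' combinations of timepoints (`kind = "between"`) and all unordered pairs of
#' distinct timepoints inside a study (`kind = "within"`). Ordering is
#' deterministic: studies lexicographic, timepoints ascending.
#'
#' @param timepoint_map named list, study ID -> numeric vector of
#'   post-surgery months (all > 0).
#' @return data.frame with columns `study_a`, `timepoint_a`, `study_b`,
#'   `timepoint_b`, `kind`.
#' @export
enumerate_pairs <- function(timepoint_map) {
  if (!length(timepoint_map) || is.null(names(timepoint_map)))
    stop("timepoint_map must be a non-empty named list")
  if (any(vapply(timepoint_map, length, 1L) == 0L))
    stop("every study needs >= 1 post-surgery timepoint")
  if (any(unlist(timepoint_map) <= 0))
    stop("comparison timepoints must be post-surgical (> 0)")
  studies <- sort(names(timepoint_map))
  tmap <- lapply(timepoint_map[studies], function(t) sort(unique(t)))

  rows <- list()
  for (i in seq_along(studies)) {
    # within-study: unordered pairs of distinct timepoints
    ti <- tmap[[i]]
    if (length(ti) >= 2L) {
      cmb <- utils::combn(ti, 2L)
      rows[[length(rows) + 1L]] <-
        data.frame(study_a = studies[i], timepoint_a = cmb[1L, ],
                   study_b = studies[i], timepoint_b = cmb[2L, ],
                   kind = "within", stringsAsFactors = FALSE)
    }
    # between-study: full cross of timepoints for each study pair
    if (i < length(studies)) {
      for (j in (i + 1L):length(studies)) {
        g <- expand.grid(timepoint_a = ti, timepoint_b = tmap[[j]],
                         KEEP.OUT.ATTRS = FALSE)
        rows[[length(rows) + 1L]] <-
          data.frame(study_a = studies[i], timepoint_a = g$timepoint_a,
                     study_b = studies[j], timepoint_b = g$timepoint_b,
                     kind = "between", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(study_a = character(0), timepoint_a = numeric(0),
                      study_b = character(0), timepoint_b = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$study_a, out$timepoint_a, out$study_b, out$timepoint_b), ]
  rownames(out) <- NULL
  out
}

#' Correlate two signatures over their shared features
#'
#' The concordance statistic: Spearman rank correlation (average ranks for
#' ties) of signed log10 p-values between two "timepoint-vs-baseline"
#' contrasts, restricted to features with non-missing statistics in both
#' signatures. The two-sided p-value uses the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} with n-2 df throughout. Pairs with
#' fewer than 3 shared features are flagged (`rho = NA`).
#'
#' @param sig_a,sig_b `signature_table`s (from [signature_scan()]).
#' @param pair one row of [enumerate_pairs()] output (or an equivalent list
#'   with `study_a`, `timepoint_a`, `study_b`, `timepoint_b`, `kind`).
#' @return one-row data.frame: `study_a`, `timepoint_a`, `study_b`,
#'   `timepoint_b`, `kind`, `n_shared`, `rho`, `p`.
#' @export
correlate_pair <- function(sig_a, sig_b, pair) {
  pick <- function(sig, study, tp) {
    r <- sig[sig$study_id == study & sig$timepoint_months == tp &
               !is.na(sig$signed_log10p), c("feature_id", "signed_log10p")]
    if (!nrow(r))
      stop(sprintf("signature has no rows for study '%s' timepoint %s",
                   study, tp))
    r
  }
  a <- pick(sig_a, pair$study_a, pair$timepoint_a)
  b <- pick(sig_b, pair$study_b, pair$timepoint_b)
  shared <- intersect(a$feature_id, b$feature_id)
  out <- data.frame(study_a = pair$study_a, timepoint_a = pair$timepoint_a,
                    study_b = pair$study_b, timepoint_b = pair$timepoint_b,
                    kind = pair$kind, n_shared = length(shared),
                    rho = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  if (length(shared) < 3L) return(out)
  sa <- a$signed_log10p[match(shared, a$feature_id)]
  sb <- b$signed_log10p[match(shared, b$feature_id)]
  rho <- stats::cor(sa, sb, method = "spearman")
  n <- length(shared)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  out$rho <- rho
  out$p <- p
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return q-values in input order (empty input gives empty output).
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration of the rank-sum null when both samples have at most 20
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction. Used to contrast between-
#' versus within-study correlation coefficients.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `statistic` (the Mann-Whitney U of `x`) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= 20L && length(y) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1  # all observations tied: zero-variance null
  list(statistic = unname(wt$statistic), p = min(p, 1))
}

#' Summarize concordance results by kind
#'
#' Mean and sd of Spearman rho separately for between- and within-study
#' pairs, the Wilcoxon rank-sum p contrasting the two sets of coefficients,
#' and the number of pairs significant at q < 0.05. The spread is the sd of
#' the coefficients (not a standard error).
#'
#' @param results data.frame of [correlate_pair()] rows, with a `q` column
#'   (added via [bh_adjust()] across all pairs); rows with missing `rho` are
#'   ignored.
#' @return list: `by_kind` (data.frame: kind, n, mean_rho, sd_rho),
#'   `contrast_p`, `n_significant` (q < 0.05), `n_pairs`.
#' @export
concordance_summary <- function(results) {
  ok <- results[!is.na(results$rho), , drop = FALSE]
  kinds <- c("between", "within")
  by_kind <- do.call(rbind, lapply(kinds, function(k) {
    r <- ok$rho[ok$kind == k]
    data.frame(kind = k, n = length(r),
               mean_rho = if (length(r)) mean(r) else NA_real_,
               sd_rho = if (length(r) > 1L) stats::sd(r) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  contrast_p <- NA_real_
  rb <- ok$rho[ok$kind == "between"]; rw <- ok$rho[ok$kind == "within"]
  if (length(rb) && length(rw)) {
    contrast_p <- wilcoxon_rank_sum(rw, rb)$p
  } else {
    warning("a comparison kind is absent; between-vs-within contrast omitted")
  }
  n_sig <- if ("q" %in% names(ok)) sum(ok$q < 0.05, na.rm = TRUE) else NA_integer_
  list(by_kind = by_kind, contrast_p = contrast_p,
       n_significant = n_sig, n_pairs = nrow(ok))
}

#' Hierarchically cluster a signed log10 p-value matrix
#'
#' Agglomerative clustering (Euclidean distance, complete linkage) of the
#' feature x (study, timepoint) signature matrix, for heatmap display of
#' which features move consistently across cohorts. Missing entries are
#' imputed as 0 (no evidence) for clustering only. Ties are broken
#' deterministically by input order (single fixed dissimilarity ordering).
#'
#' @param mat numeric matrix, features as rows, one column per
#'   (study, timepoint) contrast.
#' @return list with `row_order`, `row_heights`, `col_order`, `col_heights`,
#'   and the underlying `hclust` objects `row_hclust`, `col_hclust` (NULL
#'   when that dimension has < 2 elements).
#' @export
cluster_signature <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) < 2L)
    stop("need a matrix with >= 2 rows")
  mat[is.na(mat)] <- 0
  hc_row <- stats::hclust(stats::dist(mat), method = "complete")
  hc_col <- if (ncol(mat) >= 2L)
    stats::hclust(stats::dist(t(mat)), method = "complete") else NULL
  list(row_order = hc_row$order, row_heights = hc_row$height,
       col_order = if (is.null(hc_col)) seq_len(ncol(mat)) else hc_col$order,
       col_heights = if (is.null(hc_col)) numeric(0) else hc_col$height,
       row_hclust = hc_row, col_hclust = hc_col)
}
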