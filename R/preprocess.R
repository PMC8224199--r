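#' Depth-normalize a count table
#'
#' Corrects for unequal library size with the log10 transform
#' \deqn{\log_{10}\!\left(\frac{c_{fj}}{N_j}\,\bar N + 1\right)}
#' where \eqn{c_{fj}} is the raw count of feature f in sample j, \eqn{N_j}
#' the sample's total count, and \eqn{\bar N} the mean total count over the
#' samples of this table. The mean depth is computed within the table, i.e.
#' per study when studies are processed separately. Zero counts map to 0
#' exactly; with equal depths the transform reduces to `log10(count + 1)`.
#'
#' @param table a count [feature_table()].
#' @return a `normalized_table` (subclass of `feature_table`,
#'   `is_count = FALSE`) with attributes `depths` (per-sample N_j) and
#'   `mean_depth`.
#' @export
normalize_depth <- function(table) {
  validate_feature_table(table)
  if (!table$is_count)
    stop("normalize_depth expects a raw count table")
  N <- colSums(table$values)
  if (any(N == 0))
    stop("zero-depth sample(s): ",
         paste(colnames(table$values)[N == 0], collapse = ", "))
  Nbar <- mean(N)
  vals <- log10(sweep(table$values, 2L, N, "/") * Nbar + 1)
  structure(list(values = vals, is_count = FALSE,
                 depths = N, mean_depth = Nbar),
            class = c("normalized_table", "feature_table"))
}

#' Remove low-prevalence features
#'
#' Drops features that are present (value > 0) in strictly fewer than
#' `threshold` of the samples; a feature present in exactly the threshold
#' fraction is retained. Intended to be applied per study.
#'
#' @param table a [feature_table()] or `normalized_table`.
#' @param threshold prevalence fraction in `[0, 1]`; default 0.10.
#' @return the same type of table, restricted to retained features.
#' @export
prevalence_filter <- function(table, threshold = 0.10) {
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be in [0, 1]")
  prev <- rowMeans(table$values > 0)
  keep <- prev >= threshold
  if (!any(keep))
    stop("prevalence filter removed every feature")
  subset_table(table, features = which(keep))
}

#' Convert counts to relative abundances
#'
#' @param table a [feature_table()] with positive column sums.
#' @return a `feature_table` with `is_count = FALSE` whose columns sum to 1.
#' @export
relative_abundance <- function(table) {
  N <- colSums(table$values)
  if (any(N == 0))
    stop("zero-depth sample(s): ",
         paste(colnames(table$values)[N == 0], collapse = ", "))
  feature_table(sweep(table$values, 2L, N, "/"), is_count = FALSE)
}

#' Machine-learning feature transform (log-pseudocount z-scores)
#'
#' The classifier input transform: relative abundances are log10-transformed
#' after adding a pseudocount, then standardized feature-wise as z-scores.
#' In fit mode, zero-variance features are removed and the per-feature means
#' and sds are estimated on this table and returned as a frozen
#' standardization. In apply mode, a previously frozen standardization is
#' applied unchanged; features absent from the new table are imputed as
#' relative abundance 0 before the transform, and nothing is re-estimated.
#'
#' @param rel a [feature_table()] of relative abundances (values in `[0,1]`).
#' @param frozen `NULL` (fit mode) or a frozen standardization from a
#'   previous fit (apply mode).
#' @param pseudocount added before the log; default `1e-5`.
#' @return list with `x` (samples x features z-score matrix) and `frozen`
#'   (list: `features`, `mean`, `sd`, `pseudocount`).
#' @export
ml_transform <- function(rel, frozen = NULL, pseudocount = 1e-5) {
  v <- rel$values
  if (any(v < 0) || any(v > 1 + 1e-8))
    stop("ml_transform expects relative abundances in [0, 1]")
  if (is.null(frozen)) {
    lg <- t(log10(v + pseudocount))           # samples x features
    s <- apply(lg, 2L, stats::sd)
    keep <- !is.na(s) & s > 0
    if (!any(keep)) stop("all features have zero variance")
    lg <- lg[, keep, drop = FALSE]
    m <- colMeans(lg)
    s <- s[keep]
    x <- sweep(sweep(lg, 2L, m, "-"), 2L, s, "/")
    frozen <- list(features = colnames(lg), mean = m, sd = s,
                   pseudocount = pseudocount)
  } else {
    present <- intersect(frozen$features, rownames(v))
    if (!length(present))
      stop("none of the frozen standardization's features are present")
    full <- matrix(0, length(frozen$features), ncol(v),
                   dimnames = list(frozen$features, colnames(v)))
    full[present, ] <- v[present, , drop = FALSE]
    lg <- t(log10(full + frozen$pseudocount))
    x <- sweep(sweep(lg, 2L, frozen$mean, "-"), 2L, frozen$sd, "/")
  }
  list(x = x, frozen = frozen)
}
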