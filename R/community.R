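#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(i,j) = 1 - 2\sum_f \min(x_{fi},x_{fj}) / (\sum_f x_{fi} +
#' \sum_f x_{fj})}, computed between samples (columns). Two all-zero samples
#' get distance 0 by convention; an all-zero versus a non-zero sample gives 1.
#'
#' @param table a [feature_table()]/`normalized_table`, or a plain
#'   non-negative features x samples matrix.
#' @return symmetric sample x sample distance matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  v <- if (inherits(table, "feature_table")) table$values else table
  if (any(v < 0)) stop("Bray-Curtis requires non-negative values")
  if (ncol(v) < 2L) stop("need >= 2 samples")
  zero <- colSums(v) == 0
  # vegdist warns on all-zero samples and yields NaN for double-zero pairs;
  # the convention here is d = 0 for two empty samples
  d <- if (any(zero))
    suppressWarnings(as.matrix(vegan::vegdist(t(v), method = "bray")))
  else as.matrix(vegan::vegdist(t(v), method = "bray"))
  if (any(zero)) d[zero, zero] <- 0
  diag(d) <- 0
  dimnames(d) <- list(colnames(v), colnames(v))
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centering of \eqn{-\tfrac12 d^2} followed by
#' eigendecomposition. Axes are ordered by decreasing eigenvalue; axes with
#' non-positive eigenvalues carry no coordinates (negative eigenvalues are
#' still reported), and the proportion explained is computed over the
#' positive eigenvalues.
#'
#' @param dist_matrix symmetric distance matrix.
#' @return list: `coordinates` (samples x axes), `eigenvalues` (all n),
#'   `proportion_explained` (per positive axis).
#' @export
pcoa <- function(dist_matrix) {
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 samples")
  G <- gower_center(d)
  eig <- eigen(G, symmetric = TRUE)
  ev <- eig$values
  pos <- which(ev > max(ev) * 1e-12 & ev > 0)
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(ev[pos]), length(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("axis", seq_along(pos))
  list(coordinates = coords, eigenvalues = ev,
       proportion_explained = ev[pos] / sum(ev[pos]))
}

gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm_ <- rowMeans(a); gm <- mean(a)
  sweep(sweep(a, 1L, rm_, "-"), 2L, rm_, "-") + gm
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_f p_f \ln p_f} over the sample's relative abundances
#' (natural log, zero entries omitted); a joint measure of richness and
#' evenness.
#'
#' @param counts non-negative vector with at least one positive entry.
#' @return Shannon index (single number).
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero sample has no diversity")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' PERMANOVA with sequential (Type I) sums of squares
#'
#' Partitions a distance matrix by the design `study * timepoint` (or any
#' subset/order of `study`, `timepoint`, `study:timepoint`) via the
#' Gower-centered inner-product matrix, with timepoint coded pre (month 0)
#' versus post (any positive month), pooling all post-surgery months. Terms
#' are fitted sequentially in the given order; each term's pseudo-F is
#' referenced to a free permutation null of the sample labels (the
#' repeated-measures structure is deliberately not restricted; see package
#' vignette). The reported p uses the add-one rule
#' \eqn{p = (1 + \#\{F^\ast \ge F\}) / (1 + n_{perm})}, so p is never 0.
#'
#' With `exhaustive = TRUE` all `n!` label permutations are enumerated
#' (feasible for n <= 7) and `p = \#\{F^\ast \ge F\} / n!` (the identity
#' permutation is included, so again p > 0).
#'
#' @param dist_matrix symmetric distance matrix (e.g. [bray_curtis()]).
#' @param meta [sample_metadata()] rows aligned to the distance matrix, or a
#'   data.frame of factors with columns named in `terms`.
#' @param terms character vector drawn from `"study"`, `"timepoint"`,
#'   `"study:timepoint"` (or column names of a plain `meta` data.frame,
#'   with `:` for interactions), in fitting order.
#' @param n_perm number of random permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all permutations instead (n <= 7).
#' @return a `permanova_result` data.frame: one row per term plus `Residual`
#'   and `Total`, with columns `term`, `df`, `SS`, `F`, `R2`, `p`;
#'   attributes `n_perm` and `seed`.
#' @export
permanova <- function(dist_matrix, meta,
                      terms = c("study", "timepoint", "study:timepoint"),
                      n_perm = 999, seed = NULL, exhaustive = FALSE) {
  d <- as.matrix(dist_matrix)
  n <- nrow(d)
  design <- permanova_design(meta, d)
  for (tm in terms) {
    for (v in strsplit(tm, ":", fixed = TRUE)[[1L]]) {
      if (!v %in% names(design)) stop("unknown design variable: ", v)
      if (nlevels(droplevels(design[[v]])) < 2L)
        stop(sprintf("term '%s' is constant across samples", tm))
    }
  }

  G <- gower_center(d)
  ss_total <- sum(diag(G))

  # sequential projection increments H_k - H_{k-1}
  X <- matrix(1, n, 1L)
  dH <- vector("list", length(terms))
  df_terms <- integer(length(terms))
  H_prev <- hat_matrix(X)
  for (k in seq_along(terms)) {
    mm <- stats::model.matrix(stats::as.formula(paste("~", terms[k])), design)
    X <- cbind(X, mm[, -1L, drop = FALSE])
    H_k <- hat_matrix(X)
    dH[[k]] <- H_k - H_prev
    df_terms[k] <- qr(X)$rank - qr(H_prev)$rank
    H_prev <- H_k
  }
  df_terms <- pmax(df_terms, 0L)
  H_full <- H_prev
  df_res <- n - qr(H_full)$rank
  if (df_res <= 0) stop("saturated design: no residual degrees of freedom")

  f_stats <- function(Gp) {
    ss <- vapply(dH, function(A) sum(A * Gp), 0)
    ss_res <- sum(diag(Gp)) - sum(ss)
    (ss / df_terms) / (ss_res / df_res)
  }
  ss_obs <- vapply(dH, function(A) sum(A * G), 0)
  ss_res <- ss_total - sum(ss_obs)
  f_obs <- (ss_obs / df_terms) / (ss_res / df_res)

  if (exhaustive) {
    if (n > 7L) stop("exhaustive enumeration limited to n <= 7 samples")
    perms <- all_permutations(n)
    f_perm <- vapply(perms, function(p) f_stats(G[p, p]), numeric(length(terms)))
    f_perm <- matrix(f_perm, nrow = length(terms))
    p_vals <- rowMeans(f_perm >= f_obs - 1e-12)
    n_perm_used <- length(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    ge <- integer(length(terms))
    for (b in seq_len(n_perm)) {
      p <- sample.int(n)
      ge <- ge + (f_stats(G[p, p]) >= f_obs - 1e-12)
    }
    p_vals <- (1 + ge) / (1 + n_perm)
    n_perm_used <- n_perm
  }

  out <- data.frame(term = c(terms, "Residual", "Total"),
                    df = c(df_terms, df_res, n - 1L),
                    SS = c(ss_obs, ss_res, ss_total),
                    F = c(f_obs, NA_real_, NA_real_),
                    R2 = c(ss_obs, ss_res, ss_total) / ss_total,
                    p = c(p_vals, NA_real_, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm_used
  attr(out, "seed") <- seed
  class(out) <- c("permanova_result", "data.frame")
  out
}

permanova_design <- function(meta, d) {
  if (inherits(meta, "sample_metadata")) {
    if (!is.null(rownames(d)) &&
        !identical(rownames(d), meta$sample_id) &&
        all(rownames(d) %in% meta$sample_id))
      meta <- meta[match(rownames(d), meta$sample_id), , drop = FALSE]
    if (nrow(meta) != nrow(d))
      stop("metadata rows do not match the distance matrix")
    data.frame(study = factor(meta$study_id),
               timepoint = factor(ifelse(meta$timepoint_months > 0,
                                         "post", "pre"),
                                  levels = c("pre", "post")))
  } else {
    if (nrow(meta) != nrow(d))
      stop("design rows do not match the distance matrix")
    as.data.frame(lapply(meta, factor))
  }
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in 0L:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos)
    }
  }
  out
}
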