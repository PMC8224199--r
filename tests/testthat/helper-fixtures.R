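# Small in-code fixtures shared across test files.

# a tiny deterministic count table
tiny_table <- function() {
  m <- matrix(c(5L, 0L, 3L,
                2L, 7L, 1L,
                0L, 4L, 6L), nrow = 3, byrow = TRUE,
              dimnames = list(c("fA", "fB", "fC"), c("s1", "s2", "s3")))
  feature_table(m)
}

tiny_meta <- function() {
  sample_metadata(data.frame(
    sample_id = c("s1", "s2", "s3"),
    subject_id = c("P1", "P1", "P2"),
    study_id = "A",
    timepoint_months = c(0, 1, 0)))
}

# balanced paired design: n subjects, each at months 0 and 1
paired_meta <- function(n) {
  sample_metadata(data.frame(
    sample_id = paste0("s", seq_len(2 * n)),
    subject_id = rep(sprintf("P%02d", seq_len(n)), each = 2),
    study_id = "A",
    timepoint_months = rep(c(0, 1), n)))
}

# small fast synthetic config for unit tests
small_config <- function(...) {
  args <- list(n_studies = 2, n_subjects_per_study = c(10, 8),
               n_features = 40,
               timepoints_per_study = list(c(0, 1, 6), c(0, 1, 6)),
               retention_prob = 1, pi_signal = 0.25, tau_effect = 1.5,
               rho_between = 1, sigma_study = 1, sigma_subject = 0.5,
               sigma_noise = 0.6, seed = 42)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# independent brute-force oracles ------------------------------------------

# BH step-up, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact two-sided Wilcoxon rank-sum p by enumerating all C(n, nx) rank splits
wilcox_oracle <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  splits <- utils::combn(n, nx)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# pairwise-comparison AUROC
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Bray-Curtis from the min formula, one pair at a time
bray_oracle <- function(x, y) {
  if (sum(x) + sum(y) == 0) return(0)
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# single-factor PERMANOVA F and exhaustive p from group distance sums
permanova_oracle <- function(d, groups) {
  n <- nrow(d)
  ss_tot <- sum(d[upper.tri(d)]^2) / n
  ss_within <- function(g) {
    sum(vapply(unique(g), function(lev) {
      idx <- which(g == lev)
      if (length(idx) < 2) return(0)
      dd <- d[idx, idx]
      sum(dd[upper.tri(dd)]^2) / length(idx)
    }, 0))
  }
  a <- length(unique(groups))
  f_of <- function(g) {
    ssw <- ss_within(g)
    ((ss_tot - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_of(groups)
  perms <- rygbsig:::all_permutations(n)
  f_all <- vapply(perms, function(p) f_of(groups[p]), 0)
  list(F = f_obs, p = mean(f_all >= f_obs - 1e-12),
       R2 = (ss_tot - ss_within(groups)) / ss_tot)
}
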