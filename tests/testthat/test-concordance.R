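test_that("pair enumeration covers crosses and within-study combinations", {
  # two studies, one timepoint each
  p <- enumerate_pairs(list(A = 6, B = 12))
  expect_equal(nrow(p), 1)
  expect_equal(p$kind, "between")

  # one study, one timepoint: nothing to compare
  expect_equal(nrow(enumerate_pairs(list(A = 6))), 0)

  # within pairs are unordered and timepoints ascend
  p3 <- enumerate_pairs(list(A = c(3, 12, 24)))
  expect_equal(nrow(p3), 3)
  expect_true(all(p3$timepoint_a < p3$timepoint_b))

  expect_error(enumerate_pairs(list()), "non-empty")
  expect_error(enumerate_pairs(list(A = c(0, 6))), "post-surgical")
})

make_sig <- function(study, tp, features, s) {
  structure(data.frame(study_id = study, feature_id = features,
                       timepoint_months = tp, beta = sign(s), se = 1,
                       p = 10^-abs(s), signed_log10p = s,
                       n_subjects = 10, converged = TRUE,
                       stringsAsFactors = FALSE),
            class = c("signature_table", "data.frame"))
}

test_that("pair correlation is rank-invariant, signed, and symmetric", {
  feats <- paste0("f", 1:10)
  s_a <- seq(-4, 4, length.out = 10)
  pair <- list(study_a = "A", timepoint_a = 1, study_b = "B",
               timepoint_b = 3, kind = "between")
  sig_a <- make_sig("A", 1, feats, s_a)

  # strictly increasing transform: rho = 1
  sig_b <- make_sig("B", 3, feats, tanh(s_a) + s_a^3 * 1e-3)
  expect_equal(correlate_pair(sig_a, sig_b, pair)$rho, 1)

  # negation: rho = -1
  sig_c <- make_sig("B", 3, feats, -s_a)
  expect_equal(correlate_pair(sig_a, sig_c, pair)$rho, -1)

  # intersection by feature ID
  sig_d <- make_sig("B", 3, paste0("f", 3:7), rnorm(5))
  sig_e <- make_sig("A", 1, paste0("f", 1:5), rnorm(5))
  res <- correlate_pair(sig_e, sig_d, pair)
  expect_equal(res$n_shared, 3)

  # symmetry of rho and p under swap
  set.seed(7)
  sig_f <- make_sig("B", 3, feats, rnorm(10))
  swap <- list(study_a = "B", timepoint_a = 3, study_b = "A",
               timepoint_b = 1, kind = "between")
  r1 <- correlate_pair(sig_a, sig_f, pair)
  r2 <- correlate_pair(sig_f, sig_a, swap)
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p, r2$p)

  # under 3 shared features: flagged, not errored
  sig_g <- make_sig("B", 3, paste0("f", 1:2), c(1, 2))
  expect_true(is.na(correlate_pair(sig_a, sig_g, pair)$rho))
})

test_that("spearman p uses the t approximation", {
  feats <- paste0("f", 1:12)
  set.seed(9)
  sa <- rnorm(12); sb <- 0.6 * sa + rnorm(12, 0, 0.6)
  pair <- list(study_a = "A", timepoint_a = 1, study_b = "B",
               timepoint_b = 1, kind = "between")
  res <- correlate_pair(make_sig("A", 1, feats, sa),
                        make_sig("B", 1, feats, sb), pair)
  rho <- cor(sa, sb, method = "spearman")
  tv <- rho * sqrt((12 - 2) / (1 - rho^2))
  expect_equal(res$p, 2 * pt(-abs(tv), 10), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.8)), c(0.015, 0.06, 0.8))
  expect_equal(bh_adjust(0.32), 0.32)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")

  # oracle equivalence + dominance on random vectors
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # monotone in the input ranks: sorting p sorts q
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("wilcoxon rank-sum switches branches as specified", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)

  # identical multisets hit the tie-corrected approximation with p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(wilcoxon_rank_sum(rep(0.5, 3), rep(0.5, 3))$p, 1)

  # exact branch equals brute-force enumeration over a fixed random grid
  set.seed(15)
  for (i in 1:15) {
    x <- sample(seq(0.05, 3, by = 0.05), 3)
    y <- setdiff(sample(seq(0.05, 3, by = 0.05), 4), x)[1:3]
    expect_equal(wilcoxon_rank_sum(x, y)$p, wilcox_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("concordance summary contrasts between and within pairs", {
  res <- data.frame(kind = c("within", "within", "between", "between"),
                    rho = c(0.9, 0.8, 0.1, 0.2),
                    q = c(0.01, 0.01, 0.2, 0.03))
  s <- concordance_summary(res)
  expect_equal(s$by_kind$mean_rho[s$by_kind$kind == "within"], 0.85)
  expect_equal(s$by_kind$mean_rho[s$by_kind$kind == "between"], 0.15)
  expect_equal(s$n_significant, 3)

  # all coefficients equal in both kinds: sd 0, contrast p 1
  res2 <- data.frame(kind = rep(c("within", "between"), each = 3),
                     rho = rep(0.5, 6), q = rep(0.5, 6))
  s2 <- concordance_summary(res2)
  expect_equal(s2$by_kind$sd_rho, c(0, 0))
  expect_equal(s2$contrast_p, 1)

  expect_warning(concordance_summary(
    data.frame(kind = "within", rho = 0.5, q = 0.5)), "omitted")
})

test_that("signature clustering is deterministic with sane heights", {
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  cl <- cluster_signature(m)
  expect_equal(cl$row_heights[1], 0)  # identical rows merge at height 0

  m2 <- rbind(r1 = c(0, 0), r2 = c(0, 3), r3 = c(4, 0))
  cl2 <- cluster_signature(m2)
  expect_equal(min(cl2$row_heights), 3)  # closest pair at Euclidean distance 3
  expect_equal(max(cl2$row_heights), 5)  # complete linkage: max(4, 5)

  z <- matrix(0, 3, 2, dimnames = list(c("x", "y", "z"), NULL))
  expect_true(all(cluster_signature(z)$row_heights == 0))

  # missing entries impute as zero: same result as explicit zeros
  m3 <- m2; m3[1, 2] <- NA
  m4 <- m2; m4[1, 2] <- 0
  expect_equal(cluster_signature(m3)$row_heights,
               cluster_signature(m4)$row_heights)
})
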