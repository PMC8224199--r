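test_that("bray-curtis matches the min formula and its conventions", {
  m <- cbind(s1 = c(1, 0), s2 = c(1, 1), s3 = c(0, 2))
  rownames(m) <- c("f1", "f2")
  d <- bray_curtis(m)
  expect_equal(d["s1", "s2"], 1 / 3)   # 1 - 2*1/3
  expect_equal(d["s1", "s1"], 0)
  expect_equal(d["s1", "s3"], 1)       # disjoint supports

  # identical samples
  expect_equal(bray_curtis(cbind(a = c(2, 3), b = c(2, 3)))["a", "b"], 0)

  # all-zero conventions: zero/zero -> 0, zero/nonzero -> 1
  z <- cbind(z1 = c(0, 0), z2 = c(0, 0), x = c(1, 2))
  dz <- bray_curtis(z)
  expect_equal(dz["z1", "z2"], 0)
  expect_equal(dz["z1", "x"], 1)

  # oracle equivalence on random tables + per-pair scale invariance
  set.seed(21)
  v <- matrix(rpois(6 * 8, 3), 6, 8,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:8)))
  dd <- bray_curtis(v)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(dd[i, j], bray_oracle(v[, i], v[, j]), tolerance = 1e-12)
  expect_equal(bray_curtis(v * 7), dd, tolerance = 1e-12)
  expect_equal(dd, t(dd))
  expect_true(all(dd >= 0 & dd <= 1))
})

test_that("pcoa reproduces simple geometries", {
  # two samples at distance d: coordinates +/- d/2
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(d)
  expect_equal(sort(unname(ord$coordinates[, 1])), c(-1.5, 1.5))

  # three mutually equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  ev <- pcoa(d3)$eigenvalues
  pos <- ev[ev > 1e-12]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  # Euclidean input distances are reproduced exactly
  set.seed(22)
  x <- matrix(rnorm(5 * 3), 5, 3)
  de <- as.matrix(dist(x))
  ord2 <- pcoa(de)
  expect_equal(as.matrix(dist(ord2$coordinates)), de,
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(sum(ord2$proportion_explained), 1)
})

test_that("shannon diversity matches the entropy formula", {
  expect_equal(shannon(rep(5, 4)), log(4))
  expect_equal(shannon(c(0, 10, 0)), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannon(p), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(shannon(c(2, 1, 1, 0)), -sum(p * log(p)), tolerance = 1e-12)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(shannon(c(-1, 2)), "non-negative")
})

test_that("permanova partitions a planted two-group geometry exactly", {
  # 1-D coordinates {0,0,1,1}: between-group separation is everything
  x <- matrix(c(0, 0, 1, 1), 4, 1)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  meta <- data.frame(grp = c("A", "A", "B", "B"))
  res <- permanova(d, meta, terms = "grp", exhaustive = TRUE)
  expect_equal(res$R2[res$term == "grp"], 1, tolerance = 1e-10)
  expect_equal(res$p[res$term == "grp"], 1 / 3, tolerance = 1e-12)
  expect_equal(res$SS[res$term == "Total"], 1, tolerance = 1e-10)
})

test_that("permanova agrees with the brute-force oracle and adonis2", {
  set.seed(23)
  v <- matrix(rpois(5 * 6, 4) + 1, 5, 6,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  d <- bray_curtis(v)
  meta <- data.frame(grp = rep(c("A", "B"), each = 3))
  res <- permanova(d, meta, terms = "grp", exhaustive = TRUE)
  orac <- permanova_oracle(d, meta$grp)
  expect_equal(res$F[1], orac$F, tolerance = 1e-9)
  expect_equal(res$p[1], orac$p, tolerance = 1e-12)
  expect_equal(res$R2[1], orac$R2, tolerance = 1e-9)

  # sequential two-factor partition matches vegan::adonis2 (SS, F, R2)
  set.seed(24)
  v2 <- matrix(rpois(8 * 12, 4) + 1, 8, 12,
               dimnames = list(paste0("f", 1:8), paste0("s", 1:12)))
  d2 <- bray_curtis(v2)
  meta2 <- data.frame(study = rep(c("A", "B"), each = 6),
                      timepoint = rep(c("pre", "post"), 6))
  res2 <- permanova(d2, meta2, terms = c("study", "timepoint",
                                         "study:timepoint"),
                    n_perm = 29, seed = 1)
  ad <- vegan::adonis2(as.dist(d2) ~ study * timepoint, data = meta2,
                       permutations = 29, by = "terms")
  expect_equal(res2$SS[1:3], ad$SumOfSqs[1:3], tolerance = 1e-9)
  expect_equal(res2$F[1:3], ad$F[1:3], tolerance = 1e-9)
  expect_equal(res2$R2[1:3], ad$R2[1:3], tolerance = 1e-9)

  # SS decomposition and p bounds
  expect_equal(sum(res2$SS[1:4]), res2$SS[res2$term == "Total"],
               tolerance = 1e-9)
  expect_true(all(res2$p[1:3] >= 1 / 30 & res2$p[1:3] <= 1))

  # Monte-Carlo p within binomial error of the exhaustive p
  res_mc <- permanova(d, meta, terms = "grp", n_perm = 999, seed = 4)
  expect_lt(abs(res_mc$p[1] - orac$p), 3 * sqrt(orac$p * (1 - orac$p) / 999) +
              1 / 999)

  expect_error(permanova(d, data.frame(grp = rep("A", 6)), terms = "grp"),
               "constant")
})
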