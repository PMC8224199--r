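test_that("auroc equals the pairwise-comparison probability", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(auroc(c(0.1, 0.9), c(1, 1)), "both classes")

  # brute-force oracle on random inputs with ties, n <= 12
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    labels <- sample(c(0, 1, sample(0:1, n - 2, replace = TRUE)))
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(auroc(scores, labels), auroc_oracle(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("averaged ensemble scores are what AUROC is computed on", {
  # a case where auroc(mean score) differs from mean(per-model auroc)
  s1 <- c(0.9, 0.6, 0.5, 0.1)
  s2 <- c(0.2, 0.9, 0.3, 0.6)
  y <- c(1, 0, 1, 0)
  avg_then <- auroc((s1 + s2) / 2, y)
  then_avg <- mean(c(auroc(s1, y), auroc(s2, y)))
  expect_false(isTRUE(all.equal(avg_then, then_avg)))
})

make_ml_sim <- function(seed = 51, n_studies = 2, nsub = 14) {
  synthetic_config(n_studies = n_studies, n_subjects_per_study = nsub,
                   n_features = 50,
                   timepoints_per_study = rep(list(c(0, 6)), n_studies),
                   retention_prob = 1, pi_signal = 0.3, tau_effect = 2,
                   rho_between = 1, sigma_study = 1, sigma_subject = 0.5,
                   sigma_noise = 0.4, seed = seed)
}

test_that("cross-validated ensembles separate a strongly planted signal", {
  sim <- simulate_multistudy(make_ml_sim())
  s1 <- sim$studies[[1]]
  ens <- fit_cv_models(s1$table, s1$meta, "lasso", k = 4, repeats = 3,
                       seed = 3)
  expect_length(ens$models, 12)
  expect_gt(ens$within_auroc, 0.9)

  # no subject spans train and test within any repeat
  for (fold in ens$fold_assignments) {
    subj <- sim$studies[[1]]$meta$subject_id
    expect_true(all(tapply(fold, subj, function(f) length(unique(f))) == 1))
  }

  # zero-variance features never enter the feature list
  tb <- s1$table
  tb$values["taxon_001", ] <- 0L
  ens0 <- fit_cv_models(tb, s1$meta, "lasso", k = 4, repeats = 1, seed = 3)
  expect_false("taxon_001" %in% ens0$features)
})

test_that("transfer scoring is invariant to feature order and flips with labels", {
  sim <- simulate_multistudy(make_ml_sim(seed = 52))
  s1 <- sim$studies[[1]]; s2 <- sim$studies[[2]]
  ens <- fit_cv_models(s1$table, s1$meta, "lasso", k = 4, repeats = 2,
                       seed = 9)
  tr <- transfer_predict(ens, s2$table, s2$meta)
  expect_gt(tr$auroc, 0.8)  # same planted effects: transfer succeeds

  # reordering/subsetting external features changes nothing (ID matching)
  perm <- rev(feature_ids(s2$table))
  tab_perm <- feature_table(s2$table$values[perm, ], is_count = TRUE)
  expect_equal(transfer_predict(ens, tab_perm, s2$meta)$auroc, tr$auroc)

  # label inversion mirrors the AUROC
  y <- as.integer(s2$meta$timepoint_months > 0)
  tr_flip <- transfer_predict(ens, s2$table, s2$meta, labels = 1L - y)
  expect_equal(tr_flip$auroc, 1 - tr$auroc, tolerance = 1e-12)

  # per-sample scores are the across-model average
  rel <- relative_abundance(s2$table)
  x <- ml_transform(rel, frozen = ens$frozen)$x
  per_model <- vapply(ens$models,
                      function(m) rygbsig:::score_model(m, "lasso", x),
                      numeric(nrow(x)))
  expect_equal(unname(attr(tr, "scores")), unname(rowMeans(per_model)),
               tolerance = 1e-12)
})

test_that("random forests run through the same interfaces", {
  sim <- simulate_multistudy(make_ml_sim(seed = 53, nsub = 10))
  s1 <- sim$studies[[1]]
  ens <- fit_cv_models(s1$table, s1$meta, "random_forest", k = 3,
                       repeats = 1, seed = 5)
  expect_length(ens$models, 3)
  expect_gt(ens$within_auroc, 0.8)
  tr <- transfer_predict(ens, sim$studies[[2]]$table, sim$studies[[2]]$meta)
  expect_gt(tr$auroc, 0.7)
})

test_that("LOSO on a duplicated study matches its within-study accuracy", {
  sim <- simulate_multistudy(make_ml_sim(seed = 54))
  s1 <- sim$studies[[1]]
  # exact copy with renamed study/subjects/samples
  meta2 <- as.data.frame(s1$meta)
  meta2$study_id <- "COPY"
  meta2$subject_id <- sub("^S1", "COPY", meta2$subject_id)
  meta2$sample_id <- sub("^S1", "COPY", meta2$sample_id)
  v2 <- s1$table$values
  colnames(v2) <- meta2$sample_id
  copy <- list(table = feature_table(v2, is_count = TRUE),
               meta = sample_metadata(meta2))
  res <- loso(list(S1 = s1, COPY = copy), "lasso", k = 4, repeats = 3,
              seed = 6)
  within <- fit_cv_models(s1$table, s1$meta, "lasso", k = 4, repeats = 3,
                          seed = 6)$within_auroc
  expect_true(all(abs(res$auroc - within) <= 0.02))
})
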