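test_that("config validation names the offending field", {
  expect_error(small_config(pi_signal = 1.5), "pi_signal")
  expect_error(small_config(rho_between = -0.1), "rho_between")
  expect_error(small_config(sigma_noise = -1), "sigma_noise")
  expect_error(small_config(n_features = 1), "n_features")
  expect_error(small_config(timepoints_per_study = list(c(1, 6), c(0, 6))),
               "timepoints_per_study")
})

test_that("planted effects respect the between-study correlation contract", {
  # rho_between = 1: identical effects across studies
  eff <- plant_signature(small_config(rho_between = 1))
  expect_equal(eff$delta[1, , ], eff$delta[2, , ])

  # pi_signal = 0: no effects anywhere
  eff0 <- plant_signature(small_config(pi_signal = 0))
  expect_true(all(eff0$delta == 0))
  expect_length(eff0$signal_features, 0)

  # rho_between = 0: empirically independent effects between studies
  cfg <- synthetic_config(n_studies = 2, n_subjects_per_study = 5,
                          n_features = 500,
                          timepoints_per_study = list(c(0, 1), c(0, 1)),
                          pi_signal = 1, tau_effect = 1, rho_between = 0,
                          seed = 2024)
  eff_ind <- plant_signature(cfg)
  r <- cor(eff_ind$delta[1, , 1], eff_ind$delta[2, , 1])
  expect_gt(r, -0.15)
  expect_lt(r, 0.15)

  # non-signal features carry exactly zero effect
  eff <- plant_signature(small_config(pi_signal = 0.25))
  null_feats <- setdiff(dimnames(eff$delta)[[2]], eff$signal_features)
  expect_true(all(eff$delta[, null_feats, ] == 0))
})

test_that("cohort simulation honors the sampling design", {
  cfg <- small_config(retention_prob = 1)
  sim <- simulate_multistudy(cfg)
  md <- sim$studies[[1]]$meta
  # every subject sampled at every study timepoint
  tab <- table(md$subject_id)
  expect_true(all(tab == length(cfg$timepoints_per_study[[1]])))

  cfg0 <- small_config(retention_prob = 0)
  md0 <- simulate_multistudy(cfg0)$studies[[1]]$meta
  expect_true(all(md0$timepoint_months == 0))  # baseline always sampled

  # sample IDs are globally unique and follow study_subject_month
  all_ids <- unlist(lapply(sim$studies, function(s) s$meta$sample_id))
  expect_false(anyDuplicated(all_ids) > 0)
  expect_true(all(grepl("^S[0-9]+_.+_[0-9.]+$", all_ids)))
})

test_that("identical config and seed reproduce bit-identical output", {
  a <- simulate_multistudy(small_config())
  b <- simulate_multistudy(small_config())
  expect_identical(a$studies, b$studies)
  expect_identical(a$effects, b$effects)
})

test_that("feature prevalence increases with baseline log-mean", {
  cfg <- synthetic_config(n_studies = 1, n_subjects_per_study = 25,
                          n_features = 150,
                          timepoints_per_study = list(c(0, 1)),
                          retention_prob = 1, pi_signal = 0,
                          sigma_study = 0.5, seed = 99)
  sim <- simulate_multistudy(cfg)
  prev <- rowMeans(sim$studies[[1]]$table$values > 0)
  mu <- sim$effects$baseline_log_mean
  expect_gt(cor(mu, prev, method = "spearman"), 0)
})

test_that("with all variance sources off, samples share one composition", {
  cfg <- synthetic_config(n_studies = 1, n_subjects_per_study = 6,
                          n_features = 20,
                          timepoints_per_study = list(c(0, 1)),
                          retention_prob = 1, pi_signal = 0, tau_effect = 0,
                          sigma_study = 0, sigma_subject = 0, sigma_noise = 0,
                          depth_log_mean = log(1e5), depth_log_sd = 0,
                          seed = 5)
  sim <- simulate_multistudy(cfg)
  v <- sim$studies[[1]]$table$values
  rel <- sweep(v, 2, colSums(v), "/")
  # multinomial noise only: all pairwise Bray-Curtis distances near 0
  d <- bray_curtis(feature_table(v))
  expect_lt(max(d), 0.05)
  expect_lt(max(abs(rel - rowMeans(rel))), 0.01)
})

test_that("stronger study batch effects raise the PERMANOVA study R2", {
  run_r2 <- function(sstudy) {
    cfg <- synthetic_config(n_studies = 2, n_subjects_per_study = 10,
                            n_features = 50,
                            timepoints_per_study = list(c(0, 1), c(0, 1)),
                            retention_prob = 1, pi_signal = 0,
                            sigma_study = sstudy, seed = 31)
    sim <- simulate_multistudy(cfg)
    pooled <- rygbsig:::pool_studies(sim$studies)
    d <- bray_curtis(pooled$table)
    pm <- permanova(d, pooled$meta, terms = "study", n_perm = 49, seed = 1)
    pm$R2[pm$term == "study"]
  }
  expect_gt(run_r2(2), run_r2(0))
})
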