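#' Configuration for the synthetic multi-study generator
#'
#' Defines the generative conditions for a multi-cohort longitudinal
#' microbiome simulation: several studies with strong compositional batch
#' effects, a sparse intervention signature partially shared across studies,
#' subject random intercepts, unbalanced sampling at post-surgery timepoints,
#' and multinomial counts at lognormal sequencing depths.
#'
#' The defaults emulate the design of a four-cohort gastric-bypass
#' meta-analysis: four 16S studies with pre-surgery baselines of 30, 25, 19
#' and 9 subjects and post-surgery months \{1,6\}, \{3,12,24\}, \{6\} and
#' \{6,12\} respectively, with roughly 60% of subjects re-sampled at any
#' given post-surgery month.
#'
#' @param n_studies number of independent cohorts.
#' @param n_subjects_per_study integer vector (recycled) of subjects per study.
#' @param n_features number of taxa/pathways (>= 2).
#' @param timepoints_per_study list (one element per study) of month vectors;
#'   each must contain 0 (baseline) plus at least one positive month.
#' @param retention_prob probability that a subject is sampled at each
#'   post-surgery timepoint (baseline is always sampled).
#' @param pi_signal fraction of features carrying a planted signature.
#' @param tau_effect sd of planted log10-scale effects.
#' @param rho_between correlation of planted effects across studies, in
#'   `[0,1]`; 1 = one common signature, 0 = independent per-study signatures.
#' @param sigma_study sd of per-study per-feature baseline offsets (the
#'   compositional batch effect).
#' @param sigma_subject sd of subject random intercepts.
#' @param sigma_noise sd of per-sample per-feature log10-scale noise.
#' @param depth_log_mean,depth_log_sd lognormal sequencing-depth parameters
#'   (natural-log scale).
#' @param baseline_log_sd sd of the global per-feature baseline log10 means
#'   (controls rank-abundance skew).
#' @param study_ids optional character vector of study names.
#' @param seed master RNG seed.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_studies = 4,
                             n_subjects_per_study = c(30, 25, 19, 9),
                             n_features = 200,
                             timepoints_per_study = list(c(0, 1, 6),
                                                         c(0, 3, 12, 24),
                                                         c(0, 6),
                                                         c(0, 6, 12)),
                             retention_prob = 0.6,
                             pi_signal = 0.2,
                             tau_effect = 1,
                             rho_between = 0.6,
                             sigma_study = 2,
                             sigma_subject = 0.5,
                             sigma_noise = 0.8,
                             depth_log_mean = log(2e4),
                             depth_log_sd = 0.5,
                             baseline_log_sd = 1.5,
                             study_ids = NULL,
                             seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              n_subjects_per_study =
                as.integer(rep_len(n_subjects_per_study, n_studies)),
              n_features = as.integer(n_features),
              timepoints_per_study = lapply(timepoints_per_study, as.numeric),
              retention_prob = retention_prob,
              pi_signal = pi_signal,
              tau_effect = tau_effect,
              rho_between = rho_between,
              sigma_study = sigma_study,
              sigma_subject = sigma_subject,
              sigma_noise = sigma_noise,
              depth_log_mean = depth_log_mean,
              depth_log_sd = depth_log_sd,
              baseline_log_sd = baseline_log_sd,
              study_ids = study_ids %||% sprintf("S%d", seq_len(n_studies)),
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop(sprintf("invalid config field '%s': must be a probability in [0,1]",
                   nm))
  }
  chk_nonneg <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
      stop(sprintf("invalid config field '%s': must be >= 0", nm))
  }
  if (cfg$n_studies < 1L) stop("invalid config field 'n_studies': must be >= 1")
  if (cfg$n_features < 2L) stop("invalid config field 'n_features': must be >= 2")
  if (length(cfg$timepoints_per_study) != cfg$n_studies)
    stop("invalid config field 'timepoints_per_study': need one timepoint set per study")
  for (tps in cfg$timepoints_per_study) {
    if (!0 %in% tps || !any(tps > 0) || any(tps < 0) || anyDuplicated(tps))
      stop("invalid config field 'timepoints_per_study': each study needs ",
           "timepoint 0 plus >= 1 distinct positive month")
  }
  if (any(cfg$n_subjects_per_study < 2L))
    stop("invalid config field 'n_subjects_per_study': need >= 2 subjects per study")
  chk_prob(cfg$retention_prob, "retention_prob")
  chk_prob(cfg$pi_signal, "pi_signal")
  chk_prob(cfg$rho_between, "rho_between")
  chk_nonneg(cfg$tau_effect, "tau_effect")
  chk_nonneg(cfg$sigma_study, "sigma_study")
  chk_nonneg(cfg$sigma_subject, "sigma_subject")
  chk_nonneg(cfg$sigma_noise, "sigma_noise")
  chk_nonneg(cfg$depth_log_sd, "depth_log_sd")
  chk_nonneg(cfg$baseline_log_sd, "baseline_log_sd")
  if (anyDuplicated(cfg$study_ids))
    stop("invalid config field 'study_ids': duplicates")
  invisible(cfg)
}

post_months_union <- function(cfg) {
  sort(unique(unlist(lapply(cfg$timepoints_per_study, function(t) t[t > 0]))))
}

synthetic_feature_ids <- function(cfg) {
  sprintf("taxon_%03d", seq_len(cfg$n_features))
}

#' Plant the intervention signature shared (partially) across studies
#'
#' Selects `ceiling(pi_signal * n_features)` signal features and draws, for
#' each, a shared effect and per-study effects correlated with it at
#' `rho_between`:
#' \deqn{\delta_{s,f} = \rho\,\delta_f + \sqrt{1-\rho^2}\,\eta_{s,f},\qquad
#'       \delta_f,\eta_{s,f} \sim N(0, \tau^2).}
#' Effects are on the log10-abundance scale and persist unchanged across all
#' post-surgery timepoints of a study (the planted shift is a lasting state
#' change, not a transient per-month fluctuation); non-signal features have
#' effect 0 everywhere. Global per-feature baseline log10 means are drawn
#' here too, so the whole generative truth is fixed by one seed.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; defaults to the config's master seed.
#' @return a `signature_effects` list: `delta` (study x feature x post-month
#'   array over the union of post months), `shared_component` (feature x
#'   post-month matrix), `signal_features` (IDs), `baseline_log_mean`
#'   (per-feature mu_f).
#' @export
plant_signature <- function(config, seed = config$seed) {
  validate_synthetic_config(config)
  set.seed(seed)
  nf <- config$n_features
  ns <- config$n_studies
  months <- post_months_union(config)
  fid <- synthetic_feature_ids(config)

  mu_f <- stats::rnorm(nf, 0, config$baseline_log_sd)

  n_signal <- ceiling(config$pi_signal * nf)
  signal <- if (n_signal > 0) sort(sample.int(nf, n_signal)) else integer(0)

  delta_f <- numeric(nf)
  delta_sf <- matrix(0, ns, nf)
  if (n_signal > 0) {
    rho <- config$rho_between
    delta_f[signal] <- stats::rnorm(n_signal, 0, config$tau_effect)
    eta <- matrix(stats::rnorm(ns * n_signal, 0, config$tau_effect),
                  ns, n_signal)
    delta_sf[, signal] <- rho * matrix(delta_f[signal], ns, n_signal,
                                       byrow = TRUE) +
      sqrt(1 - rho^2) * eta
  }

  delta <- array(0, dim = c(ns, nf, length(months)),
                 dimnames = list(config$study_ids, fid, months))
  for (k in seq_along(months)) delta[, , k] <- delta_sf

  shared <- matrix(delta_f, nf, length(months),
                   dimnames = list(fid, months))

  structure(list(delta = delta,
                 shared_component = shared,
                 signal_features = fid[signal],
                 baseline_log_mean = stats::setNames(mu_f, fid)),
            class = "signature_effects")
}

#' Simulate one study's longitudinal count table
#'
#' Generates multinomial counts for one cohort: per-feature study offsets
#' (batch effect), subject random intercepts, planted post-surgery effects,
#' per-sample log10-scale noise, a base-10 softmax to a composition, and a
#' lognormal sequencing depth per sample. Every subject is sampled at
#' baseline and, independently with probability `retention_prob`, at each
#' post-surgery month of the study.
#'
#' @param config a [synthetic_config()].
#' @param effects a [plant_signature()] result.
#' @param study_index which study (1-based).
#' @param seed RNG seed for this study's stream.
#' @return list with `table` (a count [feature_table()]) and `meta`
#'   (a [sample_metadata()]).
#' @export
simulate_cohort <- function(config, effects, study_index, seed) {
  validate_synthetic_config(config)
  if (study_index < 1L || study_index > config$n_studies)
    stop("study_index out of range")
  set.seed(seed)
  nf <- config$n_features
  fid <- synthetic_feature_ids(config)
  sid <- config$study_ids[study_index]
  months <- config$timepoints_per_study[[study_index]]
  post <- sort(months[months > 0])
  n_subj <- config$n_subjects_per_study[study_index]
  subjects <- sprintf("%s_P%02d", sid, seq_len(n_subj))

  mu_sf <- effects$baseline_log_mean +
    stats::rnorm(nf, 0, config$sigma_study)
  u <- stats::rnorm(n_subj, 0, config$sigma_subject)

  # sampling design: baseline always, each post month kept w.p. retention_prob
  rows <- list()
  for (i in seq_len(n_subj)) {
    kept <- c(0, post[stats::runif(length(post)) < config$retention_prob])
    rows[[i]] <- data.frame(subject_id = subjects[i],
                            timepoint_months = kept,
                            u = u[i], stringsAsFactors = FALSE)
  }
  design <- do.call(rbind, rows)
  design$sample_id <- sprintf("%s_%g", design$subject_id,
                              design$timepoint_months)

  n_samp <- nrow(design)
  counts <- matrix(0L, nf, n_samp, dimnames = list(fid, design$sample_id))
  month_names <- dimnames(effects$delta)[[3]]
  for (j in seq_len(n_samp)) {
    t_j <- design$timepoint_months[j]
    d <- if (t_j > 0) {
      effects$delta[study_index, , match(as.character(t_j), month_names)]
    } else 0
    lambda <- mu_sf + d + design$u[j] + stats::rnorm(nf, 0, config$sigma_noise)
    comp <- 10^(lambda - max(lambda))
    comp <- comp / sum(comp)
    depth <- max(1, round(stats::rlnorm(1, config$depth_log_mean,
                                        config$depth_log_sd)))
    counts[, j] <- stats::rmultinom(1, depth, comp)[, 1L]
  }

  meta <- sample_metadata(data.frame(sample_id = design$sample_id,
                                     subject_id = design$subject_id,
                                     study_id = sid,
                                     timepoint_months = design$timepoint_months,
                                     stringsAsFactors = FALSE))
  list(table = feature_table(counts, is_count = TRUE), meta = meta)
}

#' Simulate a full multi-study dataset
#'
#' Plants one signature and simulates every study on its own deterministic
#' child seed, so identical configurations reproduce bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @return a `multistudy_sim` list: `studies` (named list of
#'   `list(table, meta)`), `effects`, `config`.
#' @export
simulate_multistudy <- function(config) {
  validate_synthetic_config(config)
  seeds <- spawn_seeds(config$seed, config$n_studies + 1L)
  effects <- plant_signature(config, seed = seeds[1L])
  studies <- lapply(seq_len(config$n_studies), function(s)
    simulate_cohort(config, effects, s, seed = seeds[s + 1L]))
  names(studies) <- config$study_ids
  structure(list(studies = studies, effects = effects, config = config),
            class = "multistudy_sim")
}
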