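#!/usr/bin/env Rscript
# Simulate the default four-cohort dataset: four studies with the unbalanced
# longitudinal design (baselines of 30/25/19/9 subjects; post-surgery months
# {1,6}, {3,12,24}, {6} and {6,12}), strong study-level batch effects, and a
# sparse intervention signature shared across studies at rho_between = 0.6.
# Writes one count table + metadata TSV per study under results/data/.

suppressMessages(library(rygbsig))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = seed)
sim <- simulate_multistudy(cfg)

for (nm in names(sim$studies)) {
  s <- sim$studies[[nm]]
  write_feature_table(s$table, file.path(out, paste0(nm, "_counts.tsv")))
  write_metadata(s$meta, file.path(out, paste0(nm, "_metadata.tsv")))
  message(sprintf("%s: %d features x %d samples, %d subjects, months %s",
                  nm, nrow(s$table$values), ncol(s$table$values),
                  length(unique(s$meta$subject_id)),
                  paste(sort(unique(s$meta$timepoint_months)), collapse = "/")))
}

# ground truth for downstream sanity checks
truth <- data.frame(feature_id = names(sim$effects$baseline_log_mean),
                    baseline_log_mean = sim$effects$baseline_log_mean,
                    is_signal = names(sim$effects$baseline_log_mean) %in%
                      sim$effects$signal_features)
rownames(truth) <- NULL
rygbsig:::write_result_tsv(truth, file.path(out, "planted_truth.tsv"))
message("planted signature features: ", length(sim$effects$signal_features))
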