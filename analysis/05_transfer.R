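#!/usr/bin/env Rscript
# Supervised pre/post discrimination and cross-study transfer: within-study
# 8-fold x 10-repeat cross-validation (diagonal), study-to-study model
# transfer (off-diagonal), and leave-one-study-out validation, all with
# AUROC on across-model averaged scores. LASSO by default; pass
# "random_forest" as the second argument to switch. Takes several minutes.

suppressMessages(library(rygbsig))
args <- commandArgs(TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L
model <- if (length(args) >= 2) args[2] else "lasso"

data_dir <- file.path("results", "data")
tabs <- list.files(data_dir, pattern = "_counts\\.tsv$", full.names = TRUE)
if (!length(tabs)) stop("run analysis/01_simulate.R first")

studies <- lapply(tabs, function(tp)
  align_samples(read_feature_table(tp),
                read_metadata(sub("_counts\\.tsv$", "_metadata.tsv", tp))))
names(studies) <- vapply(studies, function(s) s$meta$study_id[1], "")

seeds <- rygbsig:::spawn_seeds(seed, 2L)
tm <- transfer_matrix(studies, model_type = model, k = 8, repeats = 10,
                      seed = seeds[1])
lo <- loso(studies, model_type = model, k = 8, repeats = 10, seed = seeds[2])
res <- rbind(tm, lo)
res$seed <- seed
rygbsig:::write_result_tsv(res, file.path("results", "transfer.tsv"))

cv <- res[res$mode == "cv", ]
message("within-study CV AUROC: ",
        paste(sprintf("%s %.2f", cv$train_study, cv$auroc), collapse = ", "))
message("study-to-study AUROC range: ",
        paste(round(range(res$auroc[res$mode == "transfer"]), 2), collapse = "-"))
message("LOSO AUROC: ",
        paste(sprintf("%s %.2f", lo$test_study, lo$auroc), collapse = ", "))
message("wrote results/transfer.tsv")
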