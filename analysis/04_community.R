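#!/usr/bin/env Rscript
# Community-level structure across the joined cohorts: Bray-Curtis distances
# on the per-study log10 depth-normalized tables (joined on the feature
# union), PCoA ordination, PERMANOVA with the sequential design
# study -> timepoint (pre/post) -> interaction, and per-sample Shannon
# diversity on the raw counts.

suppressMessages(library(rygbsig))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

data_dir <- file.path("results", "data")
tabs <- list.files(data_dir, pattern = "_counts\\.tsv$", full.names = TRUE)
if (!length(tabs)) stop("run analysis/01_simulate.R first")

studies <- lapply(tabs, function(tp) {
  al <- align_samples(read_feature_table(tp),
                      read_metadata(sub("_counts\\.tsv$", "_metadata.tsv", tp)))
  al
})
norm <- lapply(studies, function(s)
  list(table = prevalence_filter(normalize_depth(s$table), 0.10),
       meta = s$meta))

pooled <- rygbsig:::pool_norm_tables(norm)
d <- bray_curtis(pooled$table)
ord <- pcoa(d)
k <- min(4, ncol(ord$coordinates))
rygbsig:::write_result_tsv(
  data.frame(sample_id = rownames(ord$coordinates),
             ord$coordinates[, 1:k, drop = FALSE]),
  file.path("results", "ordination.tsv"),
  paste("proportion explained:",
        paste(signif(ord$proportion_explained[1:k], 4), collapse = " ")))

pm <- permanova(d, pooled$meta, n_perm = 999, seed = seed)
print(as.data.frame(pm))
pm_df <- as.data.frame(pm); pm_df$n_perm <- attr(pm, "n_perm"); pm_df$seed <- seed
rygbsig:::write_result_tsv(pm_df, file.path("results", "permanova.tsv"),
                           "permutation=free (repeated measures not restricted)")

shan <- do.call(rbind, lapply(studies, function(s)
  data.frame(sample_id = s$meta$sample_id, study_id = s$meta$study_id,
             timepoint_months = s$meta$timepoint_months,
             shannon = apply(s$table$values, 2, shannon))))
rownames(shan) <- NULL
rygbsig:::write_result_tsv(shan, file.path("results", "shannon.tsv"))
agg <- aggregate(shannon ~ timepoint_months > 0, shan, mean)
message(sprintf("mean Shannon pre %.3f vs post %.3f",
                agg$shannon[1], agg$shannon[2]))
message("wrote results/ordination.tsv, permanova.tsv, shannon.tsv")
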