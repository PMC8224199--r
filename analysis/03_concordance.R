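#!/usr/bin/env Rscript
# Cross-cohort concordance: correlate signed log10 p-value signatures over
# shared features for every between-study (timepoint x timepoint) pair and
# every within-study timepoint pair, control the FDR across all pairs, and
# contrast between- vs within-study coefficients. Also clusters the
# signature matrix for heatmap display. Reads results/signature.tsv.

suppressMessages(library(rygbsig))

sig <- read.delim(file.path("results", "signature.tsv"), comment.char = "#")
tmap <- lapply(split(sig$timepoint_months, sig$study_id),
               function(t) sort(unique(t)))
pairs <- enumerate_pairs(tmap)
message(nrow(pairs), " comparison pairs (",
        sum(pairs$kind == "between"), " between, ",
        sum(pairs$kind == "within"), " within)")

conc <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
  correlate_pair(sig, sig, pairs[i, ])))
conc$q <- bh_adjust(conc$p)
rygbsig:::write_result_tsv(conc, file.path("results", "concordance.tsv"))

summ <- concordance_summary(conc)
print(summ$by_kind)
message(sprintf("within vs between Wilcoxon p = %.4g; %d/%d pairs at q < 0.05",
                summ$contrast_p, summ$n_significant, summ$n_pairs))
jsonlite::write_json(list(by_kind = summ$by_kind, contrast_p = summ$contrast_p,
                          n_significant = summ$n_significant, spread = "sd"),
                     file.path("results", "concordance_summary.json"),
                     auto_unbox = TRUE, digits = NA)

# hierarchical clustering of the feature x (study, month) signature matrix
ok <- sig[!is.na(sig$signed_log10p), ]
key <- paste(ok$study_id, ok$timepoint_months, sep = "_m")
feats <- sort(unique(ok$feature_id)); keys <- sort(unique(key))
smat <- matrix(NA_real_, length(feats), length(keys),
               dimnames = list(feats, keys))
smat[cbind(match(ok$feature_id, feats), match(key, keys))] <- ok$signed_log10p
cl <- cluster_signature(smat)
rygbsig:::write_result_tsv(
  data.frame(feature_id = feats[cl$row_order], order = seq_along(cl$row_order)),
  file.path("results", "cluster_row_order.tsv"),
  "linkage=complete distance=euclidean")
message("wrote results/concordance.tsv, concordance_summary.json, cluster_row_order.tsv")
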