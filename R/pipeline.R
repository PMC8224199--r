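#' Build a pipeline run configuration
#'
#' Either a synthetic-data block (a [synthetic_config()]) or per-study input
#' paths must be supplied, not both. Input paths are a named list
#' (study ID -> `list(table = <tsv>, meta = <tsv>)`).
#'
#' @param synthetic a [synthetic_config()], or `NULL`.
#' @param input_paths named list of per-study TSV paths, or `NULL`.
#' @param prevalence_threshold per-study prevalence filter (default 0.10).
#' @param pseudocount classifier pseudocount (default 1e-5).
#' @param p_floor signed log10 p clamp (default 1e-16).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param model classifier type, `"lasso"` or `"random_forest"`.
#' @param k,repeats cross-validation folds and repeats.
#' @param run_transfer run the (slower) ML transfer stage (default TRUE).
#' @param pathway_mode treat inputs as already-normalized pathway abundances:
#'   skip depth normalization and enter the model stage after `log10(x + 1)`.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory (created if needed).
#' @return a validated `run_config` list.
#' @export
run_config <- function(synthetic = NULL, input_paths = NULL,
                       prevalence_threshold = 0.10, pseudocount = 1e-5,
                       p_floor = 1e-16, n_perm = 999,
                       model = c("lasso", "random_forest"),
                       k = 8, repeats = 10, run_transfer = TRUE,
                       pathway_mode = FALSE, seed = 1L, out_dir = tempfile()) {
  if (is.null(synthetic) && is.null(input_paths))
    stop("config needs either a synthetic block or input paths")
  if (!is.null(synthetic) && !is.null(input_paths))
    stop("config cannot have both a synthetic block and input paths")
  if (!is.null(synthetic)) validate_synthetic_config(synthetic)
  cfg <- list(synthetic = synthetic, input_paths = input_paths,
              prevalence_threshold = prevalence_threshold,
              pseudocount = pseudocount, p_floor = p_floor,
              n_perm = n_perm, model = match.arg(model), k = k,
              repeats = repeats, run_transfer = isTRUE(run_transfer),
              pathway_mode = isTRUE(pathway_mode),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full cross-cohort analysis
#'
#' Executes every stage in order — load or simulate the studies; per study:
#' depth-normalize, prevalence-filter, mixed-model signature scan; jointly:
#' pairwise concordance with BH control and a between/within summary,
#' signature clustering, Bray-Curtis PCoA, PERMANOVA (study * timepoint),
#' Shannon diversity, and (optionally) the ML transfer matrix plus
#' leave-one-study-out validation — and writes each result as TSV/JSON under
#' `config$out_dir`. Re-running with an identical config reproduces all
#' outputs bit-identically.
#'
#' @param config a [run_config()].
#' @return (invisibly) the run manifest: config hash, seeds, package version,
#'   per-stage row counts, output paths; also written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  comments <- sprintf("config_hash=%s seed=%d", hash, config$seed)
  stage <- "load"
  res <- tryCatch({
    studies <- if (!is.null(config$synthetic)) {
      simulate_multistudy(config$synthetic)$studies
    } else {
      lapply(config$input_paths, function(p) {
        al <- align_samples(read_feature_table(p$table), read_metadata(p$meta))
        list(table = al$table, meta = al$meta)
      })
    }

    stage <- "preprocess"
    norm <- lapply(studies, function(s) {
      tb <- if (config$pathway_mode) {
        structure(list(values = log10(s$table$values + 1), is_count = FALSE,
                       depths = colSums(s$table$values),
                       mean_depth = mean(colSums(s$table$values))),
                  class = c("normalized_table", "feature_table"))
      } else normalize_depth(s$table)
      list(table = prevalence_filter(tb, config$prevalence_threshold),
           meta = s$meta)
    })

    stage <- "scan"
    sigs <- lapply(norm, function(s)
      signature_scan(s$table, s$meta, p_floor = config$p_floor))
    sig_all <- do.call(rbind, sigs)
    rownames(sig_all) <- NULL
    write_result_tsv(sig_all, out("signature.tsv"), comments)

    stage <- "concordance"
    tmap <- lapply(sigs, function(s) sort(unique(s$timepoint_months)))
    names(tmap) <- vapply(sigs, function(s) s$study_id[1L], "")
    names(sigs) <- names(tmap)
    pairs <- enumerate_pairs(tmap)
    conc <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      pr <- pairs[i, ]
      correlate_pair(sigs[[pr$study_a]], sigs[[pr$study_b]], pr)
    }))
    conc$q <- NA_real_
    ok <- !is.na(conc$p)
    conc$q[ok] <- bh_adjust(conc$p[ok])
    write_result_tsv(conc, out("concordance.tsv"), comments)
    summ <- concordance_summary(conc)
    jsonlite::write_json(
      list(by_kind = summ$by_kind, contrast_p = summ$contrast_p,
           n_significant = summ$n_significant, n_pairs = summ$n_pairs,
           spread = "sd", config_hash = hash),
      out("concordance_summary.json"), auto_unbox = TRUE, digits = NA)

    stage <- "cluster"
    sig_ok <- sig_all[!is.na(sig_all$signed_log10p), , drop = FALSE]
    key <- paste(sig_ok$study_id, sig_ok$timepoint_months, sep = "_m")
    feats <- sort(unique(sig_ok$feature_id))
    keys <- sort(unique(key))
    smat <- matrix(NA_real_, length(feats), length(keys),
                   dimnames = list(feats, keys))
    smat[cbind(match(sig_ok$feature_id, feats), match(key, keys))] <-
      sig_ok$signed_log10p
    clust <- cluster_signature(smat)
    write_result_tsv(
      data.frame(feature_id = rownames(smat)[clust$row_order],
                 order = seq_along(clust$row_order)),
      out("cluster_row_order.tsv"),
      c(comments, "linkage=complete distance=euclidean"))

    stage <- "community"
    pooled <- pool_norm_tables(norm)
    d <- bray_curtis(pooled$table)
    ord <- pcoa(d)
    ord_df <- data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates[, seq_len(min(4, ncol(ord$coordinates))),
                                         drop = FALSE])
    write_result_tsv(ord_df, out("ordination.tsv"),
                     c(comments, paste("eigenvalues:",
                                       paste(signif(ord$eigenvalues[1:4], 6),
                                             collapse = " "))))
    perm <- permanova(d, pooled$meta, n_perm = config$n_perm,
                      seed = config$seed)
    perm_df <- as.data.frame(perm)
    perm_df$n_perm <- attr(perm, "n_perm")
    perm_df$seed <- config$seed
    write_result_tsv(perm_df, out("permanova.tsv"),
                     c(comments, "permutation=free (repeated measures not restricted)"))
    shan <- do.call(rbind, lapply(studies, function(s)
      data.frame(sample_id = s$meta$sample_id,
                 study_id = s$meta$study_id,
                 timepoint_months = s$meta$timepoint_months,
                 shannon = apply(s$table$values[, s$meta$sample_id,
                                                drop = FALSE], 2L, shannon))))
    rownames(shan) <- NULL
    write_result_tsv(shan, out("shannon.tsv"), comments)

    stage <- "transfer"
    transfer <- NULL
    if (config$run_transfer) {
      seeds <- spawn_seeds(config$seed, 2L)
      tm <- transfer_matrix(studies, model_type = config$model,
                            k = config$k, repeats = config$repeats,
                            seed = seeds[1L])
      lo <- loso(studies, model_type = config$model, k = config$k,
                 repeats = config$repeats, seed = seeds[2L])
      transfer <- rbind(tm, lo)
      transfer$seed <- config$seed
      write_result_tsv(transfer, out("transfer.tsv"), comments)
    }

    list(signature = sig_all, concordance = conc, summary = summ,
         permanova = perm, ordination = ord, shannon = shan,
         transfer = transfer, cluster = clust)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    package_version = pkg_version_string(),
    config_hash = hash,
    seed = config$seed,
    stages = list(
      scan = list(rows = nrow(res$signature)),
      concordance = list(rows = nrow(res$concordance)),
      permanova = list(rows = nrow(res$permanova)),
      shannon = list(rows = nrow(res$shannon)),
      transfer = list(rows = if (is.null(res$transfer)) 0L
                      else nrow(res$transfer))))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(manifest = manifest, out_dir = config$out_dir)))
}

# Join per-study normalized tables on the union of features (fill 0) for the
# joint Bray-Curtis ordination and PERMANOVA.
pool_norm_tables <- function(norm) {
  feats <- sort(unique(unlist(lapply(norm, function(s) feature_ids(s$table)))))
  mats <- lapply(norm, function(s) {
    m <- matrix(0, length(feats), ncol(s$table$values),
                dimnames = list(feats, colnames(s$table$values)))
    m[feature_ids(s$table), ] <- s$table$values
    m
  })
  meta <- do.call(rbind, lapply(norm, function(s) as.data.frame(s$meta)))
  rownames(meta) <- NULL
  list(table = feature_table(do.call(cbind, mats), is_count = FALSE),
       meta = sample_metadata(meta))
}
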