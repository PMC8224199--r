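#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a randomly chosen positive sample receives a higher score
#' than a randomly chosen negative one, with ties counted 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1, logical, or two-level factor); both
#'   classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUROC")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  as.integer(labels)
}

# Partition subjects into k folds; returns per-sample fold indices. Retries
# until every fold's training split contains both classes (a fold holding all
# of one class would leave an untrainable split).
subject_folds <- function(subjects, labels, k, max_tries = 100L) {
  subj <- unique(subjects)
  k <- min(k, length(subj))
  for (try in seq_len(max_tries)) {
    fold_of_subj <- stats::setNames(
      sample(rep_len(seq_len(k), length(subj))), sample(subj))
    fold <- unname(fold_of_subj[subjects])
    ok <- all(vapply(seq_len(k), function(f) {
      tr <- labels[fold != f]
      length(unique(tr)) == 2L && sum(fold == f) > 0L
    }, TRUE))
    if (ok) return(fold)
  }
  stop("could not build subject-grouped folds with both classes in every ",
       "training split after ", max_tries, " tries")
}

fit_one_model <- function(x, y, model_type, seed) {
  if (model_type == "lasso") {
    suppressWarnings(
      glmnet::cv.glmnet(x, y, family = "binomial", nfolds = 5,
                        type.measure = "auc", nlambda = 50))
  } else {
    ranger::ranger(x = x, y = factor(y, levels = c(0L, 1L)),
                   probability = TRUE, num.trees = 500,
                   seed = seed, num.threads = 1)
  }
}

score_model <- function(model, model_type, x) {
  if (model_type == "lasso") {
    as.numeric(stats::predict(model, newx = x, s = "lambda.min",
                              type = "response"))
  } else {
    stats::predict(model, data = x, num.threads = 1)$predictions[, "1"]
  }
}

#' Train a cross-validated classifier ensemble on one (pooled) training set
#'
#' Discriminates pre- from post-surgery samples (timepoint 0 -> label 0, any
#' positive month -> label 1). The feature transform ([ml_transform()]) is
#' fitted once on the full training table and frozen. Samples are then
#' partitioned into `k` folds grouped by subject (all samples of a subject
#' share a fold, so repeated measures never leak between train and test),
#' repeated `repeats` times; one model is trained per fold x repeat
#' (`k * repeats` models). Within-study performance is the mean over repeats
#' of the AUROC on that repeat's pooled held-out predictions.
#'
#' LASSO models are L1-penalized logistic regressions with the penalty chosen
#' by inner 5-fold cross-validation maximizing AUROC (on a fixed 50-step
#' penalty path); random forests use 500 trees with default feature
#' subsampling.
#'
#' @param table a [feature_table()] (counts are converted to relative
#'   abundances first; the classifier branch does not use depth
#'   normalization).
#' @param meta matching [sample_metadata()].
#' @param model_type `"lasso"` or `"random_forest"`.
#' @param k folds (default 8).
#' @param repeats repeats (default 10).
#' @param seed RNG seed.
#' @return a `model_ensemble` list: `models` (length `k * repeats`),
#'   `model_type`, `frozen`, `features`, `within_auroc`, `per_repeat_auroc`,
#'   `train_study`, `k`, `repeats`.
#' @export
fit_cv_models <- function(table, meta, model_type = c("lasso", "random_forest"),
                          k = 8, repeats = 10, seed = 1L) {
  model_type <- match.arg(model_type)
  al <- align_samples(table, meta)
  table <- al$table; meta <- al$meta
  if (table$is_count) table <- relative_abundance(table)
  y <- as.integer(meta$timepoint_months > 0)
  if (length(unique(y)) < 2L)
    stop("training data must contain both pre- and post-surgery samples")
  tf <- ml_transform(table)
  x <- tf$x
  set.seed(seed)
  models <- vector("list", 0L)
  per_repeat <- numeric(repeats)
  fold_assignments <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold <- subject_folds(meta$subject_id, y, k)
    fold_assignments[[r]] <- fold
    k_eff <- max(fold)
    held_scores <- rep(NA_real_, nrow(x))
    for (f in seq_len(k_eff)) {
      tr <- fold != f
      m <- fit_one_model(x[tr, , drop = FALSE], y[tr], model_type,
                         seed = sample.int(.Machine$integer.max - 1L, 1L))
      models[[length(models) + 1L]] <- m
      held_scores[!tr] <- score_model(m, model_type, x[!tr, , drop = FALSE])
    }
    per_repeat[r] <- auroc(held_scores, y)
  }
  structure(list(models = models, model_type = model_type,
                 frozen = tf$frozen, features = tf$frozen$features,
                 within_auroc = mean(per_repeat),
                 per_repeat_auroc = per_repeat,
                 fold_assignments = fold_assignments,
                 sample_ids = meta$sample_id,
                 train_study = paste(sort(unique(meta$study_id)),
                                     collapse = "+"),
                 k = k, repeats = repeats),
            class = "model_ensemble")
}

#' Score an external study with a trained ensemble
#'
#' The external table is passed through the ensemble's frozen standardization
#' (apply mode: features are matched by ID, absent features imputed as
#' relative abundance 0, no statistic recomputed), every model of the
#' ensemble scores every external sample, per-sample scores are averaged
#' across models, and AUROC is computed on the averaged scores.
#'
#' @param ensemble a [fit_cv_models()] result.
#' @param table external study's [feature_table()].
#' @param meta external study's [sample_metadata()].
#' @param labels optional binary label override (default: timepoint > 0).
#' @param mode label for the result row (`"transfer"` or `"loso"`).
#' @return one-row data.frame: `train_study`, `test_study`, `mode`,
#'   `model_type`, `auroc`; the averaged per-sample scores are attached as
#'   attribute `scores`.
#' @export
transfer_predict <- function(ensemble, table, meta, labels = NULL,
                             mode = "transfer") {
  al <- align_samples(table, meta)
  table <- al$table; meta <- al$meta
  if (table$is_count) table <- relative_abundance(table)
  y <- if (is.null(labels)) as.integer(meta$timepoint_months > 0)
       else as_binary_labels(labels)
  x <- ml_transform(table, frozen = ensemble$frozen)$x
  score_mat <- vapply(ensemble$models,
                      function(m) score_model(m, ensemble$model_type, x),
                      numeric(nrow(x)))
  scores <- rowMeans(matrix(score_mat, nrow = nrow(x)))
  out <- data.frame(train_study = ensemble$train_study,
                    test_study = paste(sort(unique(meta$study_id)),
                                       collapse = "+"),
                    mode = mode, model_type = ensemble$model_type,
                    auroc = auroc(scores, y), stringsAsFactors = FALSE)
  attr(out, "scores") <- stats::setNames(scores, meta$sample_id)
  out
}

#' Leave-one-study-out transfer validation
#'
#' For each study in turn, the remaining studies are pooled (each converted
#' to relative abundances first, features joined by ID with absent features
#' as 0), a fresh ensemble is trained on the pool with the standardization
#' frozen on the pooled training data, and the held-out study is scored.
#'
#' @param studies named list of `list(table, meta)` (>= 2 studies), e.g.
#'   `simulate_multistudy(cfg)$studies`.
#' @param model_type,k,repeats,seed as in [fit_cv_models()].
#' @return data.frame of [transfer_predict()] rows, one per held-out study,
#'   `mode = "loso"`.
#' @export
loso <- function(studies, model_type = c("lasso", "random_forest"),
                 k = 8, repeats = 10, seed = 1L) {
  model_type <- match.arg(model_type)
  if (length(studies) < 2L) stop("LOSO needs >= 2 studies")
  seeds <- spawn_seeds(seed, length(studies))
  rows <- lapply(seq_along(studies), function(h) {
    train <- pool_studies(studies[-h])
    ens <- fit_cv_models(train$table, train$meta, model_type = model_type,
                         k = k, repeats = repeats, seed = seeds[h])
    transfer_predict(ens, studies[[h]]$table, studies[[h]]$meta,
                     mode = "loso")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full study-to-study transfer matrix
#'
#' Within-study cross-validation on the diagonal and study-to-study model
#' transfer off the diagonal, mirroring an AUROC heatmap of train-study by
#' test-study.
#'
#' @inheritParams loso
#' @return data.frame with one row per (train, test) combination; diagonal
#'   rows have `mode = "cv"` and `test_study = "self"`.
#' @export
transfer_matrix <- function(studies, model_type = c("lasso", "random_forest"),
                            k = 8, repeats = 10, seed = 1L) {
  model_type <- match.arg(model_type)
  seeds <- spawn_seeds(seed, length(studies))
  rows <- list()
  for (i in seq_along(studies)) {
    ens <- fit_cv_models(studies[[i]]$table, studies[[i]]$meta,
                         model_type = model_type, k = k, repeats = repeats,
                         seed = seeds[i])
    rows[[length(rows) + 1L]] <-
      data.frame(train_study = ens$train_study, test_study = "self",
                 mode = "cv", model_type = model_type,
                 auroc = ens$within_auroc, stringsAsFactors = FALSE)
    for (j in seq_along(studies)) {
      if (j == i) next
      rows[[length(rows) + 1L]] <-
        transfer_predict(ens, studies[[j]]$table, studies[[j]]$meta)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pool several studies into one table/metadata pair on the union of features
# (absent features filled with 0); counts are converted to relative
# abundances per study first so depths never leak across studies.
pool_studies <- function(studies) {
  tabs <- lapply(studies, function(s)
    if (s$table$is_count) relative_abundance(s$table) else s$table)
  feats <- sort(unique(unlist(lapply(tabs, feature_ids))))
  mats <- lapply(tabs, function(t) {
    m <- matrix(0, length(feats), ncol(t$values),
                dimnames = list(feats, colnames(t$values)))
    m[feature_ids(t), ] <- t$values
    m
  })
  meta <- do.call(rbind, lapply(studies, function(s) as.data.frame(s$meta)))
  rownames(meta) <- NULL
  list(table = feature_table(do.call(cbind, mats), is_count = FALSE),
       meta = sample_metadata(meta))
}
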