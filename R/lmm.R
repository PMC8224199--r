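#' Fit a random-intercept mixed model for one feature
#'
#' Fits, by REML,
#' \deqn{y_{ij} = \beta_0 + \sum_t \beta_t \, 1[\mathrm{time}(j)=t] + u_i +
#'   \varepsilon_{ij}, \quad u_i \sim N(0,\sigma_u^2),\
#'   \varepsilon \sim N(0,\sigma_e^2)}
#' with subject random intercepts and timepoint as an unordered factor whose
#' reference level is the pre-surgery baseline (month 0), so each \eqn{\beta_t}
#' is the adjusted log10-abundance difference of post-surgery month t versus
#' baseline. Unbalanced designs (subjects missing some months) are handled by
#' the likelihood. Two-sided p-values use \eqn{t = \beta_t / se_t} with
#' \eqn{df = n_{obs} - n_{subjects} - (n_{timepoints} - 1)}.
#'
#' If the mixed-model fit fails to converge, the model is refit with
#' \eqn{\sigma_u} fixed at 0 (ordinary least squares) and flagged
#' `converged = FALSE`. A response with zero variance raises a degenerate-fit
#' error (condition class `rygbsig_degenerate_fit`).
#'
#' @param y numeric response (normalized abundance), one entry per metadata row.
#' @param meta a [sample_metadata()] with rows aligned to `y`.
#' @return an `lmm_fit` list: `timepoints` (post months), `beta`, `se`,
#'   `t_stat`, `df`, `p`, `sigma_u`, `sigma_e`, `converged`, `n_subjects`,
#'   `n_obs`.
#' @export
fit_feature_lmm <- function(y, meta) {
  if (length(y) != nrow(meta))
    stop("length(y) must equal nrow(meta)")
  tp <- sort(unique(meta$timepoint_months))
  if (!(0 %in% tp) || length(tp) < 2L)
    stop("need >= 2 distinct timepoints including baseline (0)")
  if (length(unique(meta$subject_id)) < 2L)
    stop("need >= 2 subjects")
  if (stats::var(y) == 0)
    stop(structure(class = c("rygbsig_degenerate_fit", "error", "condition"),
                   list(message = "response has zero variance", call = NULL)))
  df_fit <- data.frame(y = as.numeric(y),
                       time = factor(meta$timepoint_months, levels = tp),
                       subject = factor(meta$subject_id))
  n_obs <- nrow(df_fit)
  n_subj <- nlevels(df_fit$subject)
  ddf <- n_obs - n_subj - (length(tp) - 1L)

  fit <- tryCatch(
    nlme::lme(y ~ time, random = ~ 1 | subject, data = df_fit,
              method = "REML"),
    error = function(e) NULL)
  if (!is.null(fit)) {
    fe <- nlme::fixef(fit)
    se <- sqrt(diag(fit$varFix))
    vc <- suppressWarnings(nlme::VarCorr(fit))
    sigma_u <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
    sigma_e <- fit$sigma
    converged <- TRUE
  } else {
    ols <- stats::lm(y ~ time, data = df_fit)
    cf <- summary(ols)$coefficients
    fe <- cf[, "Estimate"]
    se <- cf[, "Std. Error"]
    sigma_u <- 0
    sigma_e <- summary(ols)$sigma
    converged <- FALSE
  }
  post <- tp[tp > 0]
  nm <- paste0("time", post)
  beta <- unname(fe[nm])
  se_t <- unname(se[nm])
  t_stat <- beta / se_t
  p <- 2 * stats::pt(-abs(t_stat), df = ddf)
  structure(list(timepoints = post, beta = beta, se = se_t, t_stat = t_stat,
                 df = ddf, p = p, sigma_u = sigma_u, sigma_e = sigma_e,
                 converged = converged, n_subjects = n_subj, n_obs = n_obs),
            class = "lmm_fit")
}

#' Signed log10 p-value
#'
#' The per-feature signature statistic: \eqn{-\log_{10}} of the unadjusted
#' p-value, carrying the sign of the regression slope, so positive values
#' mark features increased after surgery and negative values features
#' decreased. p-values are floored at `p_floor` to keep the statistic finite.
#'
#' @param beta effect estimate (its sign is used; `sign(0) = 0`).
#' @param p unadjusted p-value in `(0, 1]`.
#' @param p_floor lower clamp for p; default `1e-16`.
#' @return signed log10 p (vectorized over `beta`/`p`).
#' @export
signed_log10p <- function(beta, p, p_floor = 1e-16) {
  if (any(!is.na(p) & p <= 0))
    stop("p-values must be > 0")
  if (p_floor <= 0)
    stop("p_floor must be > 0")
  sign(beta) * (-log10(pmax(p, p_floor)))
}

#' Per-feature mixed-model scan of one study
#'
#' Fits [fit_feature_lmm()] for every feature of a (prevalence-filtered,
#' depth-normalized) single-study table and assembles the study's signature:
#' one row per feature x post-surgery timepoint with the effect estimate,
#' unadjusted p-value, and signed log10 p. Features whose response is
#' degenerate (zero variance) are kept as rows with missing statistics so
#' that feature sets stay comparable across studies.
#'
#' @param table a `normalized_table` (or any `feature_table`) for one study.
#' @param meta matching [sample_metadata()]; must contain baseline and >= 1
#'   post-surgery samples of a single study.
#' @param p_floor passed to [signed_log10p()].
#' @return a `signature_table` data.frame with columns `study_id`,
#'   `feature_id`, `timepoint_months`, `beta`, `se`, `p`, `signed_log10p`,
#'   `n_subjects`, `converged`.
#' @export
signature_scan <- function(table, meta, p_floor = 1e-16) {
  al <- align_samples(table, meta)
  table <- al$table; meta <- al$meta
  study <- unique(meta$study_id)
  if (length(study) != 1L)
    stop("signature_scan expects samples from a single study")
  if (!any(meta$timepoint_months > 0))
    stop("no post-surgery samples in study ", study)
  if (!any(meta$timepoint_months == 0))
    stop("no baseline samples in study ", study)
  post <- sort(unique(meta$timepoint_months[meta$timepoint_months > 0]))

  rows <- lapply(feature_ids(table), function(f) {
    y <- table$values[f, ]
    base <- data.frame(study_id = study, feature_id = f,
                       timepoint_months = post, beta = NA_real_,
                       se = NA_real_, p = NA_real_,
                       signed_log10p = NA_real_,
                       n_subjects = length(unique(meta$subject_id)),
                       converged = NA, stringsAsFactors = FALSE)
    fit <- tryCatch(fit_feature_lmm(y, meta),
                    rygbsig_degenerate_fit = function(e) NULL)
    if (is.null(fit)) return(base)
    base$beta <- fit$beta
    base$se <- fit$se
    base$p <- fit$p
    base$signed_log10p <- signed_log10p(fit$beta, fit$p, p_floor)
    base$converged <- fit$converged
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("signature_table", "data.frame")
  out
}

#' Scan a fixed panel of features (e.g. opportunistic pathogens)
#'
#' Runs [signature_scan()] restricted to a named panel (exact string match on
#' feature IDs, e.g. `"Klebsiella pneumoniae"`) and adds Benjamini-Hochberg
#' q-values computed across all (panel feature x timepoint) p-values within
#' the study.
#'
#' @param table,meta,p_floor as in [signature_scan()].
#' @param panel character vector of feature IDs to scan.
#' @return a `signature_table` with an extra `q` column.
#' @export
panel_scan <- function(table, meta, panel, p_floor = 1e-16) {
  if (!length(panel)) stop("panel is empty")
  present <- intersect(panel, feature_ids(table))
  if (!length(present))
    stop("no panel feature present in the table; panel: ",
         paste(panel, collapse = ", "))
  missing <- setdiff(panel, present)
  if (length(missing))
    warning(sprintf("%d panel feature(s) absent: %s", length(missing),
                    paste(missing, collapse = ", ")))
  sig <- signature_scan(subset_table(table, features = present), meta,
                        p_floor = p_floor)
  sig$q <- NA_real_
  ok <- !is.na(sig$p)
  sig$q[ok] <- bh_adjust(sig$p[ok])
  sig
}
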