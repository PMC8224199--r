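# rygbsig

Cross-cohort concordance analysis of gut-microbiome signatures after
Roux-en-Y gastric bypass (RYGB) surgery.

Independent longitudinal microbiome studies of bariatric surgery often
disagree about which taxa respond, because cohorts differ in demographics,
geography, and laboratory technique, and because study-level batch effects
dwarf the biological signal. `rygbsig` implements a meta-analysis pipeline
that asks whether the *direction and strength* of post-surgical shifts
replicate across cohorts when every study is processed identically, and
ships a synthetic multi-study generator so the entire pipeline is testable
without any external sequence data.

## The method

For each study, raw counts are depth-normalized as

```
log10( count / N_j * N̄ + 1 )
```

(`N_j` = sample depth, `N̄` = mean depth in the study), features present in
fewer than 10% of samples are removed, and each feature is fit with a
random-intercept linear mixed model

```
abundance ~ timepoint,  random = ~1 | subject
```

with timepoint as an unordered factor referenced at the pre-surgery
baseline, so every post-surgery month gets a "pre-vs-post" coefficient
even when subjects miss visits. Each (feature, month) contrast is reduced
to a **signed log10 p-value**: `sign(beta) * -log10(p)`. Two contrasts —
from two studies (between) or two months of one study (within) — are then
compared by Spearman rank correlation of their signed log10 p-values over
shared features, with Benjamini–Hochberg control across all comparison
pairs and a Wilcoxon rank-sum contrast of between- vs within-study
coefficients.

Around this core the package provides:

* community-level structure: Bray–Curtis distances, principal-coordinates
  ordination, PERMANOVA with the sequential design
  `distance ~ study * timepoint` (pre vs pooled post), Shannon diversity;
* supervised transfer validation: LASSO or random-forest classifiers of
  surgical status (8-fold × 10-repeat cross-validation with subject-grouped
  folds), study-to-study model transfer with frozen feature
  standardization, and leave-one-study-out (LOSO) validation, all scored
  by AUROC on across-model averaged predictions;
* a fixed-panel scan (e.g. opportunistic pathogens) with per-study FDR;
* a synthetic multi-study generator with planted, partially shared
  log10-scale effects (`rho_between` controls cross-study sharing),
  subject random intercepts, study batch effects, unbalanced retention,
  and multinomial counts at lognormal depths.

## Worked example

```r
library(rygbsig)

cfg <- synthetic_config(n_studies = 2, n_subjects_per_study = 30,
                        n_features = 150,
                        timepoints_per_study = list(c(0, 6), c(0, 6)),
                        retention_prob = 1, pi_signal = 0.4,
                        tau_effect = 1.2, rho_between = 1,
                        sigma_study = 1.5, sigma_subject = 0.5,
                        sigma_noise = 0.4, depth_log_mean = log(5e4),
                        seed = 1)
sim <- simulate_multistudy(cfg)

sigs <- lapply(sim$studies, function(s) {
  nt <- prevalence_filter(normalize_depth(s$table), 0.10)
  signature_scan(nt, s$meta)
})

pair <- enumerate_pairs(list(S1 = 6, S2 = 6))
correlate_pair(sigs$S1, sigs$S2, pair[1, ])
#>   study_a timepoint_a study_b timepoint_b    kind n_shared       rho            p
#> 1      S1           6      S2           6 between       45 0.5742144 3.717355e-05
```

The two simulated cohorts carry one identical planted signature
(`rho_between = 1`) but independent batch effects, subjects, and counts;
over the 45 features that survive both studies' prevalence filters, their
signed log10 p-value signatures correlate at Spearman rho = 0.57 with
p ≈ 4e-05 — the shared signature is recovered despite the batch effects.
The acceptance suite sweeps `rho_between` over {0, 0.3, 0.6, 0.9, 1} (10
seeds each) and checks that the recovered between-study rho rises
monotonically from ≈ 0 to ≈ 0.7.

The full analysis (simulation → scan → concordance → ordination/PERMANOVA →
ML transfer) is scripted as numbered drivers:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_signature_scan.R
Rscript analysis/03_concordance.R
Rscript analysis/04_community.R 1
Rscript analysis/05_transfer.R 1        # slow stage (several minutes)
```

Each driver prints what it found and writes TSV/JSON tables under
`results/`. `run_pipeline(run_config(...))` runs the same stages
programmatically. The methods vignette
(`vignettes/cross-cohort-concordance.Rmd`) documents the model, the
generator, and every numerical choice.

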