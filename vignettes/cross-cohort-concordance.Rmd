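---
title: "Cross-cohort concordance of post-surgical microbiome signatures: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-cohort concordance of post-surgical microbiome signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The scientific problem

Longitudinal microbiome studies of Roux-en-Y gastric bypass each report
taxa that shift after surgery, but individual reports disagree. Two
obstacles make naive comparison meaningless: (i) study-level batch effects
(extraction, primers, population) dominate compositional variation, so
abundances cannot be pooled directly; and (ii) cohorts sample different
months after surgery, with subjects missing visits. `rygbsig` addresses
both by analyzing every study separately with one fixed model and then
comparing *statistical signatures* — not abundances — across studies.

# The per-study model

Counts are depth-normalized per study as
$\log_{10}(c_{fj}/N_j \cdot \bar N + 1)$, where $N_j$ is sample $j$'s total
count and $\bar N$ the study's mean depth. Zeros map to zero exactly, and
with equal depths the transform reduces to $\log_{10}(c+1)$. The mean depth
is computed *within* each study: studies are normalized independently
before any comparison, so one study's sequencing effort never leaks into
another's scale. Features present (value > 0) in fewer than 10% of a
study's samples are removed; removal is strict ("less than"), so a feature
at exactly the threshold is kept. The filter is applied per study — the
pipeline's comparisons are pairwise over shared features, so a feature
rare in one cohort simply drops out of that cohort's signature rather than
being censored globally.

Each retained feature is fit by REML with `nlme::lme`:

$$y_{ij} = \beta_0 + \textstyle\sum_t \beta_t\,1[\mathrm{time}(j)=t] + u_i + \varepsilon_{ij},
\qquad u_i \sim N(0,\sigma_u^2),\ \varepsilon_{ij} \sim N(0,\sigma_e^2)$$

with timepoint as an unordered factor referenced at the pre-surgery
baseline. A mixed model rather than paired tests because subjects do not
attend every visit; the subject intercept $u_i$ absorbs each person's
baseline microbiome. Two-sided p-values use $t=\beta_t/se_t$ with
$df = n_{obs} - n_{subjects} - (n_{timepoints}-1)$. This df convention is a
fixed choice, not an inference; downstream concordance is rank-based, so
modest df differences are immaterial, but tests need a pinned convention.
If the mixed fit does not converge it is refit with $\sigma_u$ fixed at 0
(ordinary least squares) and flagged, rather than dropped — keeping feature
sets comparable across studies. Features with a zero-variance response are
flagged degenerate and kept as missing rows; they are excluded pairwise in
concordance, never globally.

The signature statistic is the signed log10 p-value
$s = \mathrm{sign}(\beta)\cdot(-\log_{10}\max(p, 10^{-16}))$. The floor
$10^{-16}$ keeps $s$ finite while preserving ordering near double
precision.

# Concordance

Two contrasts are compared by Spearman correlation of $s$ over the
intersection of features with non-missing statistics in both; pairs with
fewer than three shared features are flagged rather than reported. The
correlation p-value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ uniformly — no exact small-n branch —
because the statistic of record is $\rho$; p enters only FDR flagging.
Benjamini–Hochberg control is applied jointly across all comparison pairs
of a run (one family). The between- vs within-study contrast uses the
Wilcoxon rank-sum test, exact by enumeration when both groups have ≤ 20
coefficients and no ties, otherwise the tie- and continuity-corrected
normal approximation. Summaries report the *sd* of coefficients (labelled
as such, since "±" is ambiguous in prose).

For heatmap display, the feature × (study, month) matrix of $s$ is
clustered agglomeratively with Euclidean distance and complete linkage;
missing entries are imputed as 0 ("no evidence") *only* for clustering —
correlation always uses pairwise-complete features. Complete linkage is a
fixed choice recorded in the output metadata; average linkage gives
visually similar trees on this kind of matrix, but one convention must be
pinned.

# Community-level analyses

Bray–Curtis distances are computed on the per-study log10-normalized
tables joined over the feature union (absent features = 0, consistent with
zero counts). Two all-zero samples are defined to be at distance 0. PCoA
is classical scaling: Gower double-centering of $-d^2/2$, eigendecomposition,
axes ordered by eigenvalue; negative eigenvalues are reported but carry no
coordinates, and the proportion explained is over positive eigenvalues
only. Plain (unconstrained) ordination is used; a constrained-capable
ordination run without constraints is the same thing.

PERMANOVA partitions the Gower-centered inner-product matrix with
sequential (Type I) sums of squares in the order study, timepoint,
study:timepoint — the order implied by `distance ~ study * timepoint` —
with timepoint coded pre (month 0) versus post (all positive months
pooled). The permutation null permutes sample labels freely; the
repeated-measures structure is deliberately not restricted (subject-level
exchangeability is noted in the output metadata as a caveat; restricting
permutations within subject would test a different hypothesis). p-values
use the add-one rule $(1+\#\{F^* \ge F\})/(1+n_{perm})$ with
$n_{perm}=999$ by default, so p is never 0. An exhaustive mode enumerates
all $n!$ permutations for $n \le 7$; the test suite uses it to check the
Monte-Carlo branch against brute force.

Shannon diversity is $-\sum p\ln p$ (natural log) on raw counts via
`vegan::diversity`.

# Supervised transfer validation

Classifier inputs are genus-style relative abundances (depth normalization
is not used in this branch): zero-variance features are removed,
abundances are log10-transformed after a pseudocount of $10^{-5}$, and
standardized feature-wise as z-scores. The z-score parameters are *frozen*
on the training study and applied unchanged to any external study, with
features matched by ID and absent features imputed as relative abundance 0
before the transform — so external data can never influence the
standardization.

Within-study performance uses 8-fold cross-validation with 10 repeats.
Folds are grouped by subject: all samples of a subject share a fold, since
a person's pre and post samples are not independent and splitting them
across train and test would leak identity. The source workflow this
mirrors does not state its fold-blocking; blocking is the safer choice and
the leakage property is asserted in the tests. One model is trained per
fold × repeat, giving an ensemble of 80 (a published description of the
same workflow counts "180 models: 8 × 10", which is arithmetically
inconsistent; 8 × 10 = 80 is used). LASSO logistic regression selects its
penalty by inner 5-fold cross-validation maximizing AUROC on a fixed
50-step penalty path (on very small inner folds glmnet falls back to
deviance); random forests use 500 trees and default feature subsampling,
seeded. For transfer, *every* model scores every external sample, scores
are averaged across models per sample, and AUROC (Mann–Whitney, ties ½) is
computed on the averaged scores — averaging scores, not per-model AUROCs,
which differs and is asserted by test. Leave-one-study-out pools the
remaining studies (each converted to relative abundances first), refits
the transform and the ensemble on the pool, and scores the held-out study.

# The synthetic generator

The generator exists so that every stage has a ground truth. One master
seed deterministically spawns a planting seed and per-study simulation
seeds, making whole runs bit-reproducible. Per study $s$ and feature $f$:

* global baseline log10 means $\mu_f \sim N(0, 1.5^2)$ — this spread
  yields the realistic rank-abundance skew where a minority of taxa
  dominate and many hover near the detection limit;
* study offsets $a_{sf} \sim N(0, \sigma_{study}^2)$ — the compositional
  batch effect;
* subject intercepts $u_i \sim N(0, \sigma_{subject}^2)$;
* planted effects: a fraction `pi_signal` of features receives a shared
  effect $\delta_f \sim N(0,\tau^2)$ and each study's effect is
  $\delta_{sf} = \rho\,\delta_f + \sqrt{1-\rho^2}\,\eta_{sf}$,
  $\eta_{sf}\sim N(0,\tau^2)$, so `rho_between` tunes cross-study sharing
  ($\rho=1$: one signature; $\rho=0$: independent signatures). Effects are
  *persistent across post-surgery months* — the planted shift is a lasting
  state change, matching the observed pattern that responding taxa remain
  shifted at later visits. (Independent per-month draws would make two
  months of the same study as discordant as two different studies, which
  is not what real post-surgical cohorts show.) Marginally each effect is
  still $N(0,\tau^2)$;
* a sample at month $t$ has unnormalized log10 abundance
  $\mu_f + a_{sf} + \delta_{sf}\,1[t>0] + u_i + e_{jf}$,
  $e \sim N(0,\sigma_{noise}^2)$; the composition is the base-10 softmax
  over features and counts are multinomial at a lognormal depth. The
  lognormal per-sample noise provides overdispersion on top of the
  multinomial — the simplest mechanism with both compositional and
  dispersion structure (no negative binomial needed);
* every subject is sampled at baseline and at each post month
  independently with probability `retention_prob`, emulating unbalanced
  longitudinal attrition. Subjects are never shared across studies and
  sample IDs are globally unique (`study_subject_month`).

The default configuration mirrors a four-cohort 16S meta-analysis design:
baselines of 30, 25, 19 and 9 subjects; post months {1,6}, {3,12,24}, {6},
{6,12} (which yields exactly 23 between-study and 5 within-study
comparison pairs); retention 0.6; `pi_signal = 0.2`, `tau_effect = 1`,
`rho_between = 0.6`, `sigma_study = 2` (batch effects dominate, as in real
multi-cohort ordinations), `sigma_subject = 0.5`, `sigma_noise = 0.8`,
mean depth 2×10⁴. No effect-size distribution is available for the real
signature, so `tau_effect` and `pi_signal` are calibration choices, not
estimates.

What the generator does *not* emulate: read-level sequence data,
taxonomy, phylogenetic structure, strain dynamics, or zero-inflation
beyond what the multinomial and the abundance skew produce. Passing tests
on it demonstrate that the pipeline recovers planted cross-study structure
under realistic unbalance, batch effects and sparsity — not that any
particular real taxon behaves as reported.

One property of the generator deserves flagging: because planted effects
shift the softmax denominator, strong dense signatures slightly depress
all null features after surgery in every study (a genuinely compositional
artifact). It inflates between-study concordance at `rho_between = 0` by
roughly +0.05 under the strong-signal conditions below — small, but the
reason the null-concordance check uses a band rather than zero.

# Study conditions used by the test suite

Chosen once for adequate power at desk scale; stated here as the package's
simulation design.

* **Signature recovery / concordance monotonicity**: 2 studies × 30
  subjects, 150 features, months {0,6}, full retention, `pi_signal = 0.4`,
  `tau = 1.2`, `sigma_study = 1.5`, `sigma_noise = 0.4`, depth 5×10⁴, 10
  seeds per `rho_between` in {0, 0.3, 0.6, 0.9, 1}. The denser, stronger
  signature is what "strong effects" means here: with 20% sparse signals
  the rank-correlation ceiling over all shared features is ≈ 0.4 even at
  perfect power (which is, incidentally, about where the real 16S
  between-study coefficients sit).
* **Within > between**: 4 such studies with months {0,1,6} and
  `rho_between = 0.6`, retention 0.8, 120 features, 25 subjects, 10 seeds.
* **Null calibration**: single-study null cohorts (`pi_signal = 0`), 16
  subjects, months {0,1}, 500 features × 10 seeds for the LMM; 500
  datasets of 20 exchangeable samples (10 vs 10) at 199 permutations for
  PERMANOVA.
* **Transfer**: 4 studies × 40 subjects, 80 features, months {0,6},
  `pi_signal = 0.3`, `tau = 2`, `rho_between = 1`, full retention — LOSO
  with the full 8 × 10 ensembles; the label-permutation null shuffles
  count columns within each study. 40 subjects keep the null AUROC's
  sampling sd near 0.065 so chance performance is identifiable.

# Degenerate inputs and numerical conventions

Zero-depth samples are errors (they carry no information and break the
normalization). All-zero features survive simulation but become degenerate
fits, flagged and excluded pairwise. Bray–Curtis between two empty samples
is 0 by convention; empty vs non-empty is 1. PERMANOVA refuses constant
terms and saturated designs. BH is `stats::p.adjust`; Wilcoxon is
`stats::wilcox.test` behind the branch rule above, with the all-tied
zero-variance case defined as p = 1. Hierarchical clustering ties are
broken by input order via the fixed dissimilarity ordering. All result
writers emit `#` header comments with the package version and a config
hash; rerunning any stage with the same config and seed is bit-identical.

# Known limitations

* Free permutation in PERMANOVA ignores the repeated-measures structure;
  with strong subject effects its timepoint p-values are anticonservative
  relative to a subject-restricted scheme.
* The LMM assumes Gaussian residuals on the log10 scale; for very sparse
  features this is coarse (no zero-inflated or count-likelihood models are
  provided, by design).
* No meta-analytic pooling of effect sizes: the package quantifies
  concordance, it does not estimate a pooled effect.
* No rarefaction, CSS/TMM, CLR, UniFrac, or constrained ordination; no
  BIOM/FASTQ readers — tables are plain TSV.
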