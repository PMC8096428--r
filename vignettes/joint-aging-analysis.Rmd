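---
title: "Methods: joint mRNA-protein aging trend, concordance and mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint mRNA-protein aging trend, concordance and mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agetrends)
```

# The analysis problem

A cross-sectional aging cohort measures the same tissue on two platforms:
RNA-seq counts and multiplexed MS proteomics, across three age groups and
both sexes. Three questions drive the analysis: (1) which features change
with age on each platform, (2) do the directions of change agree between
mRNA and protein, and (3) are protein changes transcriptionally mediated —
i.e. explained by the corresponding mRNA — or do they arise independently,
for example through translation or degradation? This vignette documents the
models, their assumptions, the tunable parameters, and the design decisions
behind the package.

# Trend tests

## Age coding

Age groups 6, 12, 18 months are coded (−0.5, 0, 0.5). The coded variable
spans exactly one year, so a slope per coded unit is a slope per year, and
for the count model the natural-log slope divided by ln 2 is a log2 fold
change per year. A linear trend with one degree of freedom is more powerful
than a 3-level categorical test for monotone change and still detects
nonlinear changes with a net direction; with only three time points, richer
nonlinear models are not identifiable.

## Counts: negative binomial GLM

Per gene, `nb_trend_lrt()` fits a log-link NB GLM with a log size-factor
offset under the full (`~ sex + batch + age_coded`) and reduced
(`~ sex + batch`) models and reports the 1-df likelihood-ratio statistic.
Size factors come from `median_ratio_size_factors()`, the median-of-ratios
estimator (median over all-nonzero genes of the ratio to the gene's
geometric mean, rescaled to geometric mean one).

The dispersion is a single gene-wise maximum-likelihood estimate obtained
under the full model and shared by both fits, so the two log-likelihoods are
computed on the same NB family and the LRT is non-negative by construction.
We deliberately use no empirical-Bayes dispersion shrinkage: with ~60
animals per age group the gene-wise estimate is stable, and shrinkage
couples genes in a way that complicates the property-based validation this
package relies on. Underdispersed or constant rows push the ML dispersion
to zero; the estimate is clamped (theta at most 1e8), where the NB fit
degenerates smoothly to Poisson — this limit is also the test suite's
oracle, which checks the LRT against an independently coded Poisson IRLS
fit. All-zero rows and non-convergent fits are flagged (`fit_flag`),
excluded from the multiple-testing family, and never silently dropped.

## Protein: random-intercept linear mixed model

Protein abundances are rank-normal transformed per feature, then fitted
with a random-intercept LMM: fixed sex and age trend, random intercepts for
the MS labeling tag (~16 levels) and the breeding generation (~5 levels).
`fit_lmm_ml()` directly optimizes the profiled log-likelihood over the
variance ratios `gamma_k = var_k / sigma²`: for fixed ratios the GLS
estimate of the fixed effects and the ML residual variance are closed-form,
and Woodbury identities keep every evaluation at the dimension of the
random-effect levels rather than the sample count. Both models of the LRT
are fitted by ML, not REML — REML likelihoods are not comparable across
fixed-effect structures, so an REML-based LRT for a fixed effect is invalid.
The boundary `gamma = 0` is explicitly evaluated (the optimizer can miss
it), and boundary solutions are valid results flagged `"boundary"`. Because
the ratios can also be *fixed*, the OLS limit (`gammas = c(0, 0)`) is an
exact degenerate case used in the tests, and lme4's ML fits serve as an
independent cross-check rather than as the implementation.

The focal-term standard error uses the ML residual variance; with ~188
samples and 3–4 fixed coefficients the ML/REML difference is below 2% and
immaterial for the z-scores. Protein slopes are reported on the rank-normal
scale; no back-transform to a natural unit is attempted.

## Multiple testing and power

`holm_adjust()`/`bh_adjust()` validate inputs and delegate to the standard
step-down/step-up algorithms (`stats::p.adjust`); the tests pin them to
hand-stepped small vectors and to the dominance property BH q ≤ Holm p.
`trend_power()` is the design calculation: for contrast coefficients
c = (−0.5, 0, 0.5) the noncentrality is
`effect_sd · Σc² / sqrt(Σc²/n)` and the two-sided normal-approximation
power at n = 64/group, effect 0.5 SD, alpha 0.05 is 0.807 — the ~0.80 the
cohort was sized for.

# Concordance

Effect sizes on the two platforms have incomparable units, so both are
reduced to z = estimate/SE. Genes with BH q below the threshold (default
0.1, a deliberately liberal FDR chosen to admit enough genes for the joint
classification) on *both* platforms are partitioned by z signs into groups
A (both up), B (mRNA down/protein up), C (mRNA up/protein down), D (both
down); everything else is NS. When the protein table has several isoforms
per gene, `collapse_proteins()` keeps the smallest raw p per gene, ties
broken by feature ID — the collapse rule is a package decision, recorded
per gene by keeping the chosen feature ID.

# Mediation scan

The scan compares the focal term's LRT p-value between
`Protein ~ Age + Sex + Generation` and `Protein ~ mRNA + Age + Sex +
Generation`, both plain OLS on rank-normal data. This is deliberately
simpler than the LMM used for trend testing: the scan is a within-gene
*comparison* of two nested fixed-effect models, and the tag term is omitted
from both. The statistic is `delta`, the drop in −log10 p. If mRNA mediates
the focal effect, delta is large; if protein change is mRNA-independent,
the two p-values sit on the identity line. `mediation_summary()` reports
the median delta, the fraction exceeding `delta0` (default 0.5, about a
3-fold p-value drop — the analysis has no canonical cutoff, so the summary
is parameterized rather than dichotomized), and the major-axis slope of the
(base, adjusted) cloud, which is 1 when points lie on the identity line.
No formal causal estimands (ACME, bootstrap intervals) are computed: the
procedure is the significance-drop comparison, and conditioning on a noisy
mediator can only demonstrate consistency with mediation, not prove it.

Degenerate cases: an mRNA column collinear with the design is flagged
`rank_deficient`; a protein identical to its mRNA yields an adjusted focal
p of 1 (complete mediation limit).

# Structure tools

**PCA.** `pca_variance()` operates on per-feature rank-normal input —
centering only, no scaling, since rank-normal features already share a
scale and the transform suppresses outliers. Variance fractions come from
squared singular values; each component's sign is fixed by making its
largest-magnitude loading positive, removing SVD sign ambiguity from
outputs. PC–covariate association is a plain F-test of `score ~ covariate`
with age linear and sex categorical.

**Deconvolution.** Markers are selected from reference mean profiles by the
ratio of the top to the second type mean (candidates restricted to genes
whose argmax is the type), with a default minimum ratio of 2 and a cap of
50 markers per type. The cap mirrors common practice in marker-based
deconvolution; the ratio statistic is this package's own definition of
specificity. The "raw" surrogate proportion variable is the first PC of the
per-marker standardized marker × sample submatrix, extracted with *no*
covariate adjustment so the SPV's age trend is estimated independently of
any age model, sign-oriented to the mean marker signal, standardized, and
tested with `SPV ~ age_coded + sex` (BH across types). SPVs are relative
scores, not absolute proportions.

**ORA.** `ora_hypergeometric()` is the one-sided hypergeometric tail for a
user-supplied two-column gene/term annotation — no ontology parsing or
term-hierarchy propagation.

# Urinary phenotypes

Analytes are adjusted for urine concentration before analysis. The default
is the residual method — residuals of log analyte on log creatinine — with
the log-ratio method available since plots of analyte "normalized to
creatinine" conventionally mean the ratio; whether the adjustment should
regress on log or raw creatinine is genuinely underdetermined, and
residual-on-log is the package default. Below-detection values are floored
(half the detection threshold) before the log. `phenotype_mediation_test()`
then reports the age p-value with and without the candidate protein in the
model, plus the sex-adjusted partial correlation; both p-values are
reported and no verdict is forced.

# The synthetic cohort generator

`simulate_cohort()` is first-class, tested code that defines the study
conditions for every downstream validation. It emulates: the observed
age × sex cell sizes (30/31/34 males, 33/31/29 females = 188), a 2-level
RNA batch, a 16-level MS tag, 5 generations, log-normal library-size
offsets (SD 0.3, so size-factor estimation is non-trivial), NB counts with
per-gene dispersion in 0.05–0.2, and one measurement per animal
(cross-sectional, as in the design it mirrors).

Each gene carries a latent per-sample biological signal `u` shared by the
platforms. The protein's latent input is the NB log-mean signal, not the
sampled count, so count noise attenuates but does not destroy within-age
mRNA–protein correlation. Sex effects enter the latent signal for every
gene — sex differences are pervasive and transcriptionally driven in this
generator, which is what makes the sex mediation contrast informative. Age
effects differ by class: concordant/discordant classes give mRNA a direct
(latent-independent) trend and protein a direct trend of the configured
sign; mediated genes put the mRNA trend *into* the latent signal with no
direct protein term, so their true protein slope is exactly
`lambda × mRNA slope`; null genes have no age effect.

The coupling and noise knobs are not pinned by any external measurement, so
they were chosen once on realism grounds and frozen: `lambda = 0.5`,
`bio_sd = 0.4`, `protein_noise_sd = 0.7` give a within-age mRNA–protein
correlation around 0.2 — the weak-but-positive coupling typical of paired
proteogenomic data — and modest median trend significance. Unmediated
mRNA trends default to 0.1–0.4 natural-log units/year while mediated genes
draw 0.5–1.0: transcript trends in bulk tissue are mostly small, and a
transcriptional trend must be strong to drive a detectable protein trend
through `lambda = 0.5`. With these defaults the generator satisfies the
package's own design conditions: median mediation delta above 1 for
mediated genes, near 0 (±0.3) for cohorts of unmediated genes, and trend
tests that recover true slopes with regression slope within 0.8–1.2.

Default gene-class counts total 2000 (200/100/100/200 concordant and
discordant, 200 mediated, 1200 null) — a down-scaled transcriptome chosen
so that a full pipeline run completes in minutes on one core; the class
*mix* matters more than the total, and all counts are configurable.
Validation runs in the test suite use 60–300 gene panels and 2000-feature
null panels, sizes at which Monte-Carlo error is small relative to the
asserted bands.

What the generator does **not** emulate: genetic (founder haplotype)
effects and their correlation structure, peptide-level measurement and
polymorphic-peptide artifacts, count-depth heterogeneity beyond a global
library factor, heavy-tailed protein error, or real annotation structure.
Passing tests therefore demonstrate that the estimators are correct and
calibrated under the generative model they assume — not that real kidney
data satisfies those assumptions.

# Numerical choices

- Rank-normal transform: `qnorm((r − offset)/(n − 2·offset + 1))` with
  mid-ranks for ties; offset 0.5 by default (0.375 gives Blom scores —
  the convention is not pinned by the literature the transform comes from).
  Constant vectors are an error: there is no ordering information.
- LMM optimization: L-BFGS-B on the ratios with lower bound 0, start 0.1,
  plus an explicit evaluation at the all-zero boundary; ratios below 1e−10
  are treated as zero when building the Woodbury factorization.
- NB dispersion clamped to theta in [1e−8, 1e8]; LRTs clamped at 0.
- Gaussian focal-term LRT in the scans: `n·log(RSS0/RSS1)` on 1 df, with
  the 0/0 limit (perfect fits in both models) defined as p = 1.
- Holm/BH ties: `p.adjust` is order-stable; result tables additionally
  carry feature IDs so downstream sorts are reproducible.
- The median-of-ratios estimator is only *approximately* invariant to
  adding a flat gene (the extra ratio of 1 can shift the median by one
  order statistic); the tests assert stability at 5%, not identity.
- Partial correlation with a variable fully explained by the covariates
  returns r = 0 (the residual vector is numerically zero; correlating it
  would amplify machine noise).
- Concordance sign flips: negating every protein z maps A↔C and B↔D;
  negating every mRNA z maps A↔B and C↔D. Both are exercised in the tests.

# Known limitations

- Protein trend estimates have no natural unit; cross-study comparison of
  slopes requires the same rank-normal convention.
- The NB test's plug-in dispersion is slightly anticonservative in very
  small samples; at the design sizes used here (~190 samples) the null
  rejection rate is within 0.05 ± 0.01 empirically.
- The mediation scan conditions on observed (noisy) mRNA, so complete
  mediation still leaves residual focal significance proportional to the
  measurement noise; delta is a comparative, not absolute, measure.
- SPV deconvolution assumes marker expression is cell-type-proportional
  and markers remain valid in the bulk context; it returns relative
  trends, not proportions.
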