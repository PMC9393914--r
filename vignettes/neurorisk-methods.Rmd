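---
title: "Methods: brain-based and polygenic risk scores for depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain-based and polygenic risk scores for depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `neurorisk`, the
assumptions behind them, the choices we made where the methodology is
genuinely open, and what the synthetic-cohort tests do and do not establish
about real data.

## The Regional Vulnerability Index

The RVI asks how closely one person's pattern of regional brain deviations
resembles the group-level case–control pattern for a disorder. Its inputs
are a *reference panel* — one Cohen's *d* per region or tract from an
independent case–control meta-analysis — and a wide table of the cohort's
regional metrics (subcortical volumes in mm³, cortical thickness in mm,
surface area in mm², tract-wise mean diffusivity and fractional
anisotropy).

The score is computed in three steps:

1. **Residualization.** Each regional metric is regressed (OLS) on an
   intercept plus covariates — by default age, age², sex, site, education
   and income — over *all* subjects with complete data for that region.
   Only the mean/SD step below is anchored to the healthy reference;
   fitting the nuisance regression on everyone uses all the information
   about covariate effects and is the default (a healthy-only fit is a
   one-line change via the `covariates` argument if a sensitivity analysis
   needs it).
2. **Healthy-referenced z-normalization.** Residuals are z-scored with the
   mean and standard deviation of the *healthy* subjects only — here
   defined as subjects with no self-reported psychiatric diagnosis who are
   not taking antidepressants. We use the sample SD (n − 1): the healthy
   subset is a sample, not a population. By construction the healthy
   subset then has per-region mean 0 and SD 1, which the test suite
   asserts to 1e-10.
3. **Correlation.** The subject's RVI for a modality is the single Pearson
   correlation between their region-wise z-vector and the panel's *d*
   vector. With the cases-minus-controls sign convention a positive RVI
   means "more case-like". Panels distributed with the opposite convention
   can be negated on load.

`rvi_multi` is the arithmetic mean of the five modality scores. By default
a subject must have all five (`rule = "complete"`); averaging whatever is
available is supported but changes the score's meaning across subjects, so
it is opt-in.

Degenerate inputs are handled conservatively: a subject whose z-vector has
zero variance receives `NA` with a warning (one flat profile should not
abort a cohort run); a region with zero healthy-reference SD, or a panel
with a constant effect vector, is a hard error. Subjects missing any
region of a modality are not scored for that modality — we never compute
the correlation over a per-subject subset of regions, because a
correlation over shifting support is not comparable across subjects.
Panel regions absent from the cohort table must be explicitly dropped
(symmetrically from both vectors); cohort columns absent from the panel
are simply ignored, since the panel defines the score's support.
Hemisphere-split cohort tables are reconciled through a harmonization map
(YAML), with a bilateral-mean rule for two-column regions.

## Polygenic risk scores

The PRS module implements the classical clumping + thresholding pipeline
on GWAS summary statistics and cohort dosages:

* **QC.** Variants are kept when imputation INFO ≥ 0.8 (skipped when the
  column is absent), cohort MAF ≥ 0.005 (MAF = min(f, 1 − f), f = mean
  dosage / 2), and the variant is present in both inputs. Exclusions are
  logged per variant.
* **Allele alignment.** The summary-statistic effect is oriented onto the
  allele the dosage counts: matching orientation keeps β, swapped alleles
  negate it, and a strand flip (base complement) is attempted before a
  variant is dropped as a mismatch. Strand-ambiguous A/T and C/G variants
  are dropped — with effect sizes this small, the frequency-based rescue
  heuristics are not worth the misalignment risk.
* **Clumping.** Greedy, plink-style: visit variants by ascending p (ties:
  position, then id); each unremoved visit becomes an index and removes
  every not-yet-retained variant on the same chromosome within ±250 kb
  with dosage r² ≥ 0.25. LD is computed on the analysis sample's dosages
  by default; an external reference panel can be supplied via
  `ld_genotypes`. Monomorphic variants have undefined r² and are treated
  as unlinked, with a warning.
* **Scoring.** The score at threshold T is the raw weighted sum of
  dosages times aligned effects over clumped variants with p ≤ T, at the
  six standard thresholds (0.001, 0.01, 0.05, 0.1, 0.5, 1). Scores are
  z-scored by the association models downstream, so sum versus
  per-variant average is immaterial to the reported βs; the per-threshold
  variant counts are logged so either is recoverable. Missing dosages
  contribute the variant's mean dosage, keeping scores comparable across
  subjects. Effects are used as given and must be on the additive scale
  (log-odds for binary discovery traits).

The driver reports all thresholds and carries one user-chosen column
(default `pT_0.1`) into the comparison analyses. It never auto-selects the
best-performing threshold: picking the winner inside the same sample that
is then FDR-corrected would be circular.

## Association models and inference

One association = one outcome, one score, one covariate set:

* continuous outcome, no grouping → OLS;
* binary outcome → maximum-likelihood logistic regression;
* continuous outcome with a site grouping factor → linear mixed model
  with a random site intercept, fit by **maximum likelihood, not REML** —
  the AIC ladder compares models with different fixed effects, which is
  only valid for ML log-likelihoods.

The score is z-scored, continuous outcomes are z-scored, binary outcomes
stay on their natural scale; the reported coefficient is therefore a
standardized effect size, invariant (tested to 1e-8) to affine rescaling
of the raw score. Predictor p-values are Wald tests (t for OLS, normal
reference for logistic and mixed fits). Analyses are complete-case
throughout. A grouping factor with a single level degenerates to OLS: a
one-group random-intercept variance is not identifiable, and this keeps
the mixed-model surface usable on single-site cohorts.

FDR control is Benjamini–Hochberg, applied **within each score family**:
by default all outcomes tested against one score column form one family
(each RVI type its own family, the selected PRS threshold its own). The
family rule is an explicit argument because reasonable alternatives exist
(e.g. one family per cohort); the default is the narrowest reading that
still corrects each score's multiple outcomes.

### Explained-variance metrics and the model ladder

ΔR² quantifies what a score adds over the covariate-only null, in
percentage points:

* OLS: difference in R²;
* logistic: difference in McFadden pseudo-R², both models referenced to
  the shared intercept-only log-likelihood — so the difference is exactly
  the score's contribution relative to the covariate null;
* mixed: difference in Nakagawa–Schielzeth marginal R²,
  var(Xβ) / (var(Xβ) + Σ random-intercept variances + residual variance).
  This is the standard referent of "marginal R²"; with a single group it
  reduces to the OLS R² exactly.

The ladder fits M1 (base covariates), M2 (+RVI), M3 (base + genetic PCs +
plate), M4 (M3 + PRS), M5 (M4 + RVI) on the **identical complete-case row
set** — the PRS covariates often add missingness, and AICs are only
comparable on common rows, so rows missing any required column are
excluded from all five fits. AIC is recomputed as 2k − 2ℓ from the stored
parameter count and log-likelihood (the identity is asserted exactly in
the tests), and the contrasts M2−M1, M4−M3, M5−M4, M5−M3 are flagged at
the conventional 2-unit margin.

### Residualized change

For two-wave symptom scores: stage 1 regresses the follow-up score on the
baseline score, sex, age difference, education, income and site (OLS);
stage 2 regresses the stage-1 residuals, z-scored, on each z-scored
baseline score with no further covariates — they were already removed in
stage 1. If the residual SD is below 1e-10 of the follow-up SD (follow-up
fully determined by stage 1, leaving only floating-point noise), all
stage-2 effects are reported as exactly zero rather than as regressions on
numerical dust.

## The synthetic cohort

The generator exists so that every stage can be exercised, calibrated and
audited end to end with known ground truth. Its generative chain:

* **Liability.** Per subject, modality pattern expressions
  `E_m ~ N(0, 1)` and a true genetic score G (dosage-weighted causal
  effects) combine into
  `liability = γ·z(G) + Σ_m λ_m·z(E_m) + site intercept + N(0, 1)`.
  The top `case_fraction` of liability is the lifetime diagnosis. A
  liability-threshold model is the natural generator when the observed
  outcomes are a binary lifetime diagnosis plus skewed symptom counts.
* **Defaults.** λ = 0.5 for mean diffusivity and fractional anisotropy,
  0 for the three cortical/subcortical modalities, γ = 0.3: the signal
  lives in white matter, with a weaker independent genetic contribution —
  the qualitative adult pattern the pipeline should recover.
  `case_fraction = 0.3` (a community lifetime-MDD prevalence), 4 sites
  with SD-0.2 intercepts, and 10% of subjects flagged as medicated (and
  therefore excluded from the healthy reference even as diagnostic
  controls).
* **Brain metrics.** Region r of modality m is
  `covariate effects + E_m · d_r + N(0, 1)` plus small per-site offsets,
  where d is the same panel the scoring step uses. With panel effects of
  SD 0.1 against unit region noise, per-subject profile correlations land
  in a realistic ±0.3 band, and case–control RVI differences match the
  small standardized βs seen in community samples. Covariate confounds
  (age, age², sex, education, income) are injected into the metrics and
  must be removed by the residualization step. The `age2` column is
  stored on a centred, rescaled basis — the same column space as raw
  age², but commensurate in magnitude with the other design columns.
* **Genotypes.** Exchangeable LD blocks (default 5 variants, latent
  haplotype correlation 0.9, giving dosage r² well above the 0.25
  clumping cutoff within blocks and ≈ 0 across), MAF uniform on
  (0.05, 0.5), 25% of variants causal with N(0, 0.1) effects. Summary
  statistics are emitted as causal effect + sampling noise at a
  configured discovery-study size (default 100,000), so p-value
  thresholding behaves as it does with real GWAS output; a fraction of
  rows is emitted with swapped allele orientation and a small fraction
  with strand-ambiguous allele pairs, to exercise the alignment logic.
* **Symptoms.** Negative-binomial counts whose log-mean tracks
  standardized liability, scaled to baseline mean ≈ 1.3 and follow-up
  ≈ 1.6 with SD ≈ 2 — the skewed subclinical range of caregiver/self
  report symptom scales. Wave 2 re-expresses the liability drivers with
  an extra `change_loading` (default 0.2) plus innovation noise, and only
  a `followup_fraction` (default 0.55) of subjects return.

Everything is a pure function of `(config, seed)`; bundles re-written with
the same seed are byte-identical, and the manifest records a config hash
so outputs from different configurations cannot be silently mixed.

### What the tests show — and what they do not

The validation suite runs at deliberately chosen problem sizes: oracle
equivalences on tiny instances (≤ 10 subjects × 6 regions; ≤ 20 variants
against an exhaustive pairwise LD audit, 200 instances); null calibration
with all loadings zero over 600 replicate cohorts of n = 500 with compact
48-variant genotype panels; generative-structure recovery over 100 seeds
at n = 2,000 (white-matter βs must outrank cortical ones in ≥ 95% of
seeds, the AIC ladder must clear its margins, and the PRS β must land
within 2 SE of its variance-bookkept target, i.e. the ground-truth
genetic-score slope attenuated by cor(PRS, G)).

Passing these establishes internal correctness and calibration — not
external validity. The generator draws regions independently given E_m,
so it does not emulate the strong inter-regional covariance of real
morphometry; its LD is block-exchangeable, not a human LD map; there is
no kinship, no ancestry structure (the PC and plate columns are pure
nuisance columns), no scanner/batch artifacts beyond additive site
offsets, and effect sizes enter linearly on the liability scale. Results
on real cohorts additionally depend on all of those, and on the
relevance of the reference panel to the target population — an
adult-derived panel applied to adolescents is an open scientific
question, not something this package can settle.

## Known limitations

* Mixed-model p-values use the Wald normal approximation; with few sites
  and small n they are approximate (the calibration tests use the
  logistic/OLS paths).
* The clumping LD reference defaults to the analysis sample; external
  panel support is a hook (`ld_clump(..., ld_genotypes = )`), not a file
  format.
* `read_genotypes_vcf()` handles bi-allelic GT/DS records; multi-allelic
  records are dropped with a warning.
* No multiple imputation, kinship modelling, survey weights or
  shrinkage-based (LDpred-style) scores — deliberately out of scope.
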