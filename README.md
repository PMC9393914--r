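# neurorisk

Brain-based and polygenic risk scores for major depressive disorder (MDD),
compared within one statistical framework.

Group-level neuroimaging findings (e.g. ENIGMA case–control meta-analyses)
say little about any one person. The Regional Vulnerability Index (RVI)
turns them into an individual-level score: how closely a subject's brain
deviation profile resembles the expected MDD pattern. `neurorisk` computes
RVIs per imaging modality and a multimodal average, computes polygenic risk
scores (PRS) by clumping + thresholding, and compares the two families of
scores as predictors of depressive phenotypes — the workflow a psychiatric
imaging-genetics group needs when asking "does the brain score add anything
beyond the genetic score?". A seeded synthetic-cohort generator with known
ground truth makes the whole pipeline testable without access to restricted
cohort data.

## The scores

**RVI.** For subject *i* and modality *m* with regions *r = 1..R*:

1. regress each regional metric on covariates (age, age², sex, site,
   education, income) over all subjects and keep the residuals;
2. z-normalize the residuals with the mean and SD (n − 1) of the *healthy*
   subjects only (no psychiatric diagnosis, no antidepressants);
3. `RVI_im = cor(z_i, d_m)` — a single Pearson correlation between the
   subject's region-wise z-vector and the meta-analytic case–control
   Cohen's *d* vector (cases − controls, so positive = more case-like);
4. `RVI-Multi = mean(RVI_sub, RVI_corth, RVI_corsa, RVI_md, RVI_fa)`.

**PRS.** After INFO ≥ 0.8 and cohort-MAF ≥ 0.005 filtering, allele
alignment (with strand-flip resolution; A/T and C/G variants dropped) and
greedy LD clumping (clump-p = 1, clump-r² = 0.25, clump-kb = 250):

`PRS_i(T) = Σ_{j: p_j ≤ T} dosage_ij · β_j` at thresholds
T ∈ {0.001, 0.01, 0.05, 0.1, 0.5, 1}.

**Comparison.** Standardized association models (OLS / logistic /
random-intercept mixed by maximum likelihood), Benjamini–Hochberg FDR within
each score family, ΔR² relative to the covariate-only null (McFadden
pseudo-R² for logistic, Nakagawa marginal R² for mixed models), the
five-model AIC ladder

| model | predictors |
|---|---|
| M1 | base covariates |
| M2 | M1 + RVI |
| M3 | base covariates + genetic PCs + plate |
| M4 | M3 + PRS |
| M5 | M4 + RVI |

(AIC = 2k − 2ℓ; drops ≥ 2 units flagged), and a two-stage residualized-change
analysis for two-wave symptom scores.

## Worked example

```r
library(neurorisk)

cfg    <- sim_config(n_subjects = 1000, seed = 42)   # white-matter loadings 0.5, PRS loading 0.3
bundle <- simulate_cohort(cfg)
res    <- run_full_analysis(bundle, prs_threshold = "pT_0.1")

subset(res$associations, outcome == "lifetime_mdd")
#>       outcome predictor    beta     se        p        q    n loglik  k
#>  lifetime_mdd   rvi_sub -0.0530 0.0718 4.60e-01 6.90e-01 1000   -577 10
#>  lifetime_mdd rvi_corth  0.1451 0.0720 4.41e-02 1.32e-01 1000   -576 10
#>  lifetime_mdd rvi_corsa  0.0477 0.0712 5.03e-01 5.03e-01 1000   -577 10
#>  lifetime_mdd    rvi_md  0.3549 0.0744 1.85e-06 5.56e-06 1000   -566 10
#>  lifetime_mdd    rvi_fa  0.2966 0.0729 4.69e-05 1.41e-04 1000   -569 10
#>  lifetime_mdd rvi_multi  0.3245 0.0731 9.14e-06 2.74e-05 1000   -568 10
#>  lifetime_mdd    pT_0.1  0.3831 0.0745 2.73e-07 8.18e-07 1000   -562 18
```

The generator placed the brain signal in white matter only, and the fitted
standardized effects recover exactly that structure: RVI-MD, RVI-FA and
RVI-Multi associate strongly with the lifetime diagnosis (β ≈ 0.30–0.35,
FDR-significant), the cortical and subcortical RVIs do not, and the PRS
(γ = 0.3 in the generator) contributes independently.

```r
subset(res$ladder_contrasts, outcome == "lifetime_mdd" & rvi == "rvi_md")
#>       outcome    rvi contrast delta_aic meaningful
#>  lifetime_mdd rvi_md    M2-M1    -21.57       TRUE
#>  lifetime_mdd rvi_md    M4-M3    -25.46       TRUE
#>  lifetime_mdd rvi_md    M5-M4    -19.01       TRUE
#>  lifetime_mdd rvi_md    M5-M3    -44.47       TRUE
```

RVI-MD improves the covariate-only model by 21.6 AIC units on its own
(M2 − M1) and still improves the PRS model by 19.0 units (M5 − M4): the
brain and genetic scores carry additive information. The residualized-change
table (`res$change`) is null here, as the generator's symptom-change signal
is small relative to this sample size.

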