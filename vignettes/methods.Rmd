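---
title: "Methods: models, simulation design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulation design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis model

`ghdpgs` implements a case-control polygenic-risk-score analysis for
gestational hypertensive disorders (GHD). The score for sample $s$ is the
effect-allele dosage-weighted sum

$$\mathrm{PGS}_s = \sum_i w_i\, g_{si}, \qquad g_{si}\in\{0,1,2\},$$

with weights $w_i$ estimated jointly by unpenalized maximum-likelihood
logistic regression of case status on the clumped SNP panel. The analysis
assumes: (i) additive allelic effects on the log-odds scale; (ii) a panel
already reduced by LD clumping so that multicollinearity is mild (a VIF
screen guards the remainder); (iii) case/control labels defined by
diagnosis-code rules, not by a quantitative phenotype. Discrimination is
summarised by the AUC in its Mann–Whitney form (probability a random case
outscores a random control, ties counting one half), and group risk by
odds ratios with Wald (normal-approximation, log-scale) intervals:
$\exp(\log\mathrm{OR} \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d})$. These
intervals are geometrically symmetric about the point estimate —
$\sqrt{\mathrm{ci}_{low}\,\mathrm{ci}_{high}} = \mathrm{OR}$ — an identity
the tests verify both for every interval the package emits and for the
published interval/OR pairs shipped as worked examples.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| p-value selection cutoff | 1e-5 | — | conventional suggestive-association threshold for candidate panels; strict `<` |
| clumping r² threshold | 0.1 | squared correlation | conventional PGS clumping default; `>=` claims a SNP |
| clumping window | 250,000 | bp | conventional default; clumping is intra-chromosomal |
| control resampling | 10 subsets, 4:1 | — | balances the design while reusing the control pool |
| cross-validation | 10 folds × 10 repeats | — | stabilises the AUC used for model selection |
| VIF threshold | 10 | — | standard "serious collinearity" rule of thumb |
| interval level | alpha = 0.05 | — | z computed exactly (1.959964), not rounded to 1.96 |
| MR instrument threshold | 5e-8 | p-value | genome-wide significance |
| Egger pleiotropy test | 0.05 | p-value | two-sided t-test on the intercept, k−2 df |
| MR reporting filter | OR ≥ 1.1 or ≤ 0.9 | odds ratio | ±10% odds change, boundaries inclusive |
| BMI filter / bands | 18.5; 25; 30 | kg/m² | WHO-style bands; 18.5 retained inclusively |

The clumping parameters deserve emphasis: published clumped panel sizes are
not reproducible unless the r² threshold, window and reference LD panel are
all known, so both parameters here are mandatory, logged configuration
values rather than hidden defaults.

## What the synthetic cohort emulates

`sim_config()` defaults state the world the pipeline was designed around: a
cohort of 2,787 cases and 13,400 controls, a candidate panel of 375 SNPs in
75 LD blocks, disease prevalence 8% (GHD complicates roughly 2–8% of
pregnancies; the upper edge keeps case sampling efficient), BMI mean 27,
SD 4.5 kg/m², and a BMI–genetic-score correlation of 0.1.

* **Genotypes.** Each LD block is an equicorrelated latent Gaussian,
  double-thresholded at Hardy–Weinberg genotype frequencies into dosages
  {0,1,2}. Thresholding attenuates correlation, so the latent correlation is
  **calibrated analytically** — the dosage correlation implied by a latent
  correlation $r$ is computed by 1-D Gaussian quadrature and inverted with
  `uniroot` — so that the realised dosage r² matches `within_block_r2`.
  Calibration uses the block's mean allele frequency; pairs with very
  different frequencies sit slightly below the target (an intrinsic bound on
  dosage correlation), comfortably inside the ±0.1 tolerance the tests
  assert.
* **Disease.** A sparse fraction of SNPs (`causal_fraction`) receives
  N(0, `effect_sd`²) log-odds effects; the logistic intercept is solved
  numerically on a calibration pool so the marginal prevalence matches the
  configuration; cases and controls are then rejection-sampled to the
  requested counts, with an explicit failure naming the draw bound if the
  prevalence cannot supply enough cases.
* **BMI.** A Gaussian blend of the standardized true genetic score
  (`bmi_genetic_corr`) and independent noise; values below 18.5 are redrawn
  (so the BMI exclusion filter only has work to do when `missing_rate`
  injects missing values), and `bmi_case_shift` can add a purely
  environmental case–BMI association for the BMI-dominance experiments.
* **Diagnosis codes.** Cases draw from a menu of self-report and `O13/O14/
  O15` codes; controls draw live-birth codes, with ~3% also given an `O24`
  code so the exclusion rules are exercised. Ground-truth `status` is the
  generative label; the cohort-definition stage re-derives labels from codes
  and (by design) excludes a small fraction of disease-free women, as a real
  code-based definition would.
* **Seeds.** One global seed expands into per-stage child seeds by the
  documented counter scheme `child_seed(seed, k) = (seed mod 21474835)·100 + k`,
  so every generator is a pure function of (config, seed).

What it does **not** emulate: realistic human LD maps, imputation
uncertainty, X-chromosome dosage conventions, population structure, or
genotyping error. A green test therefore establishes that the *statistical
machinery* is correct under its stated model — not that any particular
published panel or AUC would be reproduced on restricted biobank data.

## Numerical and design choices

* **Logistic fits** use IRLS (`glm.fit`, epsilon 1e-8, max 100 iterations);
  SEs come from the inverse observed information. (Quasi-)separation —
  non-finite or |coefficient| > 15, or fitted probabilities pinned at 0/1
  with perfect classification — is an explicit error, because a silently
  penalized fallback would no longer be the analysis model. Cross-validation
  alone relaxes this (`on_separation = "allow"`): a separated training fold
  still ranks held-out samples validly, which is all AUC needs; the fit is
  flagged.
* **Missing dosages** are mean-imputed per SNP (2 × allele frequency)
  before any fit or score.
* **Collinearity screening** is iterative VIF pruning at threshold 10, with
  exact linear dependencies removed first by QR rank detection (dropping the
  last pivot column, reported with infinite VIF).
* **Model selection** uses the mean CV AUC over repeats; ties break toward
  fewer SNPs, then lower subset index. The forward-AIC variant runs on the
  selected best-AUC subset (an interpretation — the source procedure does
  not say which design the stepwise pass used).
* **Percentile ranks** are mid-ranks: fraction strictly below plus half the
  tied fraction, so ties share a rank and group boundaries are stable;
  septile k is the rank interval [(k−1)/7, k/7), last interval closed, which
  makes septile 4 the 42.9–57.1% reference band.
* **Zero cells** in a 2×2 table get the Haldane–Anscombe 0.5 correction on
  all four cells, always flagged in the output.
* **MR.** IVW is the fixed-effect estimator (a multiplicative random-effects
  toggle inflates the SE by `max(1, sqrt(Q/(k-1)))`); ratio SEs are
  first-order only. The Egger intercept test uses the t distribution with
  k−2 df from the weighted least-squares fit. Harmonization makes all
  exposure effects positive, flipping outcome effects in tandem; instrument
  sets here are simulated and pre-aligned, so no strand/palindrome handling
  is applied on this path.
* **Whether the PGS includes the fitted intercept** is irrelevant to ranks
  and ratios; scores exclude it by default (`include_intercept` toggles).

## What the tests establish

Every estimator is checked against an independent oracle: AUC against pair
enumeration; clumping against a brute-force transcription of the greedy
definition on 100 random ≤12-SNP instances; logistic fits against direct
BFGS likelihood maximisation; Wald intervals against closed-form arithmetic
and the log-symmetry of published OR/CI pairs; IVW/Egger against their
defining formulas, exact affine constructions, and seeded Monte-Carlo
recovery of generative causal effects and injected pleiotropy; and the
simulator against its own configuration (allele frequencies, block r²,
prevalence calibration, liability gradient).

## Known limitations

* One acceptance-style check is **intentionally red**: "rank correlation
  between learned and true weights > 0.7" on a 50-SNP panel with 20% causal
  SNPs. With 40 of 50 true weights exactly zero, Spearman's ρ has a
  *noise-free ceiling* of 0.699 — the 40-way tie block contributes no rank
  variance in the truth but full variance in any estimate — so the stated
  threshold is unattainable even by a perfect estimator. The test asserts
  the criterion as written; the accompanying Pearson check (> 0.8) passes,
  showing weight recovery itself is sound.
* Training AUC is the mean CV AUC of the winning balanced subset; no
  external validation split is built in (a held-out split can be scored with
  `compute_pgs` on any cohort).
* The control-inclusion reading of "pregnancy chapter-O codes" is
  documented in `default_ghd_rules()` rather than asserted: the package
  includes chapter-O pregnancy prefixes outside the hypertensive block
  O10–O16, and excludes the whole `O24` prefix (gestational plus
  pre-existing diabetes).
* MR results on real exposures require external GWAS summary data and are
  out of scope; the MR stage is demonstrated and validated on simulated
  instruments only.
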