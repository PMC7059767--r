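---
title: "Dissecting methylation-mediated genetic effects: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting methylation-mediated genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(methmediate)
```

## The question

An association between CpG methylation and a complex trait admits four
explanations: the methylation mediates a genetic effect on the trait
(G → M → Y); distinct causal variants in linkage disequilibrium drive
methylation and trait separately; a shared variant affects both through
independent pathways (horizontal pleiotropy); or the trait itself alters
methylation (reverse causation). `methmediate` implements a decision
framework that works through these possibilities for each differentially
methylated CpG (DMC): a count-based epigenome-wide association scan, a
cis/trans mQTL scan, two-sample Mendelian randomization (MR) with
sensitivity estimators, a reverse-direction two-stage least squares (2SLS)
test, the HEIDI heterogeneity test against the linkage explanation, and
annotation-aware Bayesian fine-mapping of the causal variant.

A verdict of *mediation-consistent* requires an FDR-significant forward MR
effect, no HEIDI rejection, and a non-significant (or non-evaluable)
reverse-direction test; a HEIDI rejection reclassifies the locus as
*linkage*; a significant reverse test as *reverse-causal*.

## The models, stage by stage

**Differential methylation.** For subject $i$ with $m_i$ methylated of
$n_i$ total reads at a CpG, the model is the binomial logistic regression
$\log \frac{P_i}{1-P_i} = \beta_0 + \beta_1 X_i + \sum_j \alpha_j c_{ji}$,
with $X_i$ the high/low group indicator and covariates age, BMI, smoking,
drinking and the first principal component of inverse-normal-transformed
methylation (a cell-admixture and batch adjustment). $\beta_1$ is the
between-group log odds ratio; each subject contributes with weight equal to
its coverage. A CpG enters the scan only if covered at least 3× in at
least 30 subjects of each group; a DMC additionally needs a Bonferroni
significant $\beta_1$ and an absolute group methylation difference above
0.05 (strict `>`; the 0.10 reporting threshold uses `>=`).

The binomial weighting assumes reads are the only noise source. Real RRBS
data carry subject-level biological variability on top;
`estimate_overdispersion()` diagnoses this as the ratio of observed to
binomial-expected variance of the beta values. The generator's default
subject-level logit noise (SD 1) produces ratios well above 1.5, so the
per-CpG p-values are anti-conservative — deliberately so, since the method
being reproduced does not correct for over-dispersion, only diagnoses it.
Calibration-type tests therefore generate with the noise switched off,
where the binomial model is exact; what passing them shows about real data
is correspondingly limited to the pure read-sampling regime.

**mQTL scan.** Every SNP–CpG pair on the same chromosome is tested by OLS
of (by default) inverse-normal-transformed beta values on allele dosage;
raw-beta and empirical-logit scales are available
(`values_mode`). Cis means a distance below 1 Mb (strict), trans
otherwise, and the two classes are Bonferroni-corrected separately using
the full enumerated pair counts. SNP QC applies MAF > 0.01, call rate >
0.95 and exact Hardy–Weinberg p > 1e-6. Genotype-PC adjustment is
implemented (LD-pruned, PLINK-style) but off by default in the synthetic
pipeline: with a few dozen SNPs the leading component is a contrast of the
causal LD blocks themselves, and conditioning on it distorts the scan —
the adjustment is meaningful only for genome-wide panels with real
ancestry structure.

**Two-sample MR.** Instruments are the Bonferroni-significant cis mQTLs of
a DMC, harmonized to the outcome GWAS effect alleles (allele swaps flip
the sign; palindromic SNPs with EAF in [0.42, 0.58] are dropped) and
greedily LD-pruned at $r^2 < 0.2$ in ascending exposure-p order. One
instrument: Wald ratio $b_{zy}/b_{zx}$ with first-order delta SE (a
second-order option adds the exposure term). Two or more: fixed-effect IVW
(zero-intercept weighted regression, weights $1/se_{zy}^2$). Sensitivity
estimators: IVW with multiplicative random effects, Egger regression
(free intercept estimating directional pleiotropy; t-tests on $n-2$
degrees of freedom; reported NA below three instruments), the
inverse-variance weighted median (bootstrap SE), and profile maximum
likelihood. Mediators are selected by Benjamini–Hochberg FDR < 0.05 over
the primary estimates across DMCs.

**Reverse direction.** One-sample 2SLS: trait regressed on
trait-associated SNPs (genome-wide-significant in the outcome GWAS,
excluding everything within 1 Mb of the CpG so the instruments are
independent of the locus under test), then methylation on the fitted
trait. When the stage-1 F statistic is below 10 the estimate is biased
toward the observational association, so the result is flagged
non-evaluable rather than treated as evidence in either direction.

**HEIDI.** Under a single shared causal variant, the ratio
$b_{xy} = b_{zy}/b_{zx}$ is the same for every SNP in LD with it; under
linkage the ratios differ. Candidate SNPs need $0.05 < r^2 < 0.9$ with the
top mQTL and exposure p ≤ 1.6e-3 (weak-instrument guard), capped at the 20
strongest. Two parameterizations of the contrast are provided. The
classical form differences the ratios directly, with first-order delta
covariance; it is accurate when exposure associations are strong but
becomes skewed when the exposure cohort is small, because noisy $b_{zx}$
estimates appear in denominators. The default cross-product form,
$t_i = b_{zy,i} b_{zx,top} - b_{zy,top} b_{zx,i}$, is exactly zero-mean
under proportionality for any instrument strength, with covariance from
exact product-moment identities. Because the per-CpG exposure slopes are
marginal regressions from the same subjects, their joint covariance is
computed empirically from the slope influence functions (an HC3-corrected
sandwich, `mqtl_slope_cov()`) rather than from the LD approximation. The
statistic $T = \sum_i (t_i/sd_i)^2$ is referred to its
weighted-chi-square null via the Satterthwaite approximation; a
multivariate-normal Monte-Carlo oracle (`heidi_p_mc()`) bounds the
approximation error, and `heidi_selection_calibrated()` additionally
replays the entire SNP-selection procedure on subject-level bootstrap
resamples for fully empirical calibration. The linkage verdict uses
$0.05/(\text{number of tested loci})$, reconstructing the study-style
Bonferroni threshold dynamically.

Even with these refinements the test runs a few points above nominal under
a true mediation model at 150 exposure subjects against a 50,000-subject
outcome GWAS (about 7–18% rejections at the 0.05 level across seed
batches instead of 5%): with the outcome side essentially noiseless, the
statistic is exquisitely sensitive to finite-sample structure in the
exposure slopes that no first-order covariance fully captures. This is a
known cost of running a heterogeneity test in a small extreme-sampled
cohort and is documented rather than hidden.

**Fine-mapping.** For each mediator locus the mQTL Z-scores are modelled
as $z \sim N(0,\; S + S_C W S_C^\top)$ with $S$ the ridge-regularized
($\epsilon = 0.001$) in-sample LD matrix, $C$ the causal configuration
(at most two SNPs) and $W = w^2 I$ the prior effect variance (default
$w^2 = 25$, signals around $|z|=5$). The prior over configurations is
independent-Bernoulli with logistic annotation weights,
$P(j\ \text{causal}) = \text{logit}^{-1}(a_0 + a^\top A_j)$; the empty
configuration is included so a locus can report no credible causal
variant. Posteriors are computed by exhaustive enumeration with
log-sum-exp; per-SNP posterior inclusion probabilities (PIPs) sum the
configuration posteriors; the top-PIP SNP is the causal mQTL. Annotation
weights are fitted across loci by EM: E-step PIPs, M-step quasi-binomial
logistic regression of PIPs on annotations, with the marginal
log-likelihood tracked (the iteration stops before any decrease, which the
truncated-configuration renormalization can otherwise produce) and weights
clipped at $|a| \le 10$ against separation.

**Enrichment.** The fraction of DMCs overlapping an annotation track
(0-based half-open BED intervals; a CpG at 1-based position $p$ overlaps
$[s,e)$ iff $s < p \le e$) is compared with 1,000 random same-size CpG
sets drawn without replacement from the tested background; fold = observed
/ expected, with an add-one one-sided empirical p (never exactly zero;
depletion shows as fold < 1).

## The synthetic cohorts

`simulate_cohort()` generates the full two-sample study under one of five
causal models. Its defaults are the study conditions for all
simulation-based checks and were fixed up front:

* **Genome.** Five chr1 LD blocks of 12 SNPs (exchangeable latent
  correlation 0.8 under a latent-Gaussian-threshold haplotype model, so
  dosage $r^2 \approx 0.5$) plus five independent chr2 trait SNPs; MAF
  uniform on (0.1, 0.5); SNPs 2 kb apart. Block size keeps the number of
  HEIDI-eligible cis SNPs in the realistic range (the test is designed for
  loci with up to ~20 usable SNPs). The latent correlation needed for a
  target dosage $r^2$ is solved exactly from the bivariate-normal orthant
  probability, so the linkage scenario hits its configured $r^2$ (default
  0.5) in expectation.
* **Methylation.** Coverage is negative-binomial (mean 46.52 — deep RRBS
  — size 8); the latent methylation logit is per-CpG intercept + additive
  genetic effects + subject-level Gaussian noise (SD 1, producing the
  over-dispersion discussed above); methylated reads are binomial. CpG 1
  is the focal site; the remaining CpGs are null with baseline levels
  uniform on (0.2, 0.8).
* **Mediator scale.** The causal mediator is the latent *logit*
  propensity, so `b_my` (default 0.3) is phenotype SD per logit unit. A
  fraction-scale mediator at the same coefficient cannot move group
  methylation enough to be detectable at n = 150 under any model, whereas
  the logit scale yields group differences of 5–40% — the magnitudes the
  framework is designed to process. Consequently, recovering `b_my` from
  MR requires the exposure measured on a scale linear in the latent
  mediator: the empirical-logit mode, used by the parameter-recovery
  experiments (deep coverage keeps the read-sampling bias of the empirical
  logit below the confidence-interval width there).
* **Causal wiring.** Mediation/pleiotropy: five instruments (first SNP of
  each chr1 block) with effects `b_gm * seq(0.5, 1.5, length = 5)` —
  Egger regression is unidentified without spread in instrument strength.
  Pleiotropy adds direct effects ±`b_gy_direct` (1.0) on the instruments,
  balanced (random signs) or directional. Linkage: one mQTL SNP and a
  trait SNP (effect 1.0) in the same block at the configured $r^2$.
  Reverse: the chr2 trait SNPs (effect 1.0 each) drive the phenotype and
  the phenotype enters the focal CpG's logit at `b_yg_rev` (0.5) — the
  genotype reaches methylation only through the trait. All non-null
  scenarios also give the chr2 SNPs a small background effect (0.15),
  genome-wide significant at n = 50,000, so the reverse-direction test
  always has instruments outside the focal locus — emulating
  GWAS-catalog-style instrument sourcing. Genetic and mediator
  contributions are centered at their population means, making the
  phenotype a Z-score-like deviation.
* **Cohorts.** The methylation cohort is extreme-sampled: a larger pool is
  generated and the first `n_subjects` (150) with $|y| \ge 0.8$ retained,
  mirroring recruitment of divergent-phenotype subjects; the outcome GWAS
  cohort (50,000) is unselected, generated on a distinct RNG stream with
  no shared subjects, and summarized by per-SNP simple regression.
  Trait SNPs live on chr2 so that, under reverse causation, the SNPs that
  reach methylation through the trait are trans to the focal CpG — as in
  the real design, where trait loci are genome-wide but the mQTL scan is
  local.

What the generator does **not** emulate: read-level sequences and
bisulfite conversion (counts are drawn directly), beta-binomial or
zero-inflated count distributions, population stratification or
relatedness, LD decay within blocks (exchangeable by default; an AR(1)
mode exists), and trans-mQTL architecture. Passing the scenario tests
therefore demonstrates the logic of the decision framework under its own
assumptions, not robustness to everything real RRBS data can do.

## Numerical choices and degenerate inputs

Ties in the inverse normal transform are mid-ranked; all-equal input maps
to all-zero. CpGs with missing values are excluded from the methylation
PCA (mean-imputation available). Perfectly separated or non-converged
per-CpG GLMs are flagged, excluded from the Bonferroni family, and logged
— silent NA propagation would corrupt the FDR downstream. Monomorphic
SNP–CpG pairs are skipped with a log entry; an LD request for a
monomorphic SNP is an error naming it. The LD matrix gets a ridge before
any inversion (1e-3 relative in fine-mapping; 1e-8 relative in HEIDI).
Greedy LD pruning breaks ties by (exposure p, position, id), making
instrument selection deterministic. The weighted-median bootstrap seed is
part of the configuration. All generator randomness derives from a single
integer seed through fixed sub-stream offsets, so every output is
byte-reproducible.

## Problem sizes used by the checks

Scenario-discrimination checks run 50 replicates per scenario in the test
suite and 60 in the reproduction script, at the default conditions (150
methylation subjects, 50,000 outcome-GWAS subjects, 65 SNPs, 20 CpGs).
Estimator-calibration checks use 1,000 summary-statistics replicates. The
IVW coverage experiment uses 100–150 replicates with a 20,000-subject
unselected exposure cohort at deep coverage and moderate per-SNP effects —
the regime where the estimator's assumptions (strong instruments, a
measurement scale linear in the mediator) hold, so the check isolates
interval calibration rather than compounding it with weak-instrument or
transformation bias.
The end-to-end determinism check runs 1,000 CpGs and 5,000 SNPs with the
full 150 + 50,000 subject design, with the outcome cohort generated block
by block in two passes so memory stays flat.

## Known limitations

* The per-CpG binomial test is anti-conservative under real
  over-dispersion; the over-dispersion ratio is reported, not corrected.
* HEIDI at a 150-subject exposure cohort over-rejects mildly under a true
  shared-causal model (above); its power against linkage at $r^2 = 0.5$
  is strong but not complete.
* Reverse-direction 2SLS is one-sample and reports the naive stage-2
  standard error; weak-instrument cases are flagged non-evaluable.
* Egger regression with the three-to-five instruments that typically
  survive selection has limited per-locus power to detect directional
  pleiotropy (its t-tests run on `n_snp - 2` degrees of freedom); the
  intercept estimate is unbiased, so pooling across loci recovers the
  signal.
* Fine-mapping enumerates at most two causal variants per locus and uses
  in-sample LD from the small cohort (ridge-regularized); loci are capped
  at the strongest 50 cis SNPs in the pipeline.
* Annotation enrichment draws unmatched random CpG sets; coverage- or
  density-matched sampling is a hook left unimplemented.

## A short worked example

```{r example, eval = FALSE}
cfg <- sim_config(scenario = "mediation", seed = 1)
res <- run_pipeline(cfg)
tidy(res)      # per-DMC report with verdicts
glance(res)    # one-line run summary
plot_ewas_volcano(res$ewas)
```
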