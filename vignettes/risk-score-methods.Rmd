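---
title: "Methods: construction and evaluation of methylation, genetic and environmental risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: construction and evaluation of methylation, genetic and environmental risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrisk)
options(bcrisk.quiet = TRUE)
```

# Scope

`bcrisk` implements the three score families used to stratify
breast-cancer risk from baseline blood samples in nested case–control
studies — a quartile-counting methylation risk score (MRS), a
weighted-allele genetic risk score (GRS) with explicit SNP quality
control, and coefficient-table environmental risk scores (ERS) — together
with the statistical evaluation such studies report: quartile odds
ratios, OR per SD, AUC, repeated cross-validation and calibration. A
synthetic cohort generator with planted effects closes the loop so that
every stage can be exercised and verified without access to cohort data.

Array preprocessing is out of scope: the package starts from a
beta-value matrix (values in $[0,1]$), a dosage matrix (values in
$[0,2]$), and tabular covariates. Leukocyte-composition deconvolution is
likewise not implemented; leukocyte fractions enter only as adjustment
covariates and the generator draws synthetic ones directly.

# Methylation risk score

For each panel CpG $j$ the 25th and 75th percentiles $Q1_j, Q3_j$ of the
beta-value distribution **among controls only** are computed
(`controlQuartiles()`), excluding missing cells per CpG
(per-CpG complete case). A sample's score is

$$\mathrm{MRS}_i \;=\; \#\{j \in \text{hyper}: \beta_{ij} > Q3_j\}
\;+\; \#\{j \in \text{hypo}: \beta_{ij} < Q1_j\},$$

where the hyper/hypo direction is the previously reported direction of
association carried by the CpG panel.

Decisions the definition leaves open, and how they are resolved here:

* **Quantile rule.** Linear interpolation between order statistics
  (`stats::quantile` type 7), the most widespread convention; the type is
  configurable and recorded in the score's provenance.
* **Ties.** "In the upper quartile" is read strictly: $\beta = Q3$ does
  not count. Strict inequalities are conservative and deterministic.
* **Missing cells** are skipped, not imputed; `nFeaturesUsed()` reports
  how many panel CpGs actually contributed per sample so that
  low-coverage samples can be filtered. Scores are not rescaled by the
  number of available CpGs — the raw count is the score.
* **Thresholds** are computed after probe filtering on the analysis
  sample's own controls, matching the nested design in which no external
  reference distribution exists.

Probes missing in more than 10% of samples (strictly) are removed before
scoring (`filterProbes()`); cells with detection $p > 0.01$ are set
missing at read time when a detection-p matrix is supplied. CpGs with
fewer than 4 non-missing control values cannot support quartiles and are
flagged unusable rather than scored.

The per-CpG association scan (`cpgAssociationScan()`) fits one
unconditional logistic regression per CpG (beta as continuous exposure,
typically adjusted for age, batch and leukocyte fractions) and applies
Benjamini–Hochberg step-up adjustment across all CpGs that produced a
p-value; non-convergent or degenerate fits are flagged and excluded from
the BH family size.

# Genetic risk score

The score is the linear form $\mathrm{GRS}_i = \sum_k \beta_k X_{ik}$
over the intersection of the genotype matrix and the supplied weight
table. QC mirrors standard polygenic-score practice:

* **Missingness filter:** SNPs missing in strictly more than 10% of
  samples are excluded.
* **MAF filter:** minor allele frequency strictly below 1% excludes a
  SNP; MAF is $\min(f, 1-f)$ with $f$ = mean dosage / 2 over non-missing
  cells. A SNP at exactly 1% survives.
* **LD pruning:** among same-chromosome pairs within 250 kb with
  **both** $D' \ge 0.95$ **and** $r^2 > 0.8$, the member with the smaller
  $|\beta_k|$ is dropped (preserving score variance; ties broken by
  dropping the lexicographically larger id), iterated to a fixed point.
* **Surrogate search:** for a missing target SNP, the candidate
  maximizing $r^2$ subject to $D' \ge 0.95$, $r^2 > 0.8$, MAF $\ge$ 1%,
  distance strictly below 250 kb and missingness strictly below 10% is
  returned from a local reference genotype set. In-sample LD is the
  default reference; no web proxy service is consulted.

$D'$ and $r^2$ are estimated by maximum likelihood with a two-locus EM
over unphased hard genotypes (fractional dosages are rounded to
$\{0,1,2\}$ for LD only). Only the double heterozygote is
phase-ambiguous; the E-step splits it between the $AB/ab$ and $Ab/aB$
phases in proportion to their current haplotype-frequency products.
Convergence is declared when the largest haplotype-frequency change
falls below $10^{-10}$, capped at 1000 iterations; at least 20 jointly
non-missing samples are required. A monomorphic locus leaves $D'$ and
$r^2$ undefined; both are reported 0 with a flag. The implementation is
verified in the test suite against a grid search of the multinomial
likelihood (which uses the fact that at the MLE the allele frequencies
equal the observed allele counts, leaving a single free parameter).

Allele orientation is resolved against the weight table at read time:
dosages are flipped $d \to 2-d$ when the stated effect allele is the
file's other allele, and SNPs whose allele pair matches neither
orientation are dropped with a warning. Multi-allelic VCF records are
rejected rather than guessed at. Sporadically missing dosages are
replaced by the SNP's mean dosage over non-missing samples (expected
dosage), the standard choice that keeps all samples scoreable;
`nFeaturesUsed()` records how many SNPs were not substituted.

# Environmental risk scores

Published ERSs reduce to a linear predictor over categorized covariates.
The engine deliberately separates machinery from data: a score is a YAML
`ErsCoefficientSpec` listing one rule per variable — continuous
(`beta` per unit, optional centering) or categorical (sorted breakpoints
defining half-open intervals, lower bound inclusive, with one beta per
interval and a mandatory reference beta of 0; or an explicit level→beta
map). Because strictly increasing breakpoints define the intervals,
overlaps and gaps are impossible by construction and are rejected at
validation. An optional inclusion predicate restricts a score to one
stratum of a categorical variable (e.g. an algorithm published for
postmenopausal women only); excluded samples receive `NA` and are
dropped from downstream evaluation with a log message.

The repository ships a worked synthetic coefficient spec
(`ers_synthetic_example.yaml`, matching the generator's planted effects)
and a structural template for a published Spanish case–control score
(`dierssen_sotos_template.yaml`) whose betas are all zero placeholders:
actual published coefficients live in the source publications'
supplements and are intentionally not reproduced here, so no coefficient
can be silently wrong.

Incomplete baseline variables (at most ~5% missing in the motivating
setting) are mean-imputed within case and control groups separately
(`imputeWithinGroup()`), which preserves each group's variable mean
exactly. Imputed means are **not** rounded before categorization; the
half-open intervals make fractional values such as a parity of 1.8
well-defined.

# Evaluation

* **Logistic fits** (`fitLogistic()`) run IRLS via `stats::glm.fit`
  followed by explicit Newton polishing until the step's largest
  coefficient change falls below $10^{-12}$ (25-step cap). The polish
  matters because IRLS stops on deviance change, which is quadratic in
  the coefficient error: without it, closed-form identities (the 2×2 OR
  equals the cross-product ratio) hold only to ~$10^{-8}$, with it to
  ~$10^{-12}$. Wald 95% intervals are $\exp(\hat\beta \pm 1.96\,
  \mathrm{se})$. Aliased (linearly dependent) columns are dropped and
  reported `NA`; complete or quasi-complete separation is flagged
  ($|\hat\beta| > 15$ or se $> 100$) and no odds ratios are reported for
  such fits. Profile-likelihood intervals are not used.
* **Quartile odds ratios** (`quartileOr()`) bin all samples by the
  25/50/75th percentiles of the **control** score distribution, lower
  bins closed on the right (Q1 $\le e_1$ < Q2 $\le e_2$ < Q3 $\le e_3$ <
  Q4), lowest bin as reference. Unadjusted indicator ORs equal the
  per-bin cross-product ratios exactly. A score constant among controls
  has degenerate edges and is an error; an empty bin yields a flagged,
  omitted OR.
* **OR per SD** standardizes by the SD over the whole analysis sample
  (cases + controls); controls-only SD is available as an option.
* **AUC** (`computeAuc()`) is the Mann–Whitney estimator with ties
  counted ½, with a DeLong 95% interval (via pROC). A constant score
  returns exactly 0.5 with a degenerate interval.
* **Cross-validation** (`crossValidate()`) uses stratified fold
  assignment preserving the case:control ratio (plain random partitions
  produce single-class folds at these sample sizes), fits on $k-1$
  folds, pools out-of-fold probabilities, computes one AUC per
  repetition, and summarizes by the mean and empirical 2.5/97.5
  percentiles. Partitions violating the one-case-one-control-per-fold
  guard are redrawn (up to 100 attempts) before erroring.
* **Hosmer–Lemeshow** (`hosmerLemeshow()`) groups by deciles of fitted
  probability with stable-order tie-breaking, uses the two-cell form
  $\sum_g (O_g - E_g)^2 / (E_g(1 - E_g/n_g))$ with $g-2$ degrees of
  freedom, and merges zero-expectation groups downward with a warning.
  At least 3 groups and $n \ge 5g$ are required.
* **Model conventions:** in the crude models ("Model I") methylation
  scores are adjusted for leukocyte composition while GRS/ERS are
  unadjusted; in the mutually adjusted models ("Model II") each score is
  adjusted for the complementary scores plus leukocyte composition
  (`riskScoreReport()` encodes both). Because leukocyte fractions sum to
  1, the most abundant fraction is dropped as the reference before
  adjustment.
* **Follow-up subgroups** (`subsetByFollowup()`) restrict cases by time
  to diagnosis (inclusive $\le$ for the early window, strict $>$ for the
  late window) and always retain all controls.

# The synthetic cohort generator

`simulateCohort()` draws a pool of `poolFactor` × (requested n)
individuals, assigns case status from a logistic model on the weighted
sum of the planted genetic and environmental effects, samples the
requested numbers of cases and controls, and generates methylation
conditional on the sampled status. Defaults mirror the motivating study
design: 101 cases and 263 controls from a 20× pool, women aged 50–75
with the corresponding reproductive/lifestyle covariate profile, uniform
time to diagnosis up to 13.6 years.

Key modelling choices:

* **Methylation** is logit-normal: noise is added on the logit scale and
  inverse-transformed, which respects the $[0,1]$ support of beta
  values. Case shifts (`cpgEffect`, logit-scale units, default 0.015)
  are applied $+$ for hyper and $-$ for hypo CpGs; a CpG-independent
  batch shift (round-robin batches, default 0.05 per batch step on the
  logit scale) is added on top. The default effect size is deliberately
  small: summed over a 60-CpG panel it yields the weak aggregate
  discrimination (AUC in the mid-0.5s, OR per SD near 1.1) that
  motivated this class of studies, rather than an unrealistically strong
  methylation signal.
* **Genotypes** are binomial(2, f) with effect-allele frequencies on an
  even grid over 0.05–0.5 and per-allele log-ORs on an even grid over
  0.03–0.18, the magnitude range of published breast-cancer SNP weights;
  summed over 40 SNPs this puts the GRS near AUC 0.6 and OR per SD
  around 1.5. Optional exchangeable-correlation Gaussian-copula blocks
  create high-LD SNP pairs solely to exercise pruning and surrogate
  search; realistic genome-wide LD structure is a non-goal.
* **Environment**: twelve variables with distributions chosen to mimic
  the baseline table of such a cohort (e.g. age N(61, 6), BMI
  N(27.5, 4.5), 86% postmenopausal, 9% with an affected first-degree
  relative) and planted effects that put the true-coefficient ERS near
  AUC 0.58 and OR per SD around 1.3–1.4.
* **Leukocyte fractions** are Dirichlet with six components
  (granulocyte-dominant), standing in for deconvolution-derived
  adjustment covariates without implementing deconvolution.
* **Missingness** is completely at random per data type (defaults 1%
  methylation, 1% genotype, 2% covariate — covariates only for the
  variables declared imputable, keeping them under the ~5% bound the
  imputation rule assumes).
* **Case sampling** is by rejection from the large pool rather than
  retrospective inversion — transparent, and exact for the logistic
  outcome model; an infeasible demand errors with advice to enlarge the
  pool. The true latent risk is written to a truth table used only by
  recovery tests, never by the pipeline, and is excluded from the run
  manifest.

What the generator does **not** emulate: probe-level measurement error
structure of arrays, cell-composition-driven confounding of methylation,
realistic LD beyond the copula blocks, non-logistic disease models, and
informative missingness. Passing tests therefore demonstrate
correctness of the algorithms under the stated statistical model, not
performance on any real cohort.

# Reproducibility and problem sizes

All randomness flows from one master seed through named substreams
(`substreamSeed()`), so re-running a stage reproduces exactly the draws
it saw inside the full pipeline, and whole runs are bit-identical given
the seed. The test suite verifies the statistical properties at sizes
chosen to keep the full suite under a few minutes on one CPU: parameter
recovery on 100 cohorts of n = 1000; null calibration of the
Hosmer–Lemeshow test on 200 fitted models of n = 1000; cross-validated
AUC on 200 no-signal cohorts of n = 300; LD estimation against a
grid-search oracle on fixed 3×3 genotype tables; and exhaustive
pair-count and cross-product oracles on small instances. The acceptance
script evaluates the pipeline at the motivating study's scale
(n = 364) with 1000 × 10-fold cross-validation.

# Known limitations

* The GRS engine assumes biallelic SNPs; multi-allelic records are
  rejected at read time rather than decomposed.
* Surrogate search uses in-sample (or user-supplied reference) LD; with
  small reference panels the $r^2$ estimates are noisy and the D′
  criterion is conservative.
* The ERS engine covers scores expressible as linear predictors over
  categorized covariates; absolute-risk projection machinery
  (competing hazards, age-interval integration) is out of scope.
* Wald intervals are reported throughout; for very sparse quartile
  cells profile-likelihood intervals would be preferable but are not
  implemented.
* Survival information is used only to restrict cases by time to
  diagnosis; no survival models are fitted.
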