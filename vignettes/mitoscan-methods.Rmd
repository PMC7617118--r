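---
title: "Methods: case-only scanning for mitonuclear interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-only scanning for mitonuclear interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoscan)
```

## The problem and the design

Nuclear and mitochondrial gene products cooperate in oxidative
phosphorylation and most other mitochondrial functions, so particular
pairings of nuclear and mitochondrial alleles ("mitonuclear
combinations") can plausibly modify disease risk. Direct case-control
tests of every mtSNP x nSNP product term are expensive in power. The
case-only design used here exploits a classical identity: if a disease
is rare and the two variants are independent in the source population,
an interaction effect on disease risk shows up as an *association
between the two variants within affected individuals*. mitoscan
therefore treats each selected mitochondrial variant as the phenotype of
a GWAS-style scan across nuclear SNPs in a single cohort, and only then
moves promising combinations into combined-cohort models.

The pipeline has five stages, each an exported function:

1. **Eligibility by power** (`associationPower`, `minimumMtMAF`): which
   mtSNP frequencies give adequate power to see an association of a
   given odds ratio at a given sample size?
2. **Haploid LD pruning** (`pruneMtSNPs`): drop mtSNPs below the
   frequency floor and collapse groups in strong mutual LD
   (pairwise R^2 above a threshold) to one representative.
3. **Case-only scan** (`caseOnlyScan`): per cohort, logistic regression
   of the mtSNP minor-allele indicator on each nuclear dosage plus
   principal components, with Benjamini-Hochberg FDR over *all*
   combinations examined in the run.
4. **Disease-status modulation** (`modulationTest`): in the pooled
   cohorts, does the mitonuclear association differ between affected
   and unaffected individuals (disease x nSNP interaction, mtSNP as
   response)?
5. **Risk interaction** (`riskInteractionTest`,
   `combinationReport`): does the mtSNP x nSNP product term affect
   disease risk (disease as response)?

## Models and their assumptions

All five fits are ordinary maximum-likelihood logistic regressions
(IRLS, deviance tolerance 1e-8, at most 50 iterations). For mtSNP *M*
(haploid 0/1, minor-allele coded), nuclear dosage *G* (0/1/2 minor
alleles), disease *D* and covariates *X*:

* scan: `logit P(M=1) = a + b G + c'X`, report `b`;
* modulation: `logit P(M=1) = a + b G + d D + e (G x D) + c'X`, report `e`;
* risk interaction: `logit P(D=1) = a + m M + b G + e (M x G) + c'X`,
  report `e`;
* marginal disease association: `logit P(D=1) = a + g V + c'X` for a
  single variant V.

The modulation model keeps the disease main effect even though only the
interaction is reported; without it the interaction term is not a
contrast of within-stratum associations. On saturated binary data the
two interaction coefficients equal differences of stratified log
cross-product ratios, which is what the test suite checks against.

The case-only identity requires (i) rare disease and (ii)
mt-nuclear independence in the source population. Population
stratification violates (ii): subpopulations differing in both mtDNA
haplogroup frequencies and nuclear allele frequencies create spurious
mitonuclear associations. The scan therefore adjusts for leading
principal components of the standardized nuclear genotype matrix
(`computePCs`, `addPCs`), and the genomic inflation factor
(`genomicInflation`) plus Q-Q coordinates (`qqData`) diagnose residual
confounding.

## Genotype coding

* Mitochondrial genotypes are haploid 0/1; heterozygous or
  heteroplasmic input calls are set missing at read time, since the
  analysis treats mtSNPs as alleles defining lineages.
* The minor allele is defined *within the analysis cohort* at analysis
  time; dosages count minor alleles (`additiveDosage` flips the stored
  ALT coding when the ALT allele is the major one). A consequence worth
  knowing: a variant whose frequency straddles 0.5 between two sample
  subsets can flip orientation between their analyses, inverting the
  reported odds ratio; the flip is recorded on the dosage object.
* The scan's exposure coding is additive by default — the GWAS
  convention; the coding is not dictated by the design. A dominant
  (carrier) coding is available and is what the closed-form 2x2 oracles
  and the analytic power construction use.
* Per-test missing-data policy is complete-case: a sample missing the
  mtSNP, the nSNP or any used covariate is dropped from that test only.
* Tests in which any observed genotype class falls below
  `minCellCount` (default 5) are skipped (`skipped_low_count`), not
  fitted, to avoid separation artifacts; separation and non-convergence
  in fitted models are reported as statuses, never as numbers.

## Analytic power and its limits

`associationPower` treats the person-level 2x2 table of mt allele x
nuclear minor-allele *carrier* status (carrier frequency
`1 - (1 - maf_n)^2`). Given the margins and the alternative odds ratio,
the cell probabilities are the admissible root of a quadratic
(`solveJointDistribution`), the log-OR variance is `sum(1/(n p_ij))`,
and power is the two-sided normal tail probability; no continuity
correction. `minimumMtMAF` inverts this by bisection (frequency
tolerance 1e-4).

Two honest caveats. First, the carrier dichotomization is a modelling
choice made so the calculation closes in a 2x2 table; the scan itself
is additive. The Monte-Carlo cross-check (`powerExperiment`) therefore
also scans with the dominant coding. Second, under this standard
approximation a power of 0.8 for OR 1.5 at alpha = 5e-8 with n = 2000
and nSNP MAF 0.10 is not reachable at *any* mtSNP frequency (power is
about 0.03 even at MAF 0.5). A published eligibility threshold of
"mtSNP MAF > 0.2" for those inputs is consistent with a considerably
less stringent alpha; at alpha = 0.05 this implementation gives a
minimum eligible MAF of about 0.16. `minimumMtMAF` consequently
reports unachievable targets explicitly rather than forcing a
threshold, and the power subcommand prints results for whatever alpha
the user chooses.

## LD pruning choices

`pruneMtSNPs` computes pairwise haploid R^2 as the squared Pearson
correlation of 0/1 call vectors on jointly non-missing samples
(mitochondria do not recombine, so this is the natural composite
measure), connects pairs with R^2 strictly above the threshold
(default 0.9, matching the "R^2 > 0.9" convention), and keeps one
representative per connected component. The representative rule —
highest MAF, ties by smallest position — is this package's choice; the
selection step it mirrors picked a representative from a linked trio
without stating a rule. Pairs monomorphic on their joint support have
undefined R^2; they are treated as unlinked and flagged with a warning.

## What the simulator emulates — and what it does not

`simulateCohort` generates the statistical structure the pipeline
assumes, not a portrait of any real cohort:

* **Stratification** via the Balding-Nichols model: subpopulation
  allele frequencies are Beta-distributed around an ancestral frequency
  with variance `Fst p (1-p)`. Default `fst = 0` (one panmictic
  population); stratification scenarios in the tests use Fst 0.05-0.1,
  the range typical of intra-European structure.
* **Nuclear LD** by first-order haplotype copying inside fixed-size
  blocks (default 10 SNPs, copying probability 0.8), independent across
  blocks. This produces the correlated neighborhoods a scan must
  tolerate while keeping across-block tests exactly null.
* **Mitochondrial variants** as independent haploid Bernoulli draws per
  subpopulation — adequate for frequency-based selection and
  association testing, but *not* a real mtDNA phylogeny: realistic
  haplogroup trees would put most mtSNP pairs in strong LD.
* **Disease** via a logistic model with optional nuclear,
  mitochondrial and mtSNP x nSNP interaction effects; the default
  intercept gives prevalence about 0.01 so the rare-disease identity
  holds. Cohorts are ascertained by rejection sampling to fixed
  case/control counts, mirroring separately collected disease and
  population cohorts (draw budget 1e7).
* **Power experiments** use a direct, disease-free mt-nuclear coupling:
  the designated pair is drawn jointly from the same margins-plus-OR
  table the analytic formula assumes.

A green calibration test therefore establishes that the pipeline's
statistics behave correctly under this generative model — uniform null
p-values, lambda near 1 after PC adjustment, recoverable interaction
parameters. It does not establish robustness to coalescent LD
structure, genotyping error, relatedness, or real haplogroup
phylogenies, all of which are out of scope.

## Numerical and calibration choices

* Null-calibration runs use independent nuclear SNPs (block size 1), so
  the Kolmogorov-Smirnov uniformity check applies to independent tests;
  LD-block cohorts are used where the question is confounding control,
  not distributional exactness.
* FDR family: all mtSNP x nSNP tests of a scan call, following the
  "number of combinations examined" convention; the combination
  report re-adjusts across its own rows only.
* Genomic lambda uses the exact 1-df chi-square null median
  (`qchisq(0.5, 1)`, about 0.4549), not the rounded 0.456.
* `computePCs` standardizes by `sqrt(2 p (1-p))`, mean-imputes missing
  genotypes after centering, and is deterministic up to sign.
* Monte-Carlo power checks use 200 replicates per parameter point —
  enough for the three-binomial-SE agreement band while keeping the
  suite fast; parameter-recovery and identity checks use 500
  replicates at the stated sample sizes.
* Seeds are fixed throughout the tests and derived per-replicate by
  small integer offsets; the simulator restores the caller's RNG state.

## Known limitations

* Wald p-values are anti-conservative in small cells; the skip rule
  bounds but does not eliminate this.
* The analytic power model is a large-sample approximation with a
  dominant exposure coding; it is validated against simulation within
  three binomial standard errors, not exactly.
* No genotype QC (call rate, HWE filters) beyond biallelic filtering is
  applied — thresholds for such QC are study-specific and none are
  assumed here.
* Only biallelic SNPs are supported; BGEN/PLINK formats, imputation and
  mixed-model association are out of scope.
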