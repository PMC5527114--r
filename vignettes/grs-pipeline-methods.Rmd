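---
title: "Methods: case-control SNP association and weighted genetic risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control SNP association and weighted genetic risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpgrs)
```

## The setting

`snpgrs` analyses unphased biallelic genotypes from a case-control study
of a polygenic trait.  The motivating design is a candidate-SNP study of
familial short stature in Han Chinese (978 cases, 1,129 controls,
34 height-associated candidate SNPs screened from a larger GWAS-derived
catalogue of 1,033), whose published count tables ship with the package as
`table1_reference()` and `table2_fixture()`.  The package is generic: any
panel of SNPs with case/control labels fits the same data model.

Dosages count copies of each SNP's *designated* minor allele — the
designation comes from an external reference panel and is kept fixed even
when that allele exceeds 50% frequency in the study cohort (one fixture
SNP sits at 51.8% in controls).  This is deliberate: it is the only
convention under which a published MAF column and a published OR table
with externally defined risk alleles stay mutually consistent.  Risk
alleles are tracked separately; association and scoring re-orient dosages
to risk-allele counts on the fly, and the flip applied twice is the
identity.  Coordinates are 1-based and allele labels are taken at face
value (no strand flipping — the data model carries no strand information).
Missing genotypes are excluded per SNP (complete-case per marker), so
per-SNP call rates are exactly the published quantity.

## Quality control

Three per-SNP filters, all thresholds exposed in `qc_thresholds()`:

* **MAF in controls** ≥ 5% (default).  The designated allele's frequency
  is reported as-is, but the *filter* clamps it to `min(f, 1 − f)`: a
  designated allele at 95% means the rarer allele is at 5%, and rarity is
  what the filter is about.
* **Call rate** ≥ 95% (default), computed per group and combined; the
  combined rate filters (whether a published call-rate column is combined
  or per-group is usually unstated — both are reported).
* **HWE in controls**, 1-df Pearson χ² against Hardy–Weinberg proportions
  at the observed allele frequency, *p* ≥ 0.05 (default).  No continuity
  correction: the fixture's published *p* = 0.35 for rs1046934
  (270/548/311) reproduces exactly without one, and a parametric-bootstrap
  null in the test suite confirms the χ²₁ approximation to within 0.01 at
  the sample sizes involved.  Case HWE is reported but never filters —
  true associations themselves distort case genotype proportions.

A SNP failing several filters records *all* its failure reasons, not the
first; filters are monotone (relaxing a threshold never shrinks the
passed set), and both properties are tested.

## Additive association on grouped counts

The additive model is a binomial GLM of case status on risk-allele dosage
fitted by IRLS (convergence tolerance 1e-10) on the three-row grouped
table — mathematically identical to the individual-level logistic fit,
which the test suite verifies to 8 decimals.  Reported per SNP:

* β (log OR per risk allele), OR, and a 95% Wald interval using the exact
  normal quantile 1.959964 (the difference from 1.96 is below printed
  precision);
* a two-sided Wald *p* (primary — the convention of mainstream commercial
  statistics packages) and a likelihood-ratio *p* for cross-checking; the
  two agree to well within an order of magnitude on every fixture row;
* the DOMDEV dominance-deviation test: the Wald *p* for a heterozygote
  indicator added to the additive model.  When a genotype cell is empty in
  one phenotype group the saturated fit separates and the Wald statistic
  collapses toward zero (the Hauck–Donner effect), so the test falls back
  to the likelihood-ratio *p* and says so in an attribute.  Under
  additive-tilt null tables (n = 2,000 per group) the test's size is
  within Monte-Carlo error of 0.05 over 1,000 replicates.

Perfect separation is flagged (`separated = TRUE`, infinite-β sentinel)
rather than silently reported as a huge finite estimate; monomorphic SNPs
are an error.  A SNP whose risk allele is not pre-specified gets it
defined as the allele with fitted OR > 1 — this deterministic rule also
resolves a labelling inconsistency in the packaged fixture (one row's
published risk-allele letter contradicts its own published counts; the
fixture stores the count-consistent orientation and keeps the published
label in `risk_allele_printed`).

Family-wise significance uses Bonferroni thresholds: α/1,033 for the
additive scan over the full candidate catalogue (0.05/1,033 ≈ 5×10⁻⁵ at
one significant figure) and α/34 for DOMDEV over the QC survivors
(0.05/34 ≈ 1.47×10⁻³).  Both counts are parameters of
`significance_policy()`.

## Linkage disequilibrium

**EM haplotype estimation.**  For a SNP pair, only double heterozygotes
are phase-ambiguous.  The EM splits them between coupling and repulsion
phases at their posterior odds each iteration, starting from linkage
equilibrium at the observed allele frequencies, until no haplotype
frequency moves by more than 1e-10 (cap 10,000 iterations).  The exact LE
start is a stationary *saddle* for phase-symmetric samples (e.g. a sample
consisting only of double heterozygotes), so the EM also runs from a small
coupling tilt and a small repulsion tilt and returns the solution with the
highest observed-data likelihood, with a deterministic tie-break
(LE, then coupling).  On small random samples the returned solution
matches a 1e-4-resolution grid search over the one free haplotype
frequency, and the likelihood is non-decreasing across iterations — both
asserted in the tests against independently coded oracles.

**Statistics.**  With major-allele margins p_A, p_B (q = 1 − p):
D = p₁₁ − p_A p_B; D′ = |D|/D_max where D_max = min(p_A q_B, q_A p_B) for
D > 0 and min(p_A p_B, q_A q_B) for D < 0; r² = D²/(p_A q_A p_B q_B).
The sign of D is reported separately from D′.  Worked example: haplotype
frequencies (0.40, 0.10, 0.20, 0.30) give D = 0.10, D′ = 0.50,
r² = 1/6.  For all valid inputs 0 ≤ r² ≤ D′ ≤ 1 (r² ≤ D′² is *not*
asserted; it is false in general).

**Bootstrap CIs and blocks.**  D′ intervals are percentile bootstrap over
resamples of individuals (seeded; monomorphic resamples carry no LD
information and are redrawn, with the count reported).  A 500-replicate
simulation in the test suite (n = 250, 200 resamples each, true
D′ = 0.5) observes coverage inside [0.92, 0.98] at the 95% level.
Blocks follow the Gabriel confidence-interval classification: a pair is
strong LD when its CI lower bound ≥ 0.70 and upper bound ≥ 0.98, strong
recombination when the upper bound < 0.90; maximal position-ordered
intervals whose outermost pair is strong and in which ≥ 95% of informative
pairs are strong become blocks.  All four numbers are exposed parameters;
they are the field's standard defaults, adopted because the design named
the CI-resampling block method only by reference.

**Pruning.**  Greedy: iterate SNPs in priority order, retain a SNP iff its
D′ with every already-retained SNP is ≤ 0.8 (parameter).  Pairs on
different chromosomes count as D′ = 0 — only physical linkage prunes.
The default priority is ascending additive *p* (keep each LD cluster's
most significant SNP); the original study did not state its re-selection
rule, so the rule in force is echoed in the run report.  Pooled genotypes
are the default basis for pruning (case-only and control-only LD are also
computable); the original study is again silent here, and pooled is the
choice that uses all the data.

## Weighted genetic risk score

Per individual, the raw score is Σᵢ wᵢ xᵢ over the pruned panel with
wᵢ = ln ORᵢ and xᵢ the risk-allele dosage.  Two conventions are carried:

* `raw`: natural-log-OR weights as is; range [0, 2Σwᵢ].
* `rescaled` (default): raw × K/Σwᵢ, where K is the panel size — the
  allele-count scale, on which a sample heterozygous everywhere scores
  exactly K.  This is the default because the reference study's published
  quartile cut-points (11.88/13.50/15.05) are unreachable on the raw scale
  (2Σ ln OR ≈ 8.48 for its 13 SNPs) but sit centrally in the rescaled
  range [0, 26]; the rescaling inference is documented here as the
  package's reading, not asserted as the original procedure, whose exact
  scaling (and log base) is unrecoverable without individual-level data.

Missing dosages default to their control-cohort expectation 2f_risk
(imputation keeps every sample scoreable); complete-case scoring with
per-sample rescaling is available by flag, and samples missing more than
half the panel are flagged unreliable either way.

Quartile cut-points default to empirical quartiles of the *pooled*
case+control score distribution (type-7 quantiles) — pooled is the only
choice consistent with quartiles that contain unequal case fractions —
and explicit published cut-points can be supplied instead.  Membership is
right-closed, (low, high]: a score exactly on a cut-point falls in the
lower quartile.  Assignment uses direct comparisons rather than `cut()`
so that tied cut-points from a very discrete score distribution (small
panels) remain well-defined; fully constant scores are a degeneracy error.

Per-quartile odds ratios come from the saturated logistic fit on the 2×4
table (identically the closed-form cross-product ratios, which the tests
verify to 1e-9) and the trend is the Cochran–Armitage score test with
integer scores 1..k, reported as a *signed* Z with a two-sided normal
*p*: Z² equals the base-R `prop.trend.test` statistic and the *p* matches
a permutation null to within ~0.02 on small tables (both checked).

## The synthetic-cohort generator

Controls draw genotypes from Hardy–Weinberg proportions at the specified
control risk-allele frequency; cases from the exponential tilt
P_case(g) ∝ P_control(g)·OR^g.  The tilt makes the additive logistic OR on
the resulting grouped data equal the specified OR *by construction*, which
turns parameter recovery into an analytic target: at n = 50,000 per group
the fitted CI covers the generating OR, and over 200 grouped replicates
the mean β̂ is within 2% of ln OR (both in the tests).  The case
ascertainment model of a real study is unknowable from published tables;
the tilt is one admissible choice and is documented as such.

LD structure comes in two forms: phenotype-neutral haplotype pools
(blocks specified by haplotype frequencies — D′ is a derived property,
since specifying a target D′ directly is an ill-posed inversion), and
haplotype-level proxy copies of a tag SNP (flip probability per
haplotype), which keep D′ near 1 while inheriting the tag's association —
the construction used to test pruning on a 34-SNP panel of 13 clusters.

Reproducibility: a single master seed; per-SNP sub-seeds are drawn once
from it so that extending the panel never perturbs earlier columns, and
identical specifications give bit-identical cohorts.

What the generator does *not* emulate: population stratification,
relatedness, genotyping batch effects, informative missingness (cells are
MCAR), or covariates — the reference design's models are unadjusted
single-SNP fits, and passing tests on these cohorts accordingly says
nothing about confounding robustness on real data.  The generator's HWE
controls also mean the control-HWE filter rejects ~5% of perfectly valid
synthetic SNPs, its nominal size; pipeline tests therefore assert the
construction-guaranteed invariants (every QC survivor significant, one
SNP retained per represented LD cluster) rather than a lucky zero-failure
QC pass.

## Pipeline and problem sizes

`run_pipeline()` executes QC → additive association (keep *p* below the
additive Bonferroni threshold) → D′ pruning of the survivors → wGRS
quartile analysis, in that order — significance filtering precedes
pruning, matching the reference design's narrated flow (34 significant
SNPs, then LD re-selection to 13).  Stage SNP counts are non-increasing;
every effective threshold, the seed, and the pruning priority rule are
recorded in the JSON run report; identical inputs, configuration, and
seed give byte-identical output files; a stage failure aborts with the
stage name and removes partial outputs.

Validation problem sizes are chosen to keep the full suite in the
low minutes while leaving comfortable statistical margins: cohorts of
10⁴–10⁵ for recovery checks, 1,000 null tables for DOMDEV size,
500 simulated pairs × 200 resamples for bootstrap coverage, 10⁵
permutations for the trend oracle, and 2,000 replicates for HWE filter
calibration.

## Known limitations

* Two-SNP EM only — no multi-locus phasing; haplotype blocks use pairwise
  CIs, not joint phase.
* No covariate adjustment, no per-sample QC (sex checks, relatedness,
  heterozygosity), no X-chromosome handling, no binary PLINK/BGEN input,
  no multi-allelic sites.
* Weights for the wGRS come from the same cohort as the score (as in the
  reference design); the quartile ORs are therefore optimistic relative
  to external validation, which is out of scope.
* The published 34 → 13 pruning and the published wGRS cut-points depend
  on individual-level data that was never released; the package reproduces
  those stages' *behaviour* on construction-matched synthetic panels and
  documents the scaling inference, but exact numeric replication of those
  two published artefacts is impossible from printed tables alone.
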