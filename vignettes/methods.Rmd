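---
title: "Models and design choices in pretermASD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in pretermASD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, and the choices made where
the design was genuinely open.

## The analysis problem

The package targets a recurring study design in autism genetics: a large
family-based cohort in which children differ in ASD diagnosis and in
gestational age at birth, with trio genome sequencing, curated phenotype
categories, and genome-wide genotypes for polygenic scoring. The
scientific questions are whether rare de novo and inherited variant
burden, common-variant polygenic load, and prematurity contribute jointly
to ASD diagnosis, and whether information available at birth predicts ASD
in preterm children. Because such cohorts are access-restricted, every
stage here is exercised on synthetic cohorts whose generative structure
matches the analyses' assumptions.

## De novo detection and the QC cascade

A candidate de novo variant requires child heterozygosity, both parents
homozygous reference, and child allele balance strictly above 0.25 (the
threshold is a strict inequality: AB = 3/12 = 0.25 exactly is rejected).
Allele balance is undefined at zero informative depth; such records are
never candidates. On chromosome X a hemizygous male child may be het or
hom-alt and only the mother must be homozygous reference; chrY is
excluded by default.

The cascade applies eight record-level filters in a fixed order — minimum
trio GQ 20, minimum trio DP 10, population allele frequency at most
0.001, homopolymer alleles (a run of at least 10 A or 10 T within the REF
or ALT allele string), excluded regions, presence in an unrelated
family's parent, candidate recurrence in children of more than three
families, and more than three ALT alleles at the originating site —
followed by a two-sided exclusion of children whose passing count lies
beyond three standard deviations from the cohort mean. Design choices a
reader should know:

* **Single deterministic rule set.** Production pipelines often intersect
  two callers; the scientific content here is the rule cascade itself, so
  detection is one deterministic rule set applied to genotype records. An
  optional second call set can be intersected upstream by filtering the
  record table before detection.
* **Filter order is fixed** (quality, frequency, sequence context,
  regional, cohort-level, site-level) so that per-filter audit counts are
  reproducible; each rejected call records every failing filter, and
  audit counts attribute it to the first.
* **Missing population frequency counts as zero**: absence from the
  reference population is evidence of novelty, which is the property the
  filter guards.
* **Homopolymer scanning is allele-local** (REF/ALT strings). Scanning
  flanking reference context would need a genome FASTA; the allele-local
  rule is self-contained and catches the indel artifacts the filter is
  aimed at.
* **GQ/DP thresholds apply to the whole trio** (`qc_scope = "trio"`), the
  stricter reading; `qc_scope = "child"` is available.
* **Outlier exclusion is two-sided**; sidedness is not dictated by the
  estimator, and symmetric trimming is the conservative default.
* **Multiallelic accounting**: input sites are decomposed to biallelic
  records that retain the original site-level ALT count (`NALT` INFO
  field on re-import), so the ">3 alleles" rule sees the site as
  genotyped, not as decomposed.

## Inherited variants

Panel genes carry a dominant or recessive annotation (monoallelic /
biallelic labels are normalized; conflicting annotations are an error
rather than a guess, since no resolution rule can be defended without
the source databases). Frequency ceilings are mode-specific (0.001
dominant, 0.01 recessive). Genotype-mode consistency: dominant calls are
child-het with at least one carrier parent; recessive calls are child
hom-alt with both parents carriers, or child-het compound-heterozygote
candidates phased by transmission — both parents carrying makes a het
call unphaseable and it is excluded from pairing. GQ/DP thresholds are
enforced in the child and every carrier parent; this is stricter than
the minimal reading but protects the transmission inference, which is
exactly the quantity the compound-het scan relies on. Damaging-missense
classification (CADD ≥ 20, SIFT D, PolyPhen P or D, PhyloP ≥ 2, REVEL ≥
0.5; any one suffices, missing scores contribute nothing) applies to
dominant-gene calls only; recessive calls are classified by genotype
configuration alone. "PolyPhen P and D" is read as membership in
{possibly, probably damaging} — the literal conjunction is a single-label
impossibility.

## Phenotype statistics

Odds ratios use the closed-form cross product with a Haldane–Anscombe
0.5 correction when any cell is zero, Woolf log-scale 95% intervals, and
a chi-square p-value (Fisher's exact when any expected cell is below 5);
the correction applies to the estimate and interval, never the test.
FDR families follow the figure groupings: nine diagnostic categories per
contrast, six quantitative measures, the post-hoc stratum pairs (term
included as a comparison level). Multimorbidity is the count of distinct
positive categories bucketed 0, 1, 2, 3, 4, ≥ 5. The Kendall trend runs
over strata ordered from most premature upward, so negative tau means
prevalence falls toward term; the direction convention is documented
rather than forced.

## GEE models

The estimating-equation solver is implemented in the package: Fisher
scoring on the marginal mean (Poisson log or binomial logit), moment
estimators for the dispersion and the exchangeable correlation at each
step, and the cluster-robust sandwich covariance at the solution. With
singleton clusters and independence correlation the estimating equations
are the GLM score equations, and the tests hold the two solvers to 1e-8
agreement. Exchangeable working correlation is the default because the
clusters are families; independence is available, and robust inference is
valid under either. The burden model is `count ~ group + sex` with no
offset (counts per child, not rates per base); the probability model is
`ASD ~ sex + preterm + PRS` with an optional preterm × PRS interaction,
and marginal probability grids are computed effect-display style by
fixing the focal variables and averaging predictions over observed rows.
The age covariate in adjusted odds ratios is age at registration in
years. Wald p-values use the robust errors; a binomial fit whose
coefficients run away (|beta| > 20) is reported as separation, naming
the covariate.

## Polygenic scores

Raw scores are per-allele averages (weighted dosage sum divided by twice
the number of non-missing variants), the convention of PLINK-style score
functions; a plain-sum mode exists. Effect alleles are oriented against
the genotype panel (REF matches flip the dosage; variants matching
neither allele are skipped and counted). Scores are z-standardized over
the scored cohort, so flipping an effect allele with a negated weight
shifts raw scores by a constant and leaves z-scores untouched — a tested
invariant. McFadden pseudo-r² is reported in both senses (full model vs
intercept, and the increment over sex + PCs) because either can be the
quantity of interest; the acceptance script reports the full-model
value. Ancestry PCs come from plain PCA of the standardized dosage
matrix, or are accepted as columns.

## At-birth prediction

Features are restricted to what exists at birth: sex, gestational age
(term births missing GA imputed at 40 weeks; preterm births with unknown
GA at 34 weeks, a late-preterm value, so the table is complete),
perinatal flags, variant-class counts, the mean CADD of a child's DNVs,
and the standardized PRS. RFE uses random-forest importance under
10-fold cross-validation (via caret's reference implementation);
correlation pruning then resolves pairs with |Pearson r| strictly above
0.7 by keeping the more general member under an explicit generality
ordering (e.g. total LOF over LOF-on-NDD-genes) — config data, not a
heuristic. Nested cross-validation uses stratified outer folds, a
repeated inner-fold grid search selected on AUROC (the inner loop is
skipped when the grid has a single candidate, where it would be a no-op),
and pools out-of-fold predictions for metrics; the accuracy interval is
exact Clopper–Pearson. Class imbalance is handled by stratification
only — no resampling — and this is a documented limitation. SHAP values
are exact TreeSHAP for XGBoost (additivity to the margin holds to about
1e-4, the single-precision arithmetic of the booster); random forest and
linear SVM fall back to permutation attributions, flagged as such.

## The synthetic cohort generator

The generator's defaults are the study conditions the analyses assume.

* **Families**: 300 by default; 1–3 children with probabilities
  (0.45, 0.40, 0.15), mean ≈ 1.7 children per family, matching a cohort
  of ~5.7k trios from ~3.4k families.
* **Prematurity**: preterm rate 0.102; stratum mix among known-GA
  preterm births (extremely 0.081, very 0.115, moderate 0.148, late
  0.656) taken from the published cohort composition; 6.3% of preterm
  births lack a recorded GA; 20% of term births lack GA (imputed as 40
  downstream).
* **ASD liability**: logistic with marginal log-ORs 1.1 (male), 0.9
  (preterm, within the reported two-to-four-fold band), 0.5 per PRS SD,
  0.3 for each perinatal flag, intercept −0.5 (cohorts of this kind are
  ASD-enriched), and a family-shared random intercept (SD 0.5). Because
  a random intercept attenuates marginal effects, the conditional
  coefficients are inflated by sqrt(1 + 0.346·sd²) so the configured
  values are what a marginal (GEE) model estimates; the approximation
  error is well under the sampling error at these settings. The perinatal
  flags are correlated with preterm status, so the unadjusted preterm
  coefficient absorbs a small share of their effect — visible as a
  slight upward shift well inside the robust intervals.
* **DNV counts**: Poisson, mean 75.9 per child, exonic fraction
  16155/432903 ≈ 3.7%, LOF fraction 986/432903, with a mean-one lognormal
  family frailty (log-SD 0.15) inducing within-family correlation. The
  configurable ASD-preterm rate ratio (default 1.5) acts on the *exonic*
  component, where the reported burden excess lives; genome-wide
  background rates are shared by all groups.
* **Inherited variants**: ~43 dominant-gene and ~0.76 recessive-gene
  variants per child (the per-trio averages implied by published totals),
  LOF and damaging-missense fractions 0.011 and 0.159 among
  dominant-gene calls; compound-het pairs default to zero (none were
  observed in the motivating data) but are plantable.
* **Diagnostic categories**: logistic prevalence models with positive
  ASD and preterm log-ORs per category (growth/birth largest, matching
  the reported OR ordering). Magnitudes are chosen for test power, not
  claimed as population estimates.
* **Artifacts**: each planted artifact violates exactly one cascade
  filter, at configurable per-child rates (default 0.05), so per-filter
  audit counts are checkable; recurrence artifacts span four families,
  cross-family artifacts pair a candidate with a carrier record in an
  unrelated family.

What the generator does **not** emulate: linkage disequilibrium between
PRS SNPs (weights are inputs; LD machinery is out of scope), mutation
spectra and read-level sequencing error, realistic gene lengths or
per-gene mutation rates, population stratification (simulated ancestry
is homogeneous, so PCA covariates are noise), and ascertainment beyond a
liability intercept. Passing tests therefore demonstrate correctness of
the estimators and filters under the stated generative model, not
robustness to every artifact of real cohorts.

## Numerical choices and problem sizes

Position space is partitioned by record kind (de novo, inherited,
artifact bands) and drawn without replacement, so synthetic variant ids
never collide across families by accident — a collision could otherwise
spuriously trigger the cross-family filter. GEE scoring iterates to a
1e-10 coefficient tolerance (100 iterations max) from the GLM start;
exchangeable correlation estimates are clamped to [−0.49, 0.99]. Grid
ties in the inner CV resolve to the first row; stratified folds are
drawn per class under the run seed, making nested CV bit-reproducible.
The test suite uses cohorts of 8–800 families; parameter-recovery checks
use 50 replicates of 300 families; the prediction controls use
preterm-only cohorts of 150–200 families (roughly the size of the
published at-birth modelling population) with 21 label permutations for
the null. These sizes were chosen so each property is measured with
comfortable statistical margin.

## Known limitations

The GEE solver supports the two families and two working correlations
the analyses need — no small-sample corrections beyond the sandwich, no
offsets, no mixed models. Compound-het phasing is by transmission only.
European-ancestry subsetting for PRS models is configuration-driven;
no default threshold is claimed. The package reads annotations as input
fields and never computes them; liftOver, caller implementations, and
PRS posterior-weight estimation are explicitly out of scope.
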