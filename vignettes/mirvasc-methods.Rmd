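---
title: "Methods: miRNA co-expression networks and vascular function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA co-expression networks and vascular function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mirvasc` implements an integrative analysis that links whole-blood miRNA
co-expression modules to quantitative markers of vascular function. This
vignette is the package's account of the models it fits, the parameters that
matter, what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where the design was genuinely open.

## Derived cardiovascular traits

Raw per-sample measurements are converted to analysis traits:

* mean arterial pressure MAP = (SBP + 2 DBP)/3 (mmHg);
* body surface area by the classic Du Bois form,
  BSA = 0.007184 · weight^0.425^ · height^0.725^ (kg, cm → m²);
* cardiac output CO = SV · HR / 1000 (L/min) and systemic vascular
  resistance SVR = 80 · MAP / CO (dynes·s·cm⁻⁵); stroke volume, CO and SVR
  are divided by BSA to give the stroke, cardiac and SVR indices;
* pulse pressure PP = SBP − DBP; total arterial compliance TAC = SV/PP
  (mL/mmHg), indexed as TACI = TAC/BSA; pulse wave velocity
  PWV = transit distance / transit time (m/s);
* reactive skin hyperemia RSH = 100·(plateau − baseline)/baseline (%);
* WMH burden = white-matter-hyperintensity volume / white matter volume.

Before modelling, PWV and RSH are natural-log transformed (both are
right-skewed), WMH burden is logit transformed, and every analysis trait is
z-standardized so association coefficients read as sd-outcome per
sd-predictor. Natural rather than base-10 logs are used; standardization
makes the base irrelevant for inference, the choice is recorded for
reproducibility. A zero burden (possible in synthetic data, not in adult
cohorts) is replaced by half the smallest positive observed burden before
the logit, which keeps the transform finite and order-preserving. A device
convention sets central venous pressure to 6 mmHg; no implemented formula
uses it (SVR is computed from MAP alone, as defined above), so it is noted
here and nowhere else.

## Preprocessing

Features are kept when their mean count strictly exceeds 15 reads and they
are nonzero in at least 5% of samples. Library sizes are removed with
median-of-ratios size factors (median over features, expressed in every
sample, of the count over the per-feature geometric mean) followed by
log2(count/s + 1). This is a deliberately simple stand-in for a fitted
variance-stabilizing transformation: it meets the two goals that matter
downstream — library-size normalization and a log-scale matrix — with a
fully specified, dependency-free algorithm, at the cost of not exactly
reproducing a fitted VST's values. One consequence worth knowing: the
geometric-mean reference ties the factors to the whole sample set, so only
factor *ratios* are identified; rescaling one sample changes every factor
by a common 2^(1/n)-type constant. Gene expression for the integration
stage passes through the same filter/normalize/residualize path.

Sequencing batch is removed by per-feature OLS residualization on batch
indicators before network construction; both miRNA and gene expression are
batch-residualized before target confirmation. Missing phenotype values are
handled per-analysis as complete cases, mirroring per-trait missingness in
population cohorts.

## Signed weighted co-expression network

The network stack is implemented from first principles:

1. **Biweight midcorrelation.** With u = (x − med x)/(9 MAD x) (MAD
   unscaled) and Tukey weights w = (1 − u²)² for |u| < 1, bicor is the
   weighted centered cross-product over the weighted norms. Features with
   zero MAD fall back to Pearson for their pairs (logged). This keeps a
   single gross outlier from manufacturing or destroying a correlation.
2. **Signed adjacency** a = ((1 + ρ)/2)^β, so negatively correlated
   features end up unconnected and modules are positively co-expressed.
3. **Soft power selection.** For each candidate power the connectivity
   distribution is binned (10 equal-width connectivity bins) and log10
   frequency is regressed on log10 mean connectivity; the signed R² is the
   scale-free fit. The selected power is the first to reach 0.90. When no
   power reaches the target — typical for compact synthetic panels whose
   planted modules are mutually independent, so the degree distribution is
   bimodal rather than scale-free — the search reports its argmax with a
   flag, and `build_network` instead falls back to a configured default
   power of 7, the customary choice for signed networks of this size. The
   flagged argmax is not used directly because on non-scale-free degree
   distributions it drifts to the top of the grid, where the topological
   overlap saturates and module structure is erased.
4. **Topological overlap.** Ω_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij),
   with l the shared-neighbour sum; 1 − Ω is the clustering dissimilarity.
   The standard (unsigned) TOM formula is applied to the signed adjacency,
   the common default; with signed adjacency, negative correlations are
   already near zero.
5. **Hybrid tree cut.** Average-linkage clustering of 1 − Ω, cut at 0.97 of
   the maximum merge height; branches smaller than 5 dissolve to
   "unassigned". A PAM-like second phase then attaches an unassigned
   feature to its nearest module only when its average dissimilarity to
   that module is below both the feature's median dissimilarity to all
   features and the module's own radius (mean + 2 sd of within-module
   dissimilarities). The radius condition is what keeps unrelated noise
   features from being absorbed — without it, the nearest of several
   module means almost always undercuts a feature's overall median, and
   every noise feature ends up assigned. The 0.97 cut sits on a stable
   plateau (0.95–0.98 give identical recovery of planted modules). An
   all-equal dissimilarity matrix yields a single module when large enough.
6. **Merging and summaries.** Module eigenvectors (first principal
   component of the per-feature standardized module expression, sign-aligned
   with the module average, unit variance) are iteratively merged while any
   pair's correlation dissimilarity is below 0.2 (eigenvector correlation
   above 0.8), lowest-label pair first. Module membership (MM) is the
   correlation between a feature and each module eigenvector. Colour
   aliases follow size rank in the conventional palette (largest =
   turquoise), purely for reporting.

## Association, hubs, effect modification

Module–trait models are OLS fits of each standardized trait on each
standardized eigenvector with age and sex as covariates; inference is the
usual t-based theory. BH-FDR is applied jointly across all module × trait
tests of an analysis — the most conservative plain reading of "corrected
across multiple testing" — and both FDR < 0.05 and < 0.1 views are
reported. Key modules have at least one trait below the configured FDR.
Hubs are members with MM > 0.8 that are individually associated with the
module's trait at p < 0.05; a key module with no qualifying member can emit
its maximal-MM member flagged "borderline" so that module remains
followable. Sensitivity analyses re-fit the four non-indexed traits (SV,
CO, TAC, SVR) with age/sex and additionally with BMI. Effect modification
is assessed with miRNA × age and miRNA × sex product terms; significant
interactions trigger stratified fits by sex or by age quartiles (sample
quantiles, linear interpolation), with strata under 30 samples flagged.

## Mediation

The exposure → mediator → outcome model is linear with covariates: two OLS
fits give a (exposure→mediator), b and c′ (outcome on mediator and exposure
jointly); indirect = a·b, total = c′ + a·b, proportion mediated =
a·b/total. For linear Gaussian paths these coincide with structural-equation
point estimates, so a dedicated SEM optimizer adds nothing but moving
parts. Inference is a nonparametric bootstrap (resampling individuals,
percentile 95% CIs, two-sided sign-proportion p for the indirect effect;
default 1000 replicates, seeded); this deviates from delta-method SEM
standard errors in inference only, never in point estimates. The
proportion is suppressed when |total| < 0.01 sd to avoid ratio blow-up —
a guard the ratio definition otherwise lacks.

## Target confirmation and enrichment

Predicted miRNA→gene pairs (union over sources, provenance kept) are
confirmed by OLS of gene on miRNA expression with age, sex and
erythrocyte/leukocyte/platelet counts as covariates: confirmed means β < 0
and p < 0.05, the sign encoding post-transcriptional repression. The
per-pair fit is computed by covariate residualization of both sides
(Frisch–Waugh), which is algebraically the full multiple regression with
the correct degrees of freedom and much faster over thousands of pairs.

Over-representation of confirmed targets uses the upper-tail
hypergeometric test against the background of all genes surviving the
expression filters (the implicit testable universe). Terms are then
aggregated by complete-linkage clustering on 1 − similarity, cut at height
1 − 0.5 so every within-group pairwise similarity is at least 0.5 — a
guarantee specific to complete linkage. When no similarity matrix is
supplied the Jaccard index of term gene sets is used; ontology-graph
semantic similarities can be passed in to reproduce graph-based behaviour,
which keeps an external ontology release out of the package's
dependencies. Within a group, p-values combine by Fisher's method
(−2Σln p against χ² with 2m df), the lowest-p member represents the group,
and BH runs across groups.

## miR-eQTL scan

Hub-miRNA expression is residualized on age, sex, batch and the first 10
genotype principal components (plain PCA of the centered,
allele-frequency-scaled dosage matrix, signs fixed by the largest loading;
a dedicated population-genetics toolchain is out of scope for the
covariate role PCs play here). Each SNP is tested by simple regression of
the residual on dosage; genome-wide significance is 5e-8. Significant SNPs
within 1 Mb of the mature miRNA on the same chromosome are *cis*
(inclusive boundary: "within 1 Mb" read as ≤), the rest *trans*.
Significant SNPs are clumped greedily per miRNA: best remaining hit seeds
a locus, which transitively absorbs hits with r² > 0.6 to any member
within a 1 Mb padding window; lead SNPs are the most-significant-first
subset with pairwise r² < 0.1, and the top lead is the minimum-p member.
Dosages may be real-valued in [0, 2] to admit imputed data.

## Synthetic cohort generator

Because the motivating cohort data are access-restricted, the package
ships a generator whose defaults define the validation conditions:

* n = 500 participants, ages spanning 30–95 (beta-shaped, mean ≈ 54),
  46% men, three sequencing batches;
* 200 miRNAs: six planted modules (sizes 40, 30, 25, 20, 15, 10) with
  factor loadings 0.8 and feature noise sd 0.6, plus 60 unassigned noise
  features; module factors carry small age/sex components so "adjusting
  for age and sex" is genuinely exercised;
* negative-binomial counts, log link, constant dispersion 0.1 (biological
  CV ≈ 0.3, typical of population blood RNA-seq), baseline means 30–800
  reads, per-sample library factors in [0.7, 1.4], per-feature batch
  shifts (sd 0.3);
* traits built by inverting the phenotype formulas so the planted
  couplings land on the *derived* traits: module→trait standardized betas
  in the 0.03–0.08 range (the scale reported for such cohort effects;
  small on purpose), age trends in the physiological directions
  (compliance, cardiac index, hyperemia fall with age; PWV, SVR and WMH
  burden rise), and a built-in mediation triple (module 1 → TACI → WMH
  burden) with known a, b, c′;
* 300 genes, half targeted by module miRNAs at coupling −0.3 with
  blood-cell confounding, plus decoy predictions for null pairs; three
  designated annotation terms are enriched in true targets;
* genotypes as two haplotypes per individual with copy-with-mutation LD
  blocks (400 SNPs, blocks of 10, copy probability 0.9) and one planted
  cis-eQTL (β = 0.5, MAF 0.3) on the first miRNA. The panel is kept at
  several hundred SNPs deliberately: with only a few dozen SNPs the 10
  genotype PCs align with individual LD blocks and can regress out the
  causal block itself, which is an artifact of tiny panels, not of the
  method.

One global seed feeds a named sub-stream per component, so adding a
component never perturbs the draws of the others; identical spec + seed
gives byte-identical outputs. Ground truth (labels, couplings, paths,
eQTL, target pairs) is serialized alongside the data and never read by
analysis code.

What the generator does *not* emulate: cell-type composition shifts,
correlated miRNA families sharing seed sequences, ancestry structure,
genotyping error, trait measurement-device drift, or the pervasive weak
positive correlation of real whole-blood expression (which is why the
scale-free fit target is typically unreached on synthetic panels — see the
power-selection fallback above). Passing tests therefore demonstrate that
the machinery recovers planted structure under a faithful statistical
caricature, not that any particular biological claim transfers.

## Problem sizes used in the validation suite

The test suite and the acceptance script run: module recovery on ten
cohorts of n = 500 × 200 miRNAs; mediation recovery (true proportion 0.2)
on twenty runs at n = 2000; eQTL recovery on ten cohorts at n = 2000 with
400 SNPs; target-confirmation sensitivity at n = 2000 with 60 true and 400
null pairs; association calibration over 2000 null fits at n = 1000 and
500 null cohorts of 14 modules × 7 traits. These sizes keep each block
well-powered for the rates being checked while completing in minutes on a
single core.

## Known limitations

* The normalization is an explicit approximation to a fitted VST; exact
  numeric parity with that transformation is a non-goal.
* The hybrid tree cut captures the published algorithm's two phases
  (adaptive cut + PAM-like assignment) but is not a line-for-line port;
  equivalence is asserted at the level of planted-structure recovery.
* The mediation model is single-mediator, linear, without
  exposure–mediator interaction.
* Enrichment similarity defaults to gene-set Jaccard, not ontology-graph
  semantic similarity (user-suppliable).
* LD clumping uses a stated greedy transitive-closure rule; external GWAS
  platforms leave their exact windowing unspecified, so equality with any
  particular tool is not claimed.
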