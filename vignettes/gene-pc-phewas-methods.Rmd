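---
title: "Methods: gene-PC association scans, cis-MR and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-PC association scans, cis-MR and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcphewas)
```

## The model

A gene-based association scan asks whether the common genetic variation in
one gene region, taken jointly, predicts a phenotype. Testing every variant
separately multiplies the testing burden and ignores linkage
disequilibrium (LD); `pcphewas` instead compresses each gene region into a
small set of principal components (PCs) of the genotype dosage matrix and
tests those jointly, the dimensionality-reduction strategy familiar from
MAGMA-style gene analysis.

### Gene regions

Gene boundaries follow the annotation source (Ensembl convention: 1-based,
inclusive ends). Protein-coding genes are padded by 1.5 kb upstream and
1 kb downstream to capture proximal regulatory variation; lincRNA genes are
not padded. Two choices the annotation convention leaves open are made
explicitly here: *upstream* is interpreted strand-aware (the 5′,
transcription-start side, the standard genomic meaning), and padded
intervals are clamped at position 1 so a gene near the chromosome start
cannot produce an invalid interval.

### Quality control

Variants enter the PCA when minor allele frequency ≥ 1% (the scan targets
common variation; PCs of rare variants are noise-dominated), imputation
info score ≥ 0.6, and per-variant missingness ≤ 2%; samples with > 2%
missing dosages are excluded, and one member of each related pair at
kinship coefficient ≥ 0.0884 (the conventional third-degree cutoff) is
removed, since the regression tests assume independent samples. MAF and
missingness are recomputed within the analysis subset by default (release
metadata can be supplied instead through the variant-metadata sidecar).
Relatedness pruning peels the highest-degree node of the kinship graph
until no edge remains — this retains more samples than dropping one member
of every pair independently — with ties broken by a seeded draw so the
result is reproducible.

### Gene PCs

Missing dosages are mean-imputed per variant, columns are centered but not
variance-scaled (all columns share the 0–2 dosage scale, so scaling would
up-weight rare variants), and a full deterministic SVD yields components.
The retained count k is the smallest for which the cumulative
explained-variance ratio reaches the target, 95% by default; the target is
exposed because sensitivity analyses at 99% are natural and cheap. Each
loading column is oriented so its largest-magnitude entry is positive,
making serialized PCs stable across runs. Mean imputation (rather than
complete-case PCA) keeps every sample's projection defined; at the ≤ 2%
missingness admitted by QC its attenuation of variance is negligible.

### Association tests

For a continuous phenotype, null (covariates only) and full (covariates +
k PC scores) linear models are compared with
\[
F = \frac{(\mathrm{RSS}_1 - \mathrm{RSS}_2)/(|P_2| - |P_1|)}
         {\mathrm{RSS}_2/(n - |P_2|)},
\]
F-distributed with \((|P_2| - |P_1|,\; n - |P_2|)\) degrees of freedom
under the null. Parameter counts include the intercept, so the numerator
df equals k. For a binary phenotype the analysis of deviance applies: both
logistic models are fitted by iteratively reweighted least squares and the
deviance drop is referred to \(\chi^2_k\); this equals twice the
log-likelihood gain, i.e. the likelihood-ratio test. Complete cases are
used per phenotype (samples missing the outcome or a covariate are
dropped); sex-stratified runs filter on the genetic-sex column and drop it
from the covariates.

Logistic fitting uses at most 25 IRLS iterations at relative deviance
tolerance 1e-8; separation is flagged when any coefficient passes 30 on the
logit scale, in which case the result is marked non-converged and its
p-value set missing rather than aborting a scan. Binary phenotypes with
fewer than 50 cases (configurable) are skipped: the χ² approximation is
unreliable there and a flagged skip is more honest than a miscalibrated
p-value.

## Multiplicity

Storey q-values are computed per gene (across phenotypes) or per phenotype
(across genes). π₀ is estimated on the grid λ = 0.05, …, 0.95 with a cubic
smoothing spline (df = 3) evaluated at λ = 0.95, the cited methodology's
standard default; with π₀ fixed at 1 the q-values reduce exactly to
Benjamini–Hochberg, which the tests exploit as an oracle. The estimate is
floored at 1/m — a smaller value would assert fewer than one null test,
which matters for degenerate single-test groups. Bonferroni correction
accepts an axis size m larger than the p-value list, so a single result can
be corrected against a full scan's test count. The inflation factor λ is
computed on 1-df χ² transforms of the p-values rather than the raw F/χ²
statistics because k varies across genes and statistics on different df are
not comparable; uniform p-values give λ = 1 by construction. Expected QQ
quantiles use the midpoint convention (i − 0.5)/m.

## cis-Mendelian randomization

The gene's PCs serve as instruments. Each PC's effect on the exposure and
on the outcome is estimated in its own covariate-adjusted marginal
regression (linear, or logistic for a binary outcome, giving log-odds
effects); marginal models are justified because PC scores are orthogonal on
the estimation sample — covariate adjustment perturbs that orthogonality
only mildly, the usual approximation of summary-statistic IVW practice.
Covariate adjustment in these regressions is the default here, chosen to
match the association engine's confounding control. PCs with exposure
P > 0.05 are removed (relevance assumption; a PC at exactly 0.05 is kept),
and the survivors are combined by the fixed-effect IVW estimator
\[
\hat\beta_{\mathrm{IVW}} =
  \frac{\sum_k \hat\beta_{Xk}\hat\beta_{Yk}\,\mathrm{se}(\hat\beta_{Yk})^{-2}}
       {\sum_k \hat\beta_{Xk}^2\,\mathrm{se}(\hat\beta_{Yk})^{-2}},
\qquad
\mathrm{se}(\hat\beta_{\mathrm{IVW}}) =
  \Big(\sum_k \hat\beta_{Xk}^2\,\mathrm{se}(\hat\beta_{Yk})^{-2}\Big)^{-1/2},
\]
with a two-sided normal p-value. First-stage uncertainty is deliberately
ignored (no weak-instrument correction), matching the estimator as defined;
the gene-vs-exposure association p-value is reported alongside so users can
judge instrument strength. Exposure and outcome are estimated on the same
sample (one-sample design) with no overlap correction — a known limitation;
weak instruments bias one-sample IVW toward the observational association.

## Drug-target enrichment

Genes associated with a phenotype (q ≤ 0.05) are tested for
over-representation in each node of the ATC hierarchy with Fisher's exact
test. The test is one-sided (greater) by default — enrichment is a
directional question — with a two-sided option. The gene universe is all
genes tested for the phenotype; genes absent from the ATC mapping count as
out-of-class. Both choices are recorded in the output metadata because
neither is forced by the method: a druggable-genes-only universe is a
defensible alternative that shrinks the out-of-class margin. Each node's
gene set is the union over its subtree, and after testing, the minimum p in
each subtree is propagated upward so a collapsed display can still signal a
significant descendant. Ontology enrichment (GO/KEGG/HPO) is delegated to
external services; the adapter only emits the gene list, and only when more
than five genes are significant.

## The synthetic-data generators

The generators define the study conditions under which the package is
validated. Haplotypes are drawn from a latent Gaussian AR(1) process with
adjacent-site correlation `ld_rho`, thresholded at each variant's
allele-frequency quantile; dosage is the two-haplotype sum. This gives one
interpretable LD knob and seeded, desk-scale data — deliberately not a
coalescent simulation: the association and MR machinery needs LD structure,
not demographic realism. Imputation noise is modelled by shrinking dosages
toward their expectation 2·MAF by √info, so the synthetic info score is a
monotone analogue of release metadata (sufficient for testing a threshold
filter). Phenotypes add age- and sex-like covariate confounding, causal
variant effects scaled to a target heritability, and (for binary traits) a
liability threshold at the target prevalence. MR scenarios chain gene →
exposure → outcome with configurable first-stage strength, true causal
effect, and an optional direct-pleiotropy path for violation studies.

What the generators do *not* emulate — population structure, genotyping
batch effects, phenotype measurement error, ascertainment — bounds what
green tests mean: calibration and recovery hold under clean LD-structured
data, not under every failure mode of real biobank data.

Default conditions: MAF ~ Uniform(0.01, 0.5); the acceptance-scale gene uses
n = 2000 samples, m = 50 variants, ld_rho = 0.6 (a dense, high-LD region
where truncation matters); the FDR simulation uses 200 replicates of 2000
p-values with 10% non-null at z-shift 3; MR recovery uses n = 5000, three
independent strong instruments, β = 0.5, 200 replicates. Test-suite
calibration of the two association tests runs 1000 null replicates at
n = 800, k = 3 — large enough for the likelihood-ratio χ² asymptotics the
deviance test relies on, and a size the scan would consider small; the
F-test is exact at any n.

## Numerical choices

- PCA uses a full `svd()`; singular values below 1e-12 of the largest are
  treated as rank deficiency so explained-variance ratios stay in (0, 1].
  The truncation comparison allows 1e-12 slack so an exact-boundary target
  (e.g. a component landing precisely on 95%) is kept rather than lost to
  floating-point rounding.
- Nested linear fits go through QR (`lm.fit`); rank deficiency is reported
  with the offending columns rather than silently dropped. RSS of the full
  model is capped at the null's RSS to absorb rounding noise with
  orthogonal-by-construction score columns.
- `rss2 = 0` (perfect fit) yields F = ∞ and a floor p-value rather than an
  error, so a degenerate phenotype does not abort a scan.
- Fisher p-values are capped at 1; q-values are clipped to (0, 1].
- All generator randomness flows through a single integer seed; RNG state
  is restored afterwards, so library calls never perturb a user's session.

## Limitations

- One-sample MR without overlap or weak-instrument correction (reported
  diagnostics only).
- Relatedness is handled by pruning, not mixed models; time-to-event
  outcomes are out of scope.
- The per-gene PCA is deliberately local: genome-wide (ancestry) PCs enter
  only as user-supplied covariates.
- Transcript-level structure, alternative assemblies and liftover are out
  of scope; annotations are taken at face value.
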