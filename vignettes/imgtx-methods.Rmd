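---
title: "Methods: linking gray-matter atrophy to spatial gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking gray-matter atrophy to spatial gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imgtx)
```

## The inference chain

`imgtx` implements the imaging-transcriptomics chain that relates group
differences in gray-matter volume (GMV) to the spatial profile of gene
expression across brain tissue samples. The chain assumes preprocessed
(segmented, normalized, modulated, smoothed) GMV volumes as given: all
upstream MRI preprocessing is out of scope, and the synthetic cohort
generator produces volumes with exactly the statistical structure the
downstream stages assume.

The stages and their core quantities:

1. **Voxelwise contrast.** At every in-brain voxel, a GLM of GMV on an
   intercept, a patient-vs-control indicator and covariates; the indicator's
   t statistic forms the contrast map. Gender is a covariate by default.
   The method reports two-sample group differences; including the covariate
   in a GLM is the standard operationalization of "two-sample t-test
   adjusted for gender", and with no covariates the GLM t reduces exactly to
   the pooled-variance two-sample t (the tests assert this closed form).
2. **Cluster-level GRF correction.** Separate one-tailed thresholding at
   voxel-level `voxel_p` for decreases and increases (matching the
   convention of reporting "decreased" and "increased" GMV separately),
   connected-component labeling, and a familywise cluster p from the
   stationary random-field expected-cluster-count approximation.
3. **Regional extraction.** Each tissue sample's regional *T* is the mean t
   over in-mask voxels whose centers lie within `radius_mm` of the sample's
   MNI coordinate.
4. **PLS1 + bootstrap Z.** First partial-least-squares component of
   regional *T* on the z-scored expression of the interesting genes;
   bootstrap over samples gives per-gene Z = weight / SE; |Z| > `z_thr`
   defines signed gene lists; lists are intersected across contrasts.
5. **Gene-wise Spearman + Bonferroni** over the consistent genes.
6. **Hypergeometric enrichment** of the signed consistent lists over the
   background gene universe, with Cohen's-kappa clustering of surviving
   terms.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `voxel_size_mm` | 1.5 | mm | isotropic VBM resampling grid |
| `smoothing_fwhm_mm` | 8 | mm | Gaussian kernel of the VBM pipeline |
| `n_per_group` | 83 | subjects | matched group size of the study design |
| `voxel_p` / `cluster_p` | 0.001 / 0.05 | – | GRF cluster correction levels |
| `radius_mm` | 4.5 | mm | 3 × voxel edge; an interior sphere on a full 1.5 mm lattice covers exactly 123 voxels |
| `n_boot` | 1000 | replicates | bootstrap SE of PLS1 weights |
| `z_thr` | 5 | – | signed-list cut on bootstrap Z |
| `alpha` | 0.05 | – | gene-stats familywise level and enrichment cut |
| `n_tests` | #consistent genes | – | Bonferroni family; 12 genes give p < 0.05/12 ≈ 4.17e-3 |
| `min_overlap` | 3 | genes | minimum query-term overlap |
| `kappa_thr` | 0.3 | – | term-cluster tree cut |
| `min_fraction` | 0.5 | – | probe present-above-background fraction |

## What the synthetic generator emulates — and what it does not

`make_cohort()` builds subject volumes as a smooth ellipsoidal baseline plus
Gaussian voxel noise smoothed to the target FWHM and rescaled to unit SD,
plus planted cluster effects expressed in Cohen's d units of the noise SD,
plus a small additive gender offset. Because effects are mean shifts added
after smoothing, a cluster of effect d shifts group means by exactly
d × noise SD inside the cluster, and the peak two-sample t concentrates at
d√(n/2). Smoothing independent noise makes the stationary-field assumptions
of the GRF correction hold by construction.

`make_expression()` draws tissue-sample coordinates uniformly within the
brain mask on both hemispheres (so left-hemisphere filtering is exercised);
the spatial placement of real AHBA samples is not emulated — uniform-in-mask
is a documented stand-in. Planted genes' noise-free profiles are constructed
to correlate with the reference atrophy field — standardized over
left-hemisphere samples, so the target ρ applies exactly to the samples the
pipeline retains — at the requested ρ. Each gene carries three probe tiers:
high-fidelity (low noise, ~10 % absent calls), degraded (heteroscedastic
noise, ~30 % absent), and junk (65 % absent, so the 50 % background filter
removes it); absent calls are set below a per-probe intensity quantile.
Donors differ by random offset and scale, which the scaled-robust-sigmoid
normalization removes by design. The default conditions are six donors, a
target of 1285 left-hemisphere samples (2 × 1285 drawn), and a 100-gene
panel whose first 41 symbols come from the packaged 52-symbol risk list, so
the risk-list intersection yields 41 interesting genes; twelve planted genes
(8 at ρ = +0.4, 4 at ρ = −0.4) carry the signal.

Passing tests on these data therefore show that the chain recovers planted
spatial associations under its own assumptions (stationary smooth noise,
exchangeable samples, monotone gene–field coupling). They do not show
robustness to real-data features that are deliberately not modeled:
realistic cortical anatomy and sample clustering along anatomical
structures, donor-specific batch structure beyond location/scale, spatial
autocorrelation between nearby tissue samples (which inflates the effective
significance of cross-sample correlations; see Limitations), or probe
re-annotation errors.

## Numerical and design decisions

- **Probe–RNA-seq agreement metric.** Spearman on log2 intensities: robust
  to scale and to the monotone distortions microarray sensitivities
  introduce; the upstream processing convention does not fix a metric.
- **Left hemisphere rule.** Strictly `mni_x < 0`; the midline x = 0 is
  excluded. A strict rule is deterministic; midline samples are ambiguous.
- **Background probe filter** pools all donors' samples, since present
  fractions refer to "sample sites" without donor stratification.
- **Between-donor harmonization** is within-donor scaled robust sigmoid
  (s = 1/(1+exp(−(x−median)/(IQR/1.35)))) plus unit-interval rescaling
  only — the simplest scheme that removes donor location/scale while
  preserving within-donor ranks. Zero-IQR genes fall back to rank-based
  uniform scores (logged via a message). Genes without an RNA-seq reference
  entry are dropped.
- **PLS1 closed form.** For a single response the first-component weights
  are the normalized cross-covariance Xᵀy; the implementation uses this
  form directly and the tests verify it against an independent PLS
  implementation (mixOmics) and the closed form at 1e−8.
- **Bootstrap unit and sign alignment.** Resampling is over tissue samples
  (rows). Each replicate's component is sign-aligned to the full-data
  weight vector by maximal dot product; without this, sign indeterminacy
  inflates SEs and collapses Z. The |Z| > 5 cut is the only multiplicity
  control at this stage — no additional FDR layer.
- **GRF approximation.** Expected cluster count from the 3-D t-field EC
  density (Worsley) with resel counts from the residual-derivative
  smoothness estimator, and the standard cluster-extent tail
  P(n ≥ k) = exp(−βk^(2/3)). Only the 3-D resel term is used; validity is
  established by null simulation (the acceptance suite requires an
  empirical familywise rate ≤ 0.10 at nominal 0.05 over 200 null cohorts)
  rather than by equivalence to any specific neuroimaging toolbox.
  Connectivity is 26-neighborhood by default and configurable (6/18/26).
  The analysis mask is implicit: voxels with cohort-mean GMV above 10 % of
  the maximum.
- **Sphere extraction.** Distances are voxel-center to sphere-center in
  world mm, boundary inclusive; out-of-mask voxels are excluded from the
  mean rather than zero-filled (zero-filling would bias edge samples toward
  0). Samples with empty spheres are dropped with a warning and propagate
  downstream by sample-ID joins, never positional indexing.
- **Spearman p-values** use the t approximation at all n. An exact
  permutation null is infeasible beyond n ≈ 10 and a Monte-Carlo null would
  make the stage stochastic; at the pipeline's n (~1285) the approximation
  is accurate, and |r| = 1 is clamped to the smallest representable
  positive p so p ∈ (0, 1].
- **Bonferroni comparisons are strict** (p < α/m), and the family defaults
  to the number of consistent genes, not genes × contrasts.
- **Enrichment background** is the analysis gene universe (the expression
  matrix's genes), not the genome — the query lists were themselves defined
  within that universe. Kappa is computed over the background (absent-absent
  pairs count as agreement); the term tree is cut where merge similarity ≥
  `kappa_thr`; clusters are labeled by the lowest-p member, ties broken by
  lexicographic term ID.
- **Determinism.** Every generator and the bootstrap take explicit seeds; a
  pipeline seed fans out to per-stage seeds, and reruns are byte-identical.

## Problem sizes used by the test and acceptance suites

Unit tests run on miniature grids (12–40 voxels per axis) and cohorts of
2–83 subjects per group, chosen so each statistical check has the power it
needs and nothing more. Null calibration uses 200 two-group null cohorts
(24³ voxels, 20/group, 6 mm smoothing) and 20 null PLS runs (500 samples ×
40 genes, 500 bootstraps). Parameter recovery runs 10 cohorts at the full
default conditions (83/group, 40×48×40 grid, ~1285 left samples, 12 planted
genes among 41, 500 bootstraps). The end-to-end determinism check uses a
reduced configuration, since determinism is size-independent.

## Known limitations

- Cross-sample Spearman p-values treat tissue samples as independent;
  spatially autocorrelated maps violate this, and autocorrelation-preserving
  nulls (spin or variogram surrogates) are acknowledged as stronger but are
  not part of this chain.
- The GRF cluster p is an asymptotic approximation requiring smoothness of
  ≳3 voxels FWHM; the estimator clamps FWHM at the voxel size with a
  warning when residuals are rougher.
- Only the first PLS component is used; multi-component inference is out of
  scope.
- The packaged 52-symbol risk list is a synthetic stand-in assembled from
  the twelve consistently associated genes plus literature GWAS locus
  symbols; users analyzing real data should supply their own list
  (`read_gene_list()`).
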