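---
title: "Global-to-local segmental morphometry: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global-to-local segmental morphometry: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tensor-based morphometry (TBM) summarizes each subject's anatomy as a map of
Jacobian determinants of the non-linear deformation that warps the subject's
brain onto a common template: values below 1 mean local volume loss, above 1
local expansion. Group analyses of such maps usually fix the unit of analysis
a priori — single voxels, or atlas regions. `hierseg` instead derives the
units from the data: voxels are clustered by how their Jacobian values
co-vary *across the population*, recursively, from the whole intracranial
volume down to small parcels. Every level of this global-to-local hierarchy
is then tested for group differences in two complementary form features per
segment — *size* (the mean Jacobian) and *shape* (the size-normalized
within-segment pattern) — under a single multiplicity-corrected family.

## The segmentation model

For voxels $i, j$ with Jacobian vectors $J_i, J_j$ over subjects, the
affinity is

$$A(i,j) = \tfrac12\,(\mathrm{corr}(J_i, J_j) + 1) \in [0, 1],$$

so anticorrelated voxels repel and correlated voxels attract. With
$D = \mathrm{diag}(d_{ii})$, $d_{ii}$ the $i$-th column sum of $A$, the
normalized Laplacian $L = D^{-1/2} A D^{-1/2}$ is eigendecomposed and the
$k = 2$ leading eigenvectors embed the voxels; Euclidean distance in the
embedding stands in for affinity and k-means bipartitions the segment.
Applying this recursively — every child segment recomputes its own affinity
from its own columns — yields a binary hierarchy; eight levels give up to
$2^8 - 1 = 255$ segments with $2^7 = 128$ leaves. The segmentation is
unsupervised: group labels never enter it, and all subjects (carriers and
non-carriers) contribute.

At realistic scale ($>5\times10^5$ voxels) neither $A$ nor $L$ fits in
memory, so the eigenvectors are estimated with the Nyström method from a
random landmark subset of affinity columns. Two robustness devices tame the
randomness of landmarks and of k-means:

1. **Averaged Nyström** — 50 estimations on independent landmark draws are
   averaged element-wise. Raw eigenvectors carry arbitrary sign and, with
   close eigenvalues, arbitrary rotation; each estimation is therefore
   aligned to the first by per-component sign flips followed by an
   orthogonal Procrustes rotation before averaging. (Averaging the
   eigenvector matrices, rather than Laplacian estimates or partitions, is
   a design choice; naive unaligned averaging cancels the signal.)
2. **Consensus k-means** — k-means is repeated 50 times; each repeat is
   matched to the first valid repeat by maximal overlap, votes are weighted
   by the inverse size of the voting cluster (so a huge cluster cannot
   swamp a small one), and the majority of normalized votes decides. Ties
   break toward the smaller label id; repeats that return an empty cluster
   are discarded, and if all are discarded the fallback thresholds the
   second eigenvector at its median — deterministic by construction.

### Numerical notes

* The Nyström degree estimate uses the low-rank expansion
  $\hat d = C W^{-1} C^\top \mathbf 1$; the one-shot orthogonalization of
  the normalized column block yields orthonormal eigenvectors. With all
  voxels as landmarks the estimate coincides with the dense
  eigendecomposition (verified to $10^{-6}$ in the tests).
* The correlation affinity has rank at most $n_\text{subjects}+1$, so the
  landmark block is *structurally* rank deficient whenever landmarks
  outnumber subjects. The pseudo-inverse handles this silently; a warning
  is raised only if the effective rank cannot support the requested number
  of eigenvectors. (A warning on every structural deficiency would fire on
  essentially every split of a large segment.)
* Embedding rows are normalized to unit length before k-means
  (Ng–Jordan–Weiss convention); configurable off.
* Landmark count defaults to $\max(\lceil 0.1\,n\rceil, 100)$ capped at the
  segment size — standard Nyström practice, configurable.
* Zero-variance voxels (possible in synthetic data, not in smoothed real
  maps) cannot enter a correlation; they are held out of the clustering and
  adopted by their nearest non-degenerate voxel in mask order.
* Segments smaller than `min_segment_voxels` (default 32; real cohorts at
  1.5 mm resolution never approach this, synthetic grids can) become leaves
  early, are recorded, and are excluded from deeper levels.
* Determinism: the tree is a pure function of (cohort, configuration,
  seed). Per-node seeds are derived from the master seed and the node id,
  so subtrees do not share randomness.

### True and false invariances

Pearson correlation across subjects is invariant to a *common* affine
rescaling of the whole data matrix, so a global rescaling of all Jacobians
changes no affinity and no segmentation (tested). It is **not** invariant
to rescaling a single subject's map: that changes single entries of every
voxel column. Per-subject affine maps do leave the sample-homogeneity QC
score invariant, because that score correlates whole rows, not columns.

## Form features

**Size** of a segment is each subject's mean Jacobian over its voxels —
the within-mask analogue of a regional volume change. Sizes decompose
exactly: a parent's size is the voxel-count-weighted mean of its
children's.

**Shape** divides each subject's within-segment Jacobians by that
subject's size (each row then averages to exactly 1), removing the scale
and leaving the spatial pattern. The patterns are mean-centered per voxel
and decomposed by PCA (SVD); when voxels outnumber subjects the
decomposition runs on the subject-side Gram matrix, which is exact and far
cheaper. Column-wise centering is a design choice the source method leaves
open; the row-mean-1 structure makes row-centering meaningless. Horn's
parallel analysis decides how many components carry signal: each of 100
null datasets permutes every column independently across subjects
(preserving marginals, destroying covariance), a component is retained
while its eigenvalue beats the 95th percentile of its null counterpart,
and retention stops at the first failure (consecutive retention, the
standard reading of Horn's rule). Percentile and replicate count are
configurable; the source method states neither.

## Hypothesis testing

Six contrasts compare each mutation's asymptomatic and symptomatic
carriers against non-carriers. The control group pools all non-carriers
(the convention of the covariate-matched univariate analyses this design
follows); age, sex, acquisition site and family membership enter every
model as fixed-effect covariates of no interest. Site and family are
dummy-coded; levels with fewer than two subjects in a contrast are dropped
with a warning (their subjects join the reference class). No intracranial
volume covariate is used anywhere: the Jacobians encode only the
non-linear deformation.

* **Size**: an equal-variance Student's t as the group coefficient of one
  linear model `size ~ group + covariates`, so the degrees of freedom are
  exact; with an empty covariate set this *is* the classical pooled
  two-sample t (machine precision, tested).
* **Shape**: canonical correlation analysis between the retained component
  scores and the group indicator with the covariates partialled out of
  both sets. With a univariate second set, Rao's F transformation of
  Wilks' $\Lambda$ is exact, and with one component and no covariates the
  p-value equals the t test's to $10^{-10}$ (tested). Segments retaining
  zero components are recorded as not computable and excluded from the
  family.
* **Multiplicity**: all p-values — 255 segments × 6 contrasts × 2 features
  = 3060 for a complete tree — form one family corrected by
  Benjamini–Yekutieli ('dep'), the FDR procedure valid under arbitrary
  dependence, which matters here because parent and child segments share
  data. The rejection threshold is data dependent; the thresholds printed
  for the original clinical cohort (P = 0.0007 segmental) are properties
  of that restricted data set and are not reproducible quantities.
  Per-contrast families are available behind a flag. Two-sided p-values
  throughout.

## Exploratory maps

Per contrast and feature, each level yields a binary map of voxels inside
significant segments; the eight binaries are *summed* into a 0–8 weight
map used to average each subject's Jacobians into one weighted value
(normalized by the total weight — "average weighted Jacobian"), and
*concatenated* into one long binary vector when two results are compared
with the Dice coefficient. The sum/concatenate distinction is deliberate
and mirrors the method's description; it is why the size-versus-shape Dice
matrix need not be symmetric and its diagonal can fall below 1.

## The synthetic world

The generator emulates exactly the structure the segmentation assumes —
and nothing else. A balanced binary hierarchy is planted by recursive
spatial bisection of the mask; each internal node carries a latent factor
loading $+1$ on its left and $-1$ on its right child, so covariance is
hierarchically nested and every split has a spectral signature; leaves can
carry independent block factors instead (making between-block correlation
$\approx 0$). Voxel value = 1 (volume preserving, so "atrophy" is < 1) +
factors + group effects + covariate confounds + iid Gaussian noise.
Defaults state a desk-scale world chosen once: a 12³ grid, depth-3
hierarchy, factor sd 0.1 versus noise sd 0.05 (within-leaf correlation
≈ 0.9), 20 subjects per mutation × status cell, age slope −0.002/year,
sex offset 0.01, site offsets with sd 0.01 — confound magnitudes a TBM
analyst would call mild but non-ignorable. Size effects add a constant to
a group's rows over a block; shape effects add a deterministic zero-mean
unit-sd spatial pattern, which leaves every subject's segmental size
mathematically unchanged — size and shape effects are orthogonal by
construction, mirroring the empirical near-disjointness of size and shape
findings.

What the generator does **not** emulate: scanner- or site-specific
covariance, smoothing-induced spatial autocorrelation within blocks,
non-Gaussian tails, registration failures. A green recovery test therefore
establishes that the pipeline recovers planted population covariance
structure, not that it segments real brains anatomically.

### The power world

One acceptance scenario fixes a planted size effect of $0.5\,\sigma$
(noise sd) with 100 subjects per cell. Detection at that effect size is
mathematically noise-limited: the t statistic's non-centrality is
$\delta / (\mathrm{sd}_\text{segment}\sqrt{1/n_a + 1/n_b})$, and with the
default factor sd (2× noise) the latent factors alone contribute
$\sqrt{3}\times0.1 \approx 0.17$ to the segmental sd, driving the
non-centrality below 1 — no test could detect it. The power world
therefore sets the factor sd to $0.2\,\sigma$, giving segmental sd
$\approx \sqrt{3(0.01)^2 + \sigma^2/27} \approx 0.02$ and non-centrality
$\approx 10$ for the planted leaf — ample power even after
Benjamini–Yekutieli correction. This constant was fixed from this
calculation before any simulation was run, and the statistics are
evaluated on the planted segmentation (segmentation recovery is a separate
criterion).

## Known limitations

* Binary splits only; no data-adaptive stopping by segment homogeneity and
  no $k > 2$ splits.
* No asymmetry features: left–right difference patterns are mostly
  invisible to the symmetric shape space.
* Family and site are fixed effects; no mixed models, no longitudinal
  support.
* NIfTI-1 single-file volumes only (the in-tree reader exists because the
  target R stack ships no NIfTI package); no DICOM, no two-file `.hdr/.img`.
* The exact vote-weighting formula of the consensus reference and the
  precise averaging target of the Nyström estimations are not specified by
  the source method; the choices here (inverse-cluster-size votes;
  aligned eigenvector averaging) are documented above and fixed.
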