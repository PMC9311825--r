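# hierseg

Global-to-local brain segmentation by **hierarchical spectral clustering**
of tensor-based-morphometry (TBM) Jacobian maps, with a segmental
statistical framework for detecting group differences in **size** and
**shape** — built for studies of presymptomatic and symptomatic
neurodegeneration (e.g. genetic frontotemporal degeneration cohorts with
*C9orf72*, *GRN* and *MAPT* mutation families), and validated end-to-end on
synthetic cohorts with planted covariance structure.

## What it does

Voxel-wise analyses fix the unit of analysis at a single voxel; atlas-based
analyses fix it a priori at named regions. `hierseg` derives the units from
the population itself. Given co-registered Jacobian-determinant maps
(values < 1 = local volume loss), voxels are clustered by the correlation
of their Jacobian values across subjects:

- affinity `A(i,j) = 0.5 * (corr(J_i, J_j) + 1)`,
- normalized Laplacian `L = D^(-1/2) A D^(-1/2)`,
- the `k = 2` leading eigenvectors embed the voxels, k-means bipartitions,
- recursively, for 8 levels: up to `2^8 - 1 = 255` nested segments from the
  whole intracranial volume down to 128 leaves.

At scale, eigenvectors are estimated by the **Nyström** method (50 averaged
estimations on random landmark subsets) and partitions are stabilized by
**consensus k-means** (50 repeats, normalized vote weighting). Per segment,
**size** (mean Jacobian) is tested with covariate-adjusted equal-variance
t-tests and **shape** (size-normalized pattern, PCA components retained by
Horn's parallel analysis) with canonical correlation analysis; all
p-values across 255 segments x 6 contrasts x 2 features form one
**Benjamini–Yekutieli ('dep')** FDR family. Exploratory outputs include
0–8 thresholded significance maps, per-subject weighted Jacobians,
phenotype ANOVAs and Dice overlap matrices.

## Worked example

Simulate a cohort with a planted hierarchy and a planted size effect
(+0.1 Jacobian on one planted leaf block for symptomatic *C9orf72*
carriers), segment it, and test all contrasts:

```r
library(hierseg)
spec <- synthetic_spec(
  grid_shape = c(8, 8, 8), levels_planted = 3, n_per_group = 20,
  size_effects = list(list(node = 4, mutation = "C9orf72",
                           status = "symptomatic", delta = 0.1)),
  seed = 7)
sim <- generate_cohort(spec)
tree <- build_hierarchy(sim$cohort, levels = 3, seed = 7)
adjusted_rand_index(tree_level_labels(tree, 3), tree_level_labels(sim$tree, 3))
feats <- segment_features(sim$cohort, tree, seed = 7)
res <- run_all_contrasts(tree, feats, sim$table, alpha = 0.05)
```

which prints (abridged):

```
<jacobian_cohort> 180 subjects x 512 masked voxels (grid 8x8x8)
<segment_tree> depth 3, 7 segments (1/2/4 per level), 512 voxels
recovery ARI vs planted leaves: 1
BY threshold: 1.11e-30 over a family of 72 tests
   segment_id level                           contrast feature            p
13          1     1 C9orf72:symptomatic-vs-non-carrier    size 1.111239e-30
weighted Jacobian: carriers 1.039 vs others 1.013
```

Reading this: the segmentation recovers the planted leaf partition exactly
(ARI 1). The planted +0.1 effect is detected in the correct contrast and
feature. It surfaces most strongly at the *global* level here because the
planted nested latent factors load +1/−1 on sibling blocks and therefore
cancel in every ancestor's mean — the ancestor's size is nearly noise-free
while the leaf's size carries the full factor variance. This is exactly the
granularity trade-off the hierarchy exists to expose. The weighted
Jacobian (Jacobians averaged under the significance-weight map) separates
carriers (1.039) from everyone else (1.013), consistent with the planted
`0.1 * 128/512 = 0.025` global dilution.

The same pipeline is scriptable end to end:

```sh
Rscript inst/cli/hierseg simulate --config cfg.json --out sim/
Rscript inst/cli/hierseg segment  --cohort sim/ --levels 8 --seed 7 --out tree.json
Rscript inst/cli/hierseg features --cohort sim/ --tree tree.json --out feats/
Rscript inst/cli/hierseg test     --cohort sim/ --tree tree.json --table sim/cohort.csv --out results.tsv
Rscript inst/cli/hierseg report   --cohort sim/ --tree tree.json --results results.tsv --out report/
```

## Real data

`load_jacobian_cohort()` ingests per-subject NIfTI Jacobian maps plus a
binary intracranial mask (all on one template grid); the cohort table is a
CSV with `subject_id, mutation, status, phenotype, age, sex, site, family`.
`sample_homogeneity()` provides the per-subject QC correlation score. See
the methods vignette (`vignettes/hierseg-methods.Rmd`) for the model,
parameter defaults, numerical choices and known limitations.
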