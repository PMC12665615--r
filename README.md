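# dfamri — director field analysis of white matter geometry

`dfamri` is an R package for quantifying the *geometry* of the white matter
fiber orientation field from diffusion tensor MRI, and for running the
statistical pipeline that turns those geometric maps into group findings,
clinical correlates and staging classifiers. It is aimed at neuroimaging
researchers studying degenerative disease — the motivating application is the
cerebellar subtype of multiple system atrophy, where cerebellar and brainstem
tracts deform in regionally distinct ways that conventional FA/MD summaries
cannot separate.

## The core idea

The principal eigenvector of the diffusion tensor is treated as a **director**
n(x): a unit orientation with antipodal symmetry (n ≡ −n). The spatial
deformation of the director field decomposes into the three classical
distortion modes of an oriented medium, each in units of 1/mm:

| index | formula | meaning |
|---|---|---|
| splay | s = \|∇·n\| | fibers fanning perpendicular to their axis |
| bend  | b = ‖n × (∇×n)‖ | curvature along the fiber axis |
| twist | t = \|n · (∇×n)\| | rotation of neighbors about the axis |

with the **total distortion** d = √(s² + b² + t²). All derivatives are taken
after per-voxel sign alignment, so every map is invariant under arbitrary
sign flips of the input directors. Because the indices depend only on
*orientation change between voxels*, a field of identically shaped tensors
has constant FA and MD while its distortion maps vary — the dissociation the
package's analytic phantoms demonstrate.

Around this core the package provides:

* log-linear diffusion tensor fitting, FA/MD, principal-director extraction
  (`fit_tensor_lls`, `tensor_scalars`, `principal_director`);
* mask-restricted voxelwise GLM group inference with Freedman–Lane
  permutation, TFCE enhancement (Rcpp), exact family-wise error control over
  both contrast directions, and a leave-one-out consistency guard for small
  groups (`glm_tstat`, `tfce_enhance`, `permutation_fwe`, `loo_consistency`);
* atlas-based feature extraction under strict voxel-count inclusion rules
  (`label_clusters`, `parcel_features`, `intersect_coaltered`);
* normality-gated correlations with Benjamini–Hochberg correction and
  eTIV volume normalization (`gated_correlation`, `family_correlations`,
  `bh_fdr`, `volume_normalize`, `group_compare_scalars`);
* a nested cross-validated stacked-ensemble classifier with averaged-ROC AUC
  and permutation feature importance (`stratified_folds`, `fit_stacked`,
  `evaluate_nested`, `permutation_importance`, `top_features`);
* analytic phantoms, a Rician DWI simulator and a synthetic cohort generator
  that give every stage a ground-truth test surface (`make_phantom`,
  `simulate_dwi`, `make_cohort`);
* NIfTI and FSL bval/bvec IO (`read_dwi`, `write_scalar_nifti`, ...).

## Worked example

A helical phantom with twist rate k = 0.1 rad/mm, then a synthetic two-group
cohort with a −1.5 SD twist decrease planted in one region, analyzed end to
end:

```r
library(dfamri)

helix <- make_phantom(phantom_spec("twist", shape = c(24, 24, 24), rate = 0.1))
maps  <- dfa_maps(helix)
maps$twist
#> <scalar_map 'twist'> 24x24x24 grid, 13824 in-mask voxels, range [0.09983, 0.09983]
```

The recovered twist is 0.0998/mm everywhere (the analytic value 0.1 times the
0.17% central-difference sinc bias), while FA stays constant at 0.8704 with
sd 5e-17: orientation changes, tensor shape does not.

```r
eff <- data.frame(group = "MSA", roi = "ROI_B", metric = "twist", size = -1.5)
co  <- make_cohort(cohort_spec(
  metrics = "twist", effects = eff, output = "volumes",
  clinical = data.frame(score = "sara", feature = "ROI_B_twist", r = -0.5),
  seed = 42))

des <- make_design(co$subjects$group,
                   data.frame(age = co$subjects$age,
                              sex = as.numeric(co$subjects$sex)))
res <- permutation_fwe(cohort_metric_matrix(co, "twist"), des,
                       n_perm = 1000, seed = 42)
res
#> <stat_result> 1000 permutations, 200/600 voxels FWE-significant at alpha = 0.05
```

Exactly the 200 voxels of the affected region survive correction. Extracting
the region feature (retained because its 200-voxel overlap exceeds the
50-voxel rule for geometric metrics), correlating it with the generated
clinical score, and classifying:

```r
feats <- parcel_features(label_clusters(res$sig_mask), co$roi_labels,
                         list(twist = co$maps$twist), "DFA",
                         subject_ids = co$subjects$id)
family_correlations(feats, co$clinical["sara"], family = "clinical",
                    group = co$subjects$group)
#>        x_name y_name  method         r        p_raw  n        p_fdr   family
#> 1 ROI_B_twist   sara pearson -0.484805 4.913996e-05 64 4.913996e-05 clinical

evaluate_nested(feats, co$subjects$group, outer_folds = 10, inner_folds = 10,
                seed = 42)
#> <nested_cv> AUC (averaged ROC) = 0.861, pooled = 0.811; accuracy = 0.793,
#>             sensitivity = 0.825, specificity = 0.767
```

The planted correlation (target −0.5) is recovered at r = −0.48, and a single
−1.5 SD feature separates the groups at AUC ≈ 0.86 under nested 10×10
cross-validation, as expected for that effect size.

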