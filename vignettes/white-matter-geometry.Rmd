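---
title: "Measuring white matter geometry with director field analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring white matter geometry with director field analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfamri)
```

## The model

Diffusion tensor imaging summarizes each voxel by a symmetric tensor whose
principal eigenvector points along the dominant fiber direction. Classical
scalar summaries (fractional anisotropy FA, mean diffusivity MD) describe the
tensor *within* a voxel and are blind to how orientation changes *between*
voxels. `dfamri` treats the principal eigenvector as a **director** — a unit
orientation with antipodal symmetry, so $n$ and $-n$ are the same object — and
measures the spatial deformation of the director field $n(x)$ with the three
classical distortion modes of an oriented medium:

* **splay** $= |\nabla \cdot n|$ — fibers fanning apart perpendicular to their
  axis;
* **bend** $= \lVert n \times (\nabla \times n)\rVert$ — curvature of the
  fibers along their axis;
* **twist** $= |n \cdot (\nabla \times n)|$ — rotation of neighboring
  directions about the axis.

All three have units of 1/mm (equivalently rad/mm). The **total distortion**
is their root-sum-of-squares, $d = \sqrt{s^2 + b^2 + t^2}$, a single
non-negative severity index. These continuous-field definitions are the
operative formulas here; reference implementations that discretize in a local
frame may differ in detail, which is why validation is anchored to analytic
phantoms with known closed forms rather than to any particular binary.

Because a director has no preferred sign, every derivative is taken after
*sign alignment*: the field is first put in a canonical per-voxel orientation
(largest-magnitude component positive), and each neighbor entering a finite
difference is flipped when its dot product with the center director is
negative (an exact zero is left unflipped). This makes the Jacobian — and
everything downstream — invariant under arbitrary per-voxel sign
reassignments, which the test suite checks to $10^{-12}$.

### Discretization choices

* Central differences, falling back to one-sided differences where a neighbor
  leaves the mask. The default keeps thin structures; `erode_boundary = TRUE`
  restricts to voxels with a full stencil instead. Voxels with no in-mask
  neighbor along an axis get a zero derivative there and are flagged.
* Derivatives are divided by the physical voxel spacing, so anisotropic
  acquisitions (e.g. 1.8 x 1.8 x 2 mm) are handled correctly.
* Magnitudes are reported (the indices are non-negative severity measures),
  and no smoothing or neighborhood normalization is applied before
  differencing.
* Radial and circular phantoms mask a one-voxel core around the central
  singularity, where the analytic 1/r indices diverge.

On a helical phantom with twist rate $k = 0.1$ rad/mm the discrete twist is
$k \,\mathrm{sinc}(k\,\Delta z)$ — a 0.17% bias at 1 mm spacing — and interior
splay/bend vanish to rounding error; on radial/circular phantoms the recovered
index tracks $1/r$ within 5% for $r \ge 5$ voxels, improving as the voxel size
shrinks:

```{r phantom}
helix <- make_phantom(phantom_spec("twist", shape = c(16, 16, 16), rate = 0.1))
maps <- dfa_maps(helix)
mean(maps$twist$values[5:12, 5:12, 5:12])   # ~0.0998, analytic value 0.1
```

## Tensor estimation and the director

`fit_tensor_lls()` solves the log-linear model
$\log S_i = \log S_0 - b_i\, g_i^\top D\, g_i$ by ordinary least squares
(default) or signal-weighted least squares (`method = "wls"`). The unweighted
fit is the default because the single-shell, 30-direction design it targets is
well conditioned and the choice is then exactly invertible on noise-free data
(validated to $10^{-10}$). Negative eigenvalues are clamped to zero rather
than rejecting voxels, preserving the mask for spatial derivatives. FA and MD
are computed from rotation invariants; the director is the leading
eigenvector, with voxels masked out when FA falls below `fa_floor` (default
0.1 — deliberately below the 0.2 analysis threshold, since directors are
meaningless in near-isotropic voxels) or when the two leading eigenvalues are
degenerate (relative gap below $10^{-6}$).

The DWI simulator adds **Rician** noise — the magnitude of two independent
Gaussian channels with $\sigma = S_0/\mathrm{SNR}$ — because magnitude MR data
are Rician, not Gaussian; its second moment $\nu^2 + 2\sigma^2$ is verified by
simulation.

## Voxelwise inference

Group comparisons use a per-voxel GLM with the group indicator and demeaned
nuisance covariates (age, sex), reducing exactly to the pooled-variance
two-sample *t*-test when covariates are absent. Significance is assessed by
**Freedman–Lane permutation**: residuals from the nuisance-only model are
row-permuted, the full model is refit, and each permutation contributes the
maximum **TFCE**-enhanced statistic over the analysis mask.

TFCE integrates cluster extent over all thresholds,
$\mathrm{TFCE}(v) = \sum_h e_h(v)^E\, h^H\, \mathrm{d}h$ with the neuroimaging
defaults $E = 0.5$, $H = 2$, 26-connectivity, and $\mathrm{d}h$ set per map to
max/100 (the implementation is an incremental union-find over descending
thresholds, verified voxel-for-voxel against a brute-force component-labeling
oracle). Conventions worth stating:

* **Both contrast directions** are enhanced ($+t$ and $-t$) and reported as
  separate maps, mirroring the increase/decrease maps such studies publish.
  The permutation null records the maximum TFCE across *both* directions, and
  both observed maps are compared against that common null, so the union of
  the two significance maps controls family-wise error at $\alpha$ exactly —
  a property the suite verifies on 200 null cohorts. When a specific direction
  is hypothesized (e.g. a planted decrease in a simulation), selectivity is
  read off that direction's map.
* Corrected p-values use $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$,
  so no p-value is ever exactly zero.
* If the group labelling admits fewer distinct reassignments than `n_perm`
  (and there are no covariates), the distinct assignments are enumerated
  exhaustively with a warning.
* The analysis mask is mean-FA $> 0.2$ intersected with an anatomical region
  mask. Full skeleton projection and nonlinear registration are out of scope:
  subjects are assumed to share a grid, which the synthetic cohorts do by
  construction. Results on real data therefore require prior spatial
  normalization by other tools.

For small groups, `loo_consistency()` repeats the full comparison once per
left-out member of the small group and intersects the significance masks, so
a finding driven by a single subject cannot survive.

Scalar measures (e.g. brainstem subregion volumes normalized to eTIV) are
compared with a normality-gated test: Shapiro–Wilk within each group plus
Levene's homogeneity test choose between the pooled *t*-test and the
Mann–Whitney U test, with Benjamini–Hochberg correction across the family.
The same gate (Shapiro–Wilk alone when no grouping exists — homogeneity is
undefined for an ungrouped pair) chooses between Pearson and Spearman
correlation in `gated_correlation()`. Correlation families (clinical scores,
subregion volumes, cross-modal fixel columns) are corrected separately, as
distinct analyses.

## Feature extraction

Significant clusters are labeled at 26-connectivity and intersected with an
integer atlas volume. A parcel-metric is retained only when the overlap
*strictly exceeds* the family threshold — more than 100 voxels for FA/MD and
fixel-based metrics, more than 50 for the geometric indices — and co-altered
regions require an *inclusive* 30 voxels in the intersection of two
significance maps. Overlap is counted per parcel total (not per cluster); the
thresholds follow the strict/inclusive distinction exactly as stated.
Features are per-subject means over the overlap voxels, and every emitted
column carries its provenance voxel count, which is asserted against the
threshold on every table. No atlas files are shipped; synthetic label volumes
stand in, and users supply their own atlas on real data.

## Staging classifier

`evaluate_nested()` implements the two-tier protocol: an outer stratified
10-fold cross-validation reserves each fold in turn as an untouched test set;
within each training set, heterogeneous base learners (ridge logistic
regression, a probability random forest, naive Bayes) are cross-fit over
inner stratified folds, and a ridge meta-learner is trained **only on their
out-of-fold predictions** before the bases are refit on the full training
set. The roster is deliberately small and fixed: the protocol (not an AutoML
model zoo, whose exact contents are irreproducible) is the contract, and no
training-time budget is emulated — everything is deterministic per seed. A
diagnostic `meta_input = "insample"` variant trains the meta-learner on leaky
in-sample predictions; a regression test asserts its apparent AUC is never
below the leakage-safe variant's.

ROC curves are averaged vertically (mean TPR on a fixed 101-point FPR grid
across folds) and the AUC is the trapezoidal area of the averaged curve; the
pooled-prediction AUC is reported alongside and agrees within 0.02 on large
cohorts. Accuracy, sensitivity and specificity use a 0.5 score threshold
(the natural cut for calibrated probabilities). Permutation feature
importance is the mean held-out-fold AUC drop when a feature column is
shuffled, averaged across folds, with the top-10 report normalized to the
maximum. On a single Gaussian feature with effect size $\delta/\sigma = 2$
the nested AUC matches the closed form
$\Phi(\delta/(\sigma\sqrt{2})) \approx 0.921$ within 0.05.

For stage discrimination, the feature set is restricted to the six
stage-different geometric features (twist and distortion in the middle
cerebellar peduncle, pontocerebellar tract, and right corticospinal tract);
the cohort generator can emit a matching six-column table by relabeling its
regions:

```{r staging, eval = FALSE}
lab <- default_roi_labels()
attr(lab, "lookup") <- c(MCP = 1L, PCT = 2L, CST_R = 3L)
eff <- expand.grid(group = "late", roi = c("MCP", "PCT", "CST_R"),
                   metric = c("twist", "distortion"), stringsAsFactors = FALSE)
eff$size <- -1.5
co <- make_cohort(cohort_spec(
  n_per_group = c(early = 15, late = 16), metrics = c("twist", "distortion"),
  roi_labels = lab, effects = eff,
  age = list(early = c(mean = 54.4, sd = 7.6), late = c(mean = 60.3, sd = 5.0)),
  sex_prop_female = c(early = 0.45, late = 0.45), seed = 42))
evaluate_nested(co$features, co$subjects$group, seed = 42)
```

## What the synthetic data do and do not emulate

The generator produces the structures the pipeline needs with known ground
truth: constant-shape tensor fields with analytically known distortion maps;
two-group cohorts (defaults 33 controls vs 31 patients, with a 15/16
early/late split available) with region-level metric values
$\mathcal{N}(\text{baseline}, \sigma_s)$, planted (group, region, metric)
effects in units of $\sigma_s$, age/sex covariates matching the published
demographics, clinical scores and fixel-metric stand-in columns constructed
to a specified population correlation, and brainstem volume tables with eTIV.

Defaults, chosen once and documented rather than fit to anything: baseline
1.0 and between-subject SD $\sigma_s = 0.1$ (dimensionless — no absolute
index scales are established for patient populations, so the baseline is
arbitrary and effects are what matter); voxelwise measurement noise SD 0.05,
half the between-subject SD, reflecting that regional biological variability
dominates well-averaged voxel noise; a 10 x 10 x 8 label volume with three
200-voxel slab regions separated by background planes (so clusters cannot
bridge regions), small enough that a 500-permutation TFCE analysis takes
about a second; brainstem volumes (medulla 4600, midbrain 6500, pons
14500 mm^3, 8% CV) with a strong planted pontine atrophy, and eTIV
$\mathcal{N}(1.45 \times 10^6, 1.2 \times 10^5)$ mm^3.

What this *does not* emulate: real anatomy and registration error, spatially
correlated physiological noise, crossing fibers, multi-shell acquisitions,
motion/eddy artifacts, or any relationship between the metric volumes and an
underlying tensor field (cohort metric maps are generated directly, not
through the tensor pipeline). Passing tests therefore demonstrate that the
algorithms are correct and calibrated on data satisfying their assumptions —
not that any particular clinical effect will replicate on scanner data.

## Problem sizes and numerical conventions

The test suite and the acceptance script run everything at deliberately
modest sizes — 32^3 phantoms, 200 null cohorts at 500 permutations for the
calibration check, 50 planted-effect runs, 10–40 classifier seeds — chosen so
the whole validation completes in minutes on one core while keeping binomial
confidence bands tight enough to be meaningful. Degenerate inputs follow
fixed rules: zero-variance voxels get $t = 0$ and a flag; isotropic or
eigenvalue-degenerate voxels are masked out of the director field with a
count; constant inputs to correlation or group comparison raise errors rather
than silently returning NaN; empty significance masks warn and propagate as
empty feature sets.

## Known limitations

* No skeleton projection or registration: the grid-shared assumption is the
  major simplification relative to a full tract-based pipeline.
* Fixel-based metrics are consumed as precomputed feature columns; computing
  them is out of scope.
* The reference discretization of the distortion indices in other tools may
  differ near mask boundaries; this implementation's behavior there is the
  documented one-sided-difference rule.
* The leave-one-out consistency report is conservative by construction; with
  marginal effects it can return an empty intersection even when the pooled
  analysis is significant.
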