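---
title: "Intratumoral and peritumoral radiomics for TME prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intratumoral and peritumoral radiomics for TME prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The composition of the tumor microenvironment (TME) — the extracellular-matrix
(ECM) proteins collagen, laminin and nidogen, and the balance between
regulatory (FOXP3+) and cytotoxic (CD8+) T cells — carries prognostic
information in invasive breast cancer, but quantifying it requires tissue.
`radiotme` implements a noninvasive surrogate: radiomic texture analysis of
multiparametric breast MRI, using both the segmented tumor (intratumoral
region) and a thin shell of surrounding tissue (peritumoral region), to
predict whether each TME component is above or below its cohort median.

The pipeline is:

1. **Region geometry.** Each image/mask pair is resampled to a 1 mm isotropic
   grid (trilinear for images, nearest-neighbour for masks). The peritumoral
   annulus is built by *physical-distance* dilation: every voxel whose
   centre lies within 4 mm (Euclidean, in mm) of a tumor voxel centre,
   minus the tumor itself, clipped to the image bounds. An 8 mm annulus is
   available for margin-sensitivity analysis.
2. **Feature extraction.** A fixed, countable registry of 1618 features per
   region per sequence: 17 first-order statistics, 7 shape features,
   162 texture features (GLCM + GLRLM), and 1432 wavelet features
   (first-order + texture recomputed on the 8 sub-bands of a single-level
   3D Haar decomposition). With five sequences (T2, DWI b=800, precontrast
   T1, initial and delayed postcontrast T1) and two regions (intratumoral;
   intratumoral + peritumoral combined), each case yields 16 180 features.
3. **Signature discovery.** Features are z-scored, the cohort is split 7:3,
   and an L1-penalized (LASSO) linear model of each binary TME label is
   refit 25 times on the training cohort, re-randomizing the fivefold CV
   partition each time. Features with nonzero coefficients in at least 20 of
   the 25 iterations are *significant*; the top 5 (by selection count, then
   mean |coefficient|, then name) form the radiomic signature, which enters
   an ordinary least-squares linear model of the label.
4. **Evaluation.** Test-cohort AUC with percentile-bootstrap 95% CIs
   (2.5/97.5 percentiles, 1000 replicates), confusion-matrix metrics at the
   training Youden threshold, paired DeLong tests between the
   intratumoral-only and combined models with Bonferroni-corrected
   thresholds (0.05/m for m = 5, 4, 2 comparisons), fivefold cross-validated
   AUCs in which the *entire* selection + fit pipeline reruns inside each
   fold, decision curves over threshold probabilities 0.10–0.40, and
   subtype-stratified bootstrap comparisons (strata with fewer than 10 cases
   are excluded).

Because the patient cohort behind the original analysis is not publicly
deposited, the package ships a synthetic cohort generator whose statistical
structure matches what the analysis assumes; every stage is tested against
analytic oracles and calibration simulations on that generator.

# The synthetic cohort generator

`generate_cohort()` draws, per case:

- **Latents.** `u_ecm` and an immune-specific component `e_imm`, i.i.d.
  standard normal; the immune latent is `u_imm = rho*u_ecm +
  sqrt(1-rho^2)*e_imm` with `latent_correlation` rho = 0.3 by default.
- **TME panel.** Collagen, laminin and nidogen immunoreactivities are
  lognormal in `u_ecm` (`exp(0.8*u_ecm + 0.3*eps)`), regulatory T-cell
  counts rise with `u_imm` and cytotoxic T-cell counts fall with it, both
  rounded positive counts. Binary labels are strict median splits (values
  equal to the median get label 0). Molecular subtype is multinomial with
  frequencies 57/121, 49/121, 4/121, 11/121 (luminal A/B, HER2-enriched,
  triple-negative).
- **Planted image signal.** The intratumoral texture amplitude is
  `sigma_tex = 10*exp(0.25*x)` with driver
  `x = d*collagen_class + 0.25*e_imm + eta`, where `eta` is sized so the
  non-class variance is exactly 1. Because the measured intratumoral
  intensity SD is a strictly monotone transform of `x` (up to small
  estimation noise), the ideal feature's AUC against the collagen label is
  the binormal value `pnorm(d/sqrt(2))` by construction, and texture rises
  with the Treg latent and falls with the CD8 latent through `e_imm`. The
  immune modulation deliberately enters through the component of the immune
  latent orthogonal to the ECM latent, so the planted discriminability `d`
  is exact rather than inflated by latent correlation. The peritumoral rim
  (a ramp of width 6 mm outside the tumor surface, amplitude
  `12*exp(0.25*y)`) mirrors this with the Treg class as the class driver,
  giving combined-region models a genuine advantage for immune endpoints.
- **Geometry.** Tumors are random-orientation ellipsoids with diameters
  uniform on `tumor_diameter_range_mm` (default 10–115 mm, matching the
  population the method targets: sub-centimetre tumors are excluded) and
  axis ratios uniform on 0.65–1. All five sequences sample one underlying
  continuous noise field (trilinear interpolation of a 1 mm white-noise
  lattice) on their own acquisition grids — 1 mm isotropic for the three T1
  volumes, 0.33 x 0.33 x 3 mm for T2, 1.21 x 1.21 x 4 mm for DWI — plus
  additive white acquisition noise (SD 2).

The default `effect_size_d = 1.3` puts the ideal-feature AUC at
`pnorm(1.3/sqrt(2)) ~ 0.82`, the performance regime the method is designed
to operate in. The generator's defaults are the study conditions; tests and
examples that need many cases shrink only the tumor-diameter range (to
10–30 mm) so volumes stay tractable — tumor size does not enter the planted
signal, only the per-case estimation noise of the texture SD.

What the generator does **not** emulate: MRI acquisition physics (coil
profiles, k-space sampling, IVIM decay), breast anatomy (no skin/chest-wall
clipping of the annulus), spatially structured stroma, inter-sequence
misregistration, and histology image formation. Passing tests therefore
demonstrate internal correctness and statistical calibration of the
pipeline, not clinical performance on real data.

`null_cohort()` severs the label–image link (drivers become independent
noise) and is the negative control for selection and type-I-error tests.
`planted_feature_table()` is the feature-space counterpart — one binormal
discriminator of separation `d` plus pure-noise features — used wherever
image-scale extraction would be wasteful (e.g. selection/evaluation
calibration at n = 500).

# Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `margin_mm` | 4 (8 for sensitivity) | mm | peritumoral annulus thickness |
| `target_spacing_mm` | 1 | mm | isotropic grid before extraction |
| `n_bins` | 32 | levels | fixed-bin-count discretization for histogram/GLCM/GLRLM |
| texture offset | 1 | voxel | co-occurrence/run distance on the isotropic grid |
| `split_ratio` | 0.7 | — | train fraction of the 7:3 split |
| `n_iterations` / `selection_threshold` | 25 / 20 | — | stability-selection rule |
| `top_k` | 5 | features | signature size |
| `lambda_grid` | log-spaced 1–0.005 | — | brackets the reference optimum 0.05 |
| `bootstrap_reps` | 1000 | — | percentile CIs and subtype tests |
| decision thresholds | 0.10–0.40 step 0.01 | probability | net-benefit grid |

# Numerical and design choices

- **Distance transform.** Dilation uses the exact squared Euclidean distance
  transform (Felzenszwalb–Huttenlocher, per-axis lower envelopes, compiled),
  with centre-to-centre distance and inclusive comparison
  `d^2 <= margin^2 (1 + 1e-9)` to absorb float error on lattice-exact radii.
  On a 1 mm grid a 4 mm dilation of a single voxel is exactly the 257-point
  lattice ball.
- **Discretization.** The source analysis does not state its discretization;
  we use a fixed bin count (32) over the region's intensity range, which
  makes discretized texture features invariant under adding a constant to
  the image. Constant regions map to level 1.
- **GLCM/GLRLM.** Matrices are computed per direction over the 13 unique 3D
  offsets; GLCM is symmetric (pairs counted both ways) and normalized.
  The 162-feature texture block realizes the printed count as 26 GLCM
  descriptors x 5 direction-aggregation statistics (mean/SD/min/max/range)
  plus 16 GLRLM descriptors x 2 (mean/SD) — the `_Std` suffix on published
  signature names motivates per-direction computation with statistic
  aggregation. Descriptors undefined on degenerate matrices (Correlation,
  IMC1/2, MCC on a single occupied gray level) return `NaN`;
  `extract_all()` raises an error naming the feature rather than silently
  emitting 0, so degenerate ROIs surface instead of polluting tables.
- **Wavelets.** Single-level *undecimated* (stationary) Haar decomposition
  with circular boundary: sub-bands keep the input grid, so the tumor mask
  applies directly, and the inverse is exact (`x = (L + H)/sqrt(2)` per
  axis), which the tests exploit as a perfect-reconstruction invariant.
  Shape features are computed once from the mask, not per sub-band — this is
  what makes the wavelet block 8 x (17 + 162) = 1432.
- **Surface area.** Marching tetrahedra with linear interpolation over a
  vertex-centred field (each mesh vertex averages its 8 adjacent voxels).
  Plain binary marching tetrahedra overestimates curved surfaces by ~25%
  (diagonal staircase); the smoothed field removes that bias (digital ball
  r = 15: within ~2% of the true sphere area, sphericity 0.98) at the cost
  of chamfering sharp edges at the one-voxel scale (a 10-voxel cube measures
  ~532 mm^2 against the ideal 600, sphericity 0.91 against the ideal 0.806).
  Masks too small to mesh fall back to exposed voxel-face area. Maximum 3D
  diameter uses surface voxels, deterministically thinned above 3000 points.
- **First-order conventions.** SD/variance/skewness/kurtosis use the
  population denominator `n`; kurtosis is excess (0 for a normal
  distribution); energy is the plain sum of squared intensities.
- **Lambda rule.** Each stability-selection iteration picks the penalty by
  fivefold CV from the grid. We use the one-standard-error rule by default:
  the plain CV minimizer lets features that are chance-correlated with the
  label pass the 20/25 threshold even on signal-free data (the data are
  fixed across iterations; only folds re-randomize), which both breaks the
  empty-null property and dilutes recovered signatures with noise features.
  The 1-SE rule keeps the significant set empty on null cohorts and the
  pipeline's cross-validated AUC close to the planted binormal value. The CV
  minimizer and a fixed lambda = 0.05 remain available as options. The 25
  iterations re-randomize folds only (no case resampling), the stricter
  reading of the iterated-selection procedure.
- **Normalization order.** The default normalizes over all cases before
  splitting, replicating the published order; `normalization_scope =
  "train_only"` is available for leakage-free hygiene. On well-behaved
  synthetic cohorts the two differ negligibly because features are
  homogeneous across the split.
- **Linear probability scoring.** The signature model is OLS on the 0/1
  label, as published, with logistic regression as an option. The
  classification threshold (never stated in the source) is the
  training-set Youden point. Scores are min-max calibrated against the
  training score range before decision-curve analysis.
- **Composite endpoints.** `ecm_overall` is the median split of the mean
  z-scored ECM components; `immune_overall` averages z-scored Treg counts
  with sign-reversed z-scored CD8 counts. The source does not define its
  composite; this is the package's choice and is configurable in analysis
  code.
- **Ties in AUC** count one half (Mann–Whitney convention); the DeLong test
  uses midrank structural components and returns p = 1 by convention for
  identical score vectors.
- **Determinism.** Every stochastic stage takes a seed; `run_pipeline()`
  derives per-stage seeds from one master seed (`derive_seed()`), and
  `with_seed()` restores the caller's RNG state, so a single integer
  reproduces an entire run bit for bit.

# Problem sizes in tests and scripts

Unit tests run on small fixtures (grids up to 20^3, cohorts of 10–25 cases
with 10–16 mm tumors). The calibration checks use the sizes the properties
are stated at: DeLong null calibration with 2000 replicates at n = 120;
bootstrap coverage over 500 (tests) / 300 (script) datasets at n = 120 with
1000 bootstrap replicates; pipeline signal recovery at n = 500 with
d = 1.3 (averaged over three planted tables to damp fold noise); null
stability selection over 20 (tests) / 10 (script) seeds at n = 150 with 100
noise features; the image-level planted-AUC check at n = 500 cases with
10–30 mm tumors. The end-to-end demonstration runs 60 cases, one sequence,
two endpoints, both region modes.

# Known limitations

- The annulus is clipped to image bounds only, not to breast tissue; real
  peritumoral shells near skin or chest wall would include non-tissue voxels.
- The exact identity of the original 162 texture and 17 first-order features
  is not recoverable from printed counts and names; the registry realizes
  the counts with the classical descriptor sets and is data-driven, so a
  different realization can be swapped in.
- Surface-area estimation trades edge fidelity for curvature fidelity (see
  above); absolute shape values are estimator-specific.
- Linear probability scoring can leave the [0, 1] range; decision curves
  rely on min-max calibration rather than a proper probability model.
- Synthetic cohorts cannot validate clinical performance; they validate the
  machinery.
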