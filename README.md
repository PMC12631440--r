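# radiotme

Intratumoral **and** peritumoral MRI radiomics for predicting
tumor-microenvironment (TME) components in invasive breast cancer.

## The problem

The TME — extracellular-matrix (ECM) proteins (collagen, laminin, nidogen)
and immune-cell densities (FOXP3+ regulatory T cells, CD8+ cytotoxic
T cells) — shapes prognosis and treatment response, but assessing it requires
tissue. `radiotme` implements a noninvasive surrogate for researchers in
quantitative imaging: radiomic texture models built from multiparametric
breast MRI that classify each TME component as above or below its cohort
median, comparing models that use the tumor alone against models that add a
peritumoral shell.

The core pipeline, per MRI sequence (T2, DWI b=800, precontrast T1, initial
and delayed postcontrast T1):

1. **Regions.** Resample image + tumor mask to a 1 mm isotropic grid; build
   the peritumoral annulus as the exact Euclidean-distance dilation of the
   tumor by margin *r* = 4 mm (8 mm for sensitivity analysis) minus the
   tumor: `peri = {v : d(v, tumor) <= r} \ tumor`.
2. **Features.** Extract a fixed registry of 1618 features per region:
   17 first-order, 7 shape, 162 texture (26 GLCM descriptors x
   {mean, SD, min, max, range} over the 13 unique 3D directions + 16 GLRLM
   descriptors x {mean, SD}), and 8 x 179 = 1432 Haar-wavelet sub-band
   features. Two regions x five sequences = 16 180 features per case.
3. **Signatures.** After z-scoring and a 7:3 split, iterated LASSO stability
   selection on the training cohort (25 iterations of fivefold
   cross-validated LASSO; features selected >= 20 times are significant; the
   top 5 form the signature), then an OLS linear model of the binary label:
   `score = b0 + sum_k b_k x_k`.
4. **Evaluation.** Test AUC (Mann–Whitney) with percentile-bootstrap 95% CIs,
   confusion metrics at the training Youden threshold, paired DeLong tests
   between intratumoral-only and combined models with Bonferroni-corrected
   thresholds (0.05/m), fivefold cross-validated AUCs re-running the whole
   selection pipeline per fold, decision curves
   (`NB(pt) = TP/n - FP/n * pt/(1-pt)` over pt = 0.10–0.40), and
   subtype-stratified bootstrap comparisons.

Because the original patient cohort is not publicly deposited, the package
includes a synthetic multiparametric cohort generator
(`generate_cohort()` / `null_cohort()`) with analytically controlled planted
effects: the ideal discriminating feature has binormal AUC
`pnorm(d / sqrt(2))` against the collagen label by construction, which gives
every downstream stage a closed-form oracle. See the methods vignette
(`vignettes/radiotme-methods.Rmd`) for the full model and design rationale.

## Worked example

```r
library(radiotme)

# a 40-case synthetic cohort, small tumors for speed
coh <- generate_cohort(cohort_config(n_cases = 40, seed = 1,
                                     tumor_diameter_range_mm = c(10, 16)))
case <- generate_case(coh, 1, sequences = "T1_delayed")

iso  <- resample_isotropic(case$images$T1_delayed, case$masks$T1_delayed)
regs <- build_regions(iso$mask, region_config(margin_mm = 4))
regs
#> <region_set> margin 4 mm: tumor 1526 vx, annulus 3778 vx, combined 5304 vx

fv <- extract_all(iso$image, regs$combined)
length(fv)
#> [1] 1618
round(fv[c("first_order_StandardDeviation", "glcm_Contrast_Mean",
           "shape_Sphericity")], 3)
#> first_order_StandardDeviation            glcm_Contrast_Mean
#>                        15.876                        27.075
#>              shape_Sphericity
#>                         0.984
```

The `region_set` shows the 4 mm annulus holding ~2.5x the tumor's voxels at
this size; the 1618-length vector is one region's feature block, and the
three printed values are the combined-region intensity spread, mean
co-occurrence contrast over the 13 directions, and the near-spherical mask's
sphericity. An end-to-end run wires the stages together:

```r
rep <- run_pipeline(run_config(
  cohort = cohort_config(n_cases = 40, seed = 1,
                         tumor_diameter_range_mm = c(10, 16)),
  endpoints = "collagen", sequences = "T1_delayed", master_seed = 5))
summary(rep)[, c("endpoint", "mode", "auc")]
#>   endpoint              mode       auc
#> 1 collagen intratumoral_only 0.8000000
#> 2 collagen          combined 0.6857143
```

Both models recover the planted collagen signal on the 12-case test split
(intratumoral test AUC 0.80); at this desk scale the combined model's larger
candidate pool costs it a little test AUC for the ECM endpoint, while for
immune endpoints it is the combined model that sees the peritumoral rim
signal.

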