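# thioseg

Weakly supervised segmentation and morphometric profiling of
thioflavin-S-positive parenchymal amyloid deposits in fluorescence
micrographs — using only patch-level presence/absence labels, never
pixel-level annotation.

## Who this is for

Quantitative neuropathology groups who can say *whether* a cropped region
contains parenchymal amyloid pathology but cannot afford dense manual
masks. Thioflavin-S stains both plaques and vascular amyloid brightly, so
plain thresholding cannot isolate the parenchymal fraction; the pipeline
learns the semantic distinction from image-level labels alone.

## The method

The chain has three learned/analytic stages plus statistics:

1. **Preprocessing.** A multi-image illumination correction function
   (ICF) — the smoothed pixelwise mean of many micrographs — removes
   vignetting by division (`estimate_icf`, `apply_icf`). Background is
   selected by the Silver Mountain Operator: the norm of a 7-px moving
   average of unit gradient vectors, which concentrates near 0 in
   uncorrelated background; pixels below the 5th SMO percentile define the
   background distribution whose median is subtracted
   (`smo_map`, `subtract_background`).

2. **CAM localization.** A compact fire-module classifier with a
   thresholded-average-pooling head — TAP(τ) = mean of activations above
   τ — is trained on patch labels with class-conditional mixup
   (`train_classifier`). Class activation maps
   `Σ_k max(w_k, 0) · F_k` (negative head weights clamped) coarsely
   localize deposits (`extract_cam`).

3. **Pseudo-labels → segmenter.** CAM > 0.5 components become an object
   bank, screened by margin contrast so that bright structures continuing
   beyond their mask (vascular segments) are excluded
   (`margin_contrast`); CAM > 0.2 regions, dilated, are inpainted away to
   build a background bank (`build_banks`). Training scenes are synthesized by
   soft copy-paste: object contours are polygon-approximated, perturbed
   along local normals, pasted with distance-weighted edge blending, and
   the blend ring is ignored during training (trimap)
   (`compose_scene`). A valid-convolution encoder–decoder (572→388 at
   full scale) is trained with the asymmetric unified focal loss
   `L = λ·L_maF + (1−λ)·L_maFT` (λ = 0.5, δ = 0.6, γ = 0.5)
   (`train_segmenter`, `unified_focal_loss`), and applied to full
   micrographs by mirrored overlap tiling plus thresholding, hole
   filling, size and border exclusion (`predict_full`, `postprocess`),
   followed by morphology-based vascular exclusion: predicted components
   whose containing bright region extends far beyond them sit on vessels
   and are removed (`exclude_vascular`).

4. **Morphometry + statistics.** 19 parameters per deposit — log-scale
   size and convex-hull metrics, box-counting fractal dimension and
   lacunarity, shape and symmetry ratios, intensity descriptors
   (`assemble_records`) — then PCA over deposits and ANOVA + Tukey HSD of
   component scores across region × dementia groups (`run_pca`,
   `compare_groups`), all under patient-wise group k-fold
   cross-validation (`make_fold_plan`, `evaluate_pipeline`).

Because the source material (autopsy tissue) has no public accession, the
package includes a seeded synthetic-micrograph generator with full ground
truth — bright plaque cores with diffuse halos, bright but semantically
negative vessels, vignetting, background fluorescence, subject structure
and plantable group effects (`generate_scene`, `generate_cohort`).

## Worked example

```r
library(thioseg)

sc  <- generate_scene(scene_spec(seed = 7))        # 512 px synthetic scene
bg  <- subtract_background(sc$image)
bg$model$bg_median
#> [1] 37

rec <- assemble_records(sc$image, sc$gt$instance_labels,
                        microns_per_pixel = 0.9)
round(rec[1:3, c("deposit_area", "circularity", "solidity",
                 "fractal_dimension", "diffuseness")], 3)
#>      deposit_area circularity solidity fractal_dimension diffuseness
#> row       1010.07       0.918    0.961             1.738       0.564
#> row1       417.15       0.972    0.952             1.617       0.600
#> row2       579.96       0.878    0.952             1.696       0.566
```

The background median estimate (37) sits close to the planted level of 40
(the scene's vignette dims the corners); deposit areas are in µm², the
dimensionless shape metrics behave as expected for near-elliptical deposits
(circularity below 1, solidity near but not above 1, fractal dimension
between 1 and 2), and diffuseness ≈ 0.57 reflects the halo-dominated
profile of the generated plaques.

The full weakly supervised chain on a cohort:

```r
subjects <- data.frame(subject_id = paste0("S", 1:6),
                       region   = rep(c("parietal", "temporal"), 3),
                       dementia = rep(c("yes", "no"), each = 3))
ds   <- generate_cohort(cohort_spec(subjects, scenes_per_subject = 4,
                                    seed = 42))
plan <- make_fold_plan(unique(subjects$subject_id))
rep  <- evaluate_pipeline(ds, plan, desk_profile(seed = 42),
                          folds = c(1, 4))   # ~16 min on one CPU
print(rep)
#> weakly supervised pipeline report over 2 fold(s)
#>   mean patch accuracy 0.914, dice 0.879, jaccard 0.786, vessel FP rate 0.0000
```

A Dice of ~0.88 against the synthetic ground truth with no vessel pixels
misclassified shows the pipeline learned the parenchymal/vascular
distinction from patch labels alone.

## Layout

- `R/`, `src/` — implementation (image ops via EBImage; the small
  convolutional networks run on bespoke RcppArmadillo kernels).
- `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles.
- `vignettes/weakly-supervised-amyloid-segmentation.Rmd` — the methods
  vignette: model, assumptions, parameter choices, numerical conventions,
  limitations.
- `inst/cli/thioseg.R` — thin command-line wrapper (`synth`, `measure`,
  `stats`).
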