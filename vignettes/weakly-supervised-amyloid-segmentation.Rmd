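---
title: "Weakly supervised segmentation and morphometry of ThioS-stained amyloid deposits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised segmentation and morphometry of ThioS-stained amyloid deposits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Thioflavin-S (ThioS) labels beta-sheet amyloid aggregates in brain tissue
with bright green-yellow fluorescence. Quantifying parenchymal amyloid
deposits (plaques and pre-amyloid structures) in epifluorescence micrographs
normally requires dense pixel-level annotation, which is prohibitively
expensive. The additional complication is that ThioS is not specific to
parenchymal pathology: vascular amyloid is just as bright, so any useful
segmenter must learn a *semantic* distinction that intensity thresholding
cannot make.

`thioseg` implements a weakly supervised pipeline that needs only patch-level
presence/absence labels:

1. **Preprocessing** — retrospective multi-image illumination correction and
   gradient-based background estimation;
2. **Localization** — a compact fully convolutional classifier with a
   thresholded-average-pooling (TAP) head, from which class activation maps
   (CAMs) are extracted with negative head weights clamped to zero;
3. **Pseudo-label refinement** — CAMs are converted by two-level
   thresholding into an object bank (high-confidence deposits with local
   context) and a background bank (scenes with all candidate foreground
   inpainted away); synthetic training scenes are then composed by soft
   copy-paste of contour-perturbed objects into backgrounds, and a
   valid-convolution encoder–decoder segmenter is trained on them with the
   asymmetric unified focal loss;
4. **Morphometry and statistics** — 19 parameters per segmented deposit,
   PCA over deposits, and ANOVA + Tukey comparison of component scores
   across region-by-dementia groups, all evaluated under patient-wise group
   k-fold cross-validation.

Because no public image set accompanies this problem (the source material is
autopsy tissue), the package ships a seeded synthetic-micrograph generator
that provides every stage with ground truth.

## The synthetic data model

`generate_scene()` renders, on the 8-bit 0–255 scale:

- **Plaques**: an elliptical core of constant intensity $I_c \in [150, 230]$
  and radius $r$ sampled log-uniformly from 8–16 px (desk scale), with a
  halo decaying as $A_h \exp(-d^2/2\sigma^2)$ beyond the core edge,
  $\sigma = 0.4\,r$. The ground-truth boundary is the set of pixels whose
  plaque contribution exceeds 10% of the core intensity. A rule-defined
  boundary is essential: the real counterpart of this ground truth is manual
  annotation, and Dice scores are only meaningful against an unambiguous
  reference.
- **Vessels**: smooth random spline tubes of constant width (5–9 px), as
  bright as plaque cores but always ground-truth negative. They force the
  learned models to use shape/context rather than brightness.
- **Field artifacts**: a multiplicative radial vignette (25% corner
  falloff), additive background fluorescence (level 40), and Gaussian noise
  (sd 4).

Cohorts add subject structure: a per-subject brightness factor
(sd 4%) and optional group effects that shift the mean log10 core radius
(exact in expectation, since the radius range is scaled by $10^{\text{shift}}$)
and the core elongation. The generator does **not** attempt photorealistic
tissue texture, 3-D structure, or staining chemistry; passing tests
demonstrate that the pipeline's machinery recovers known structure under
controlled morphology, not that it would reach the same numbers on human
tissue.

## Preprocessing

The illumination correction function (ICF) is the pixelwise mean of many
micrographs, refined by a Gaussian blur and a median filter so that only the
large-scale gradients representing vignetting survive. Kernel sizes default
to sigma 13 px / window 15 px at the 512-px desk scale (equivalently ~50 px
at full 1920-px scale); the sources for this method state the intent
("preserve only large gradients") rather than exact kernels, so the sizes
are package defaults, configurable. Correction divides by the ICF and
rescales by *the ICF's* spatial mean — the alternative reading (each image's
own mean) would make corrected intensities incomparable across images, which
is why the ICF mean is the default.

Background selection uses the Silver Mountain Operator: per-pixel unit
gradient vectors (central differences inside, one-sided at borders; zero
gradients contribute zero vectors) are box-averaged over a 7-px window and
the norm of the average taken. On structured signal neighboring gradients
align and the norm stays near 1; in spatially uncorrelated background the
mean of $k^2$ iid unit vectors concentrates near $1/k$. Pixels below the 5th
SMO percentile (excluding saturated ≥ 255 and empty ≤ 5 pixels) are declared
background and their median is subtracted from the whole image.

## The classifier and its CAMs

The patch classifier is a small fully convolutional network of fire modules
(1×1 squeeze, parallel 1×1/3×3 expands) with identity skip connections
around every second module, late downsampling, and a TAP head: each final
feature map is summarized by the mean of its activations above a threshold
$\tau$, and a dense sigmoid layer maps the pooled vector to the probability
that the patch contains parenchymal pathology. TAP interpolates between
global average pooling ($\tau = -\infty$) and global max pooling ($\tau$
just below the peak). The $\tau$ value used by the method's originators is
not stated for this adaptation; the package default is $\tau = 0$, i.e. the
average over positive activations, which preserves activation spread
without diluting by inactive area. CAMs are
$\sum_k \max(w_k, 0)\,F_k$ — clamping negative head weights suppresses
background-evidence channels — bilinearly upsampled to patch resolution and
normalized by the per-image maximum (an identically zero map stays zero).

Training uses RMSprop on binary cross-entropy with geometric augmentation
and within-batch mixup (Beta(8, 8) coefficients for same-class pairs,
Beta(0.2, 0.2) across classes; the sharp intra-class shape makes soft labels
near 0.5 only for pairs that genuinely share a class). The checkpoint with
the lowest development loss (10% of training patches) is retained. The full
printed recipe (800 epochs at learning rate 5e-6, batch 64, 572-px inputs)
is configuration; the desk profile uses 128-px patches and 48 epochs at
1.5e-3 (halved at 60% and 85% of training — small-batch RMSprop is unstable
late in training without decay), batch 16, on a balanced subsample of 280
patches, sizes chosen so one cross-validation fold's classifier trains in
under five minutes on one CPU with the development loss plateaued.

## Banks, composites and the segmenter

CAM > 0.5 components (≥ 20 px) become object instances with a 12–16 px
context margin. Harvested objects are additionally screened by their
*margin contrast* — the relative intensity drop from the object interior
to a thin ring just outside its mask. Parenchymal deposits have a diffuse
halo, so a CAM-derived core mask shows a clear positive margin; a bright
structure that continues undimmed beyond its mask is a vascular segment
mistaken for a deposit, and objects with margin contrast below 0.3 are
dropped. This screen is the bank-level form of the morphology-based
exclusion of vascular amyloid that is standard in ThioS quantification,
and it measurably purifies the pseudo-labels (in the synthetic cohorts it
removes the large majority of vessel-derived CAM components while keeping
~75% of deposit components). CAM > 0.2 regions dilated by a disc become
removal zones,
and the holes are filled by offset-based inpainting: candidate shifts are
scored by agreement on the known ring around the hole and the best shift
copies texture in (with an iterative ring-fill fallback). The inpainting
contract is texture coherence — the inpainted interior must match the
surrounding annulus mean within 10% — rather than a specific algorithm.
The buffer dilation radius is 25 px at full scale and scales with
resolution (6 px desk).

Composites paste 0–5 objects into background crops. Object contours are
polygon-approximated at 5-px arc-length gaps (keypoints are pushed outward
half a pixel so the zero-noise polygon conserves the digital mask area),
then each keypoint is displaced along the local normal — perpendicular to
the chord joining its neighbors, which preserves simple outlines — by
zero-mean Gaussian noise with $\sigma = 0.4 \times$ gap. The linear link
between gap and noise magnitude is a package decision; the method statement
only requires that the gap drive the noise scale. Soft copy-paste erodes
and dilates the pasted mask 5 times with a 3×3 cross: the eroded core is
pasted verbatim, the ring is blended with weights that decay with signed
distance from the mask boundary, and the ring is *ignored* during training
(trimap), never used as a soft target. The supervised foreground is the
perturbed mask minus the ignore ring, which keeps the trimap partition
disjoint.

The segmenter is a symmetric encoder–decoder with two unpadded 3×3
convolutions per level, 2×2 max pooling, transposed-convolution upsampling
and cropped skip concatenation; 572-px tiles map to 388-px outputs at depth
4, and the desk profile uses 108 → 68 at depth 2. It is trained with Adam
(0.001, 0.9/0.999, 1e-7) on the asymmetric unified focal loss

$$\mathcal{L}_{aUF} = \lambda \mathcal{L}_{maF} + (1-\lambda)\mathcal{L}_{maFT},
\qquad \lambda = 0.5,\ \delta = 0.6,\ \gamma = 0.5,$$

whose focal term keeps full (unsuppressed) cross-entropy on the rare
foreground class and down-weights easy background pixels by $(1-p_t)^\gamma$,
and whose Tversky term weights false negatives by $\delta$ and false
positives by $1-\delta$, applying the focal exponent $1-\gamma$ only to the
foreground index. Printed typography of the loss is ambiguous about the
placement of the rare-class index; the implementation follows the cited
asymmetric-unified-focal construction (true-class probability in each
pixel's log term; foreground carries the focal Tversky exponent), and the
oracle tests pin the exact formula term by term. Ignored pixels are excluded
from every sum and from $N$. The final-epoch snapshot is kept regardless of
development loss — the development stream exists for monitoring only.

Full-image inference mirrors the image at its borders by the network margin,
pads right/bottom to a whole number of output tiles, and stitches
predictions so every pixel is predicted exactly once. Postprocessing:
threshold 0.5, per-component hole filling, size exclusion (< 3500 px at full
resolution, scaled by the squared resolution factor to 249 px at desk
scale), and exclusion of border-touching components from the instance set.
Size exclusion runs before border exclusion; the two commute except for
small border objects, which both rules remove.

A final morphology-based vascular exclusion (`exclude_vascular`) follows:
for each predicted component, the image is thresholded at half the
component's mean intensity in a local window, and the connected bright
region containing the component is traced. A deposit's halo decays into
background, so its bright region barely exceeds the component (a couple of
pixels); a predicted blob sitting on a vessel bend, junction or parallel
pair belongs to a bright tube that continues tens of pixels further. The
default tolerance (12 px at desk scale) sits an order of magnitude away
from both clusters. Vessel bends and junctions are locally
indistinguishable from compact deposits at the segmenter's receptive
field, and too rare in a small cohort's patch set for the networks to
learn; this rule supplies exactly the semantic the weak labels
under-determine, using the same criterion a histologist applies when
excluding vascular amyloid by morphology.

## Morphometry

Within each predicted deposit, intensity percentiles delineate subregions:
pixels ≥ the 80th percentile form the compact core, ≥ the 50th percentile
the deposit proper (linear-interpolation percentiles, inclusive
thresholds). Measuring "deposit area" on the 50th-percentile binarization
(not the raw predicted mask) is required for the diffuseness index
$(A_{dep} - A_{comp})/A_{dep}$ to be a proper fraction; the raw mask area is
also exported. The 19 parameters:

- *size* (log10): deposit area, compact area, perimeter, hull area, hull
  perimeter, bounding-circle diameter, maximum span, mean hull radius;
- *complexity*: fractal dimension, lacunarity, roughness (perimeter / hull
  perimeter), circularity $4\pi A/P^2$, solidity;
- *geometry*: span ratio (major/minor principal axis of the hull),
  max/min centroid-to-vertex radius, hull circularity;
- *intensity*: mean gray, integrated density (area × mean gray, log10),
  diffuseness.

Perimeter uses the 8-connected boundary chain with corner-corrected step
weights (0.948 straight, 1.340 diagonal). Raw $\sqrt 2$ weighting
overestimates smooth outlines by ~5%, which would push a disc's
circularity to ~0.91; the corrected weights give 1.01 on a radius-50 disc
and are what reference measurement tools effectively report. The minimum
enclosing circle is exact (Welzl's algorithm on hull vertices).

Box counting scans the mask's bounding box with box sizes in powers of 2
from 2 px up to 45% of the larger side, on 12 randomized grid placements.
Placements are *cyclic*: the grid is shifted with wrap-around at the
bounding box, so every foreground pixel falls in exactly one box at every
size. This choice eliminates the partial-edge-box bias that otherwise
depresses the slope of compact shapes (a filled square measures 2.00
exactly under cyclic placement versus ~1.88 with clipped offset grids); on
the depth-6 Sierpinski carpet it yields 1.88 against the theoretical
$\log 8/\log 3 = 1.893$. The fractal dimension is the negative slope of
log occupied-box count against log box size; lacunarity is the squared
coefficient of variation (population form) of per-box foreground masses
over occupied boxes, averaged over sizes and placements. When a parameter
column contains zeros (typically compact area), 1 is added uniformly to
that column before the log transform.

## Evaluation protocol and statistics

All training honors patient-wise group k-fold: one fold per subject, each
subject the test case exactly once, CAMs and banks derived from a subject
used only in that subject's training folds. Violations are machine-checked
errors at the classifier, bank and segmenter stages, not warnings.

PCA z-scores the 19 parameters and decomposes the correlation structure;
component signs are fixed by making each loading column's largest-magnitude
entry positive, since the sign of an eigenvector is otherwise arbitrary and
irreproducible. Group comparison is one-way ANOVA over the four
region-by-dementia cells followed by Tukey HSD (the Tukey–Kramer form, since
deposit counts per group are unequal). Deposits are treated as independent
observations, mirroring the deposit-level analysis this package reproduces;
this ignores within-subject correlation (pseudo-replication), which is a
known caveat of the design, documented rather than "fixed" — a mixed model
is out of scope.

## Problem sizes and numerical choices

The test suite and acceptance script run a "desk" profile chosen once:
512² scenes, cohorts of 6 subjects × 4 scenes, 128-px patches
(~16 per scene, balanced subsample of 280 for training), a 108 → 68
segmenter trained for 24 epochs × 8 batches of 16 streamed composites, and
two of the six cross-validation folds evaluated end to end. On one CPU the
end-to-end run takes roughly twenty minutes and reaches Dice ≈ 0.9 against
synthetic ground truth with no vessel pixels misclassified after vascular
exclusion; the acceptance gate is Dice ≥ 0.6 and vessel FP < 2%.

Other numerical conventions: probabilities are clipped at 1e-7 inside the
loss; TAP returns 0 when nothing exceeds the threshold; metric ratios with
zero denominators are reported as NA, never as silent zeros; contour
perturbation retries on self-intersection (bounded) and errors if
unresolvable; scene composition places fewer objects when core-overlap-free
placement fails after bounded retries, recording the placements actually
made. All randomness flows through explicit seeds; identical spec + seed
reproduces scenes, training runs and composites bit for bit.

## Known limitations

- Synthetic plaques are smooth blobs with Gaussian halos; real deposits
  have filamentous substructure that the generator does not emulate, so the
  morphometric *values* (e.g. fractal dimension near 1.9 for near-solid
  blobs) are not those of real pathology — only the measurement machinery
  is validated.
- The desk-scale networks are small; the full-scale profiles (572-px
  inputs, 800-epoch classifier schedule) are provided as configuration but
  are not exercised by the tests.
- The inpainting is offset-based texture copying, adequate for the
  low-texture backgrounds generated here; highly structured backgrounds
  would need a stronger hole filler (still within the same contract).
- Group comparisons treat deposits as independent; with few subjects the
  ANOVA is exploratory, exactly as in the study design this mirrors.
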