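---
title: "glioscan: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{glioscan: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioscan)
```

## Overview

glioscan implements a classical texture-based pipeline for detecting and
classifying tumor-like regions in 2D brain MR images: denoising, seeded
region growing with morphological cleanup, multilevel wavelet
decomposition, gray-level co-occurrence (GLCM) texture features, and a
probabilistic neural network (PNN) classifier. This vignette documents
the model assumptions, every tunable parameter with its default and
rationale, the numerical edge cases, and what the synthetic phantoms do
and do not demonstrate.

## Preprocessing and fidelity metrics

Input images are converted to 8-bit grayscale on load. Color inputs are
reduced with the standard luminance weights (0.299, 0.587, 0.114);
sources deeper than 8 bits are min–max rescaled to [0, 255] (a constant
image maps to zero). Working at a uniform bit depth m = 8 keeps the GLCM
quantization and the peak term 2^m − 1 of the PSNR consistent across
sources. DICOM support covers single-frame, uncompressed little-endian
files; multi-frame inputs are rejected explicitly rather than silently
taking the first frame.

Denoising is a square median filter (default window 3) with edge
replication. The median is the natural choice for the salt-and-pepper
component of acquisition noise: it removes impulses completely while
preserving edges, and it is idempotent on locally constant regions.
`method = "none"` bypasses the stage.

Two PSNR variants are provided because the two conventions disagree by a
factor of two in log-space:

* `as_printed` (default): 20 log10((2^m − 1) / MSE). This form divides by
  the MSE itself and can go negative at large error; it is kept as the
  default for continuity with the formulation this pipeline follows.
* `standard`: 20 log10((2^m − 1) / sqrt(MSE)), the conventional
  definition.

Identical images report `Inf` rather than a capped value. The pipeline's
quality report compares the original with the denoised image — the only
image pair the pipeline possesses.

## Seeded region growing

The region starts from one or more seed pixels. Pixels are examined in
breadth-first (FIFO) order, neighbors pushed up, left, right, down, then
diagonals, so results are deterministic even when the acceptance mean
changes during growth. A pixel joins iff |I − mu| <= delta at the moment
it is examined; each pixel is examined at most once.

* `delta` (gray levels, default 10 on the 8-bit scale): the intensity
  tolerance. It must exceed the typical intra-region variation
  (residual noise plus tissue texture after denoising) while staying
  below the tumor/background contrast.
* `mean_mode`: `"running"` (default) updates mu after every accepted
  pixel and adapts to smooth intensity drift; `"fixed"` freezes mu at
  the seed mean and is exactly reproducible by a plain flood fill, which
  is how it is verified in the tests. Both are exposed because either
  reading of "the region's mean" is defensible; the FIFO contract makes
  the running variant deterministic too.
* `connectivity`: 4 for growing (default; diagonal leakage through
  one-pixel corridors is usually unwanted), 8 for component labeling.
* Automatic seeding takes the centroid of the brightest 1% of pixels of
  the denoised image (falling back to the nearest bright pixel if the
  centroid is not itself bright). This assumes the tumor is the
  brightest coherent structure, which holds for the phantoms and for
  hyperintense lesions, but not for all MRI sequences — manual seeds
  remain available.

Cleanup applies a morphological opening (erosion then dilation, default
3x3 square structuring element), removes 8-connected components smaller
than `min_component_px` (default 25), and keeps the largest survivor.
Opening removes structures smaller than the element; the component
filter removes anything speckle-like that survives. An empty result is a
valid outcome meaning "no tumor-like region found".

## Wavelet decomposition

The 2D transform is a separable orthonormal filter bank (Haar default;
Daubechies db2 and db4 available) with dyadic downsampling; level k
decomposes level k−1's LL subband. Haar is the default because the
downstream use — texture statistics on subbands — is family-agnostic,
and Haar admits exact hand-checkable examples. Default depth is 4 with
LL and HL selected at each level (HL here meaning high-pass along the
row axis); a depth of 5 is one configuration flag away, and neither
figure is privileged — texture from the first four levels is already
near the resolution floor for 128–512 px images.

Two boundary modes are implemented, both with exact perfect
reconstruction (`idwt2(dwt2(x))` recovers x to ~1e-13 relative):

* `symmetric` (default): half-point symmetric extension, subband length
  floor((n + f − 1)/2) for filter length f. Extension makes the
  transform slightly redundant at borders, so energy is not exactly
  conserved for f > 2 (about 6% excess for db2 on 64x64 inputs).
* `periodic`: periodized circular filtering, subband length ceil(n/2).
  The transform matrix is exactly orthonormal, so squared coefficients
  sum to the squared input exactly; use this mode when energy bookkeeping
  matters.

The energy-conservation property is therefore asserted in the tests for
the periodized mode (any family) and for Haar with symmetric extension
on even sizes, where the two modes coincide.

## GLCM texture features

Wavelet coefficients are real-valued, so each selected subband is first
quantized: uniform binning of [min, max] into G levels (default G = 8; a
constant subband maps to level 0). G = 8 keeps the G x G matrix well
populated at subband sizes down to ~8x8; larger G on small subbands
produces sparse, noisy matrices. Because binning is min–max based, all
features are exactly invariant to a uniform intensity shift.

Co-occurrence matrices are built at distance S = 1 for angles 0, 45, 90,
135 degrees, symmetric by default (each ordered pair counted in both
directions — the common Haralick convention), and normalized to sum 1.
The five features are contrast, correlation, energy (with the square
root), homogeneity, and entropy in bits, computed per angle and averaged
(`aggregate = "mean"`) by default; per-angle vectors are available. Mean
aggregation is a deliberate choice: a single value per feature per
subband keeps the feature table compact and the classifier input
rotation-tolerant. A variance feature is intentionally absent: it has no
agreed single definition in this family and adds nothing over contrast.

Degenerate inputs are handled explicitly: a constant subband yields
contrast 0, energy 1, homogeneity 1, entropy 0, and an *undefined*
correlation (zero marginal variance). The correlation function returns
`NA` in that case; `feature_vector()` substitutes 0 with a warning so a
flat subband cannot poison the classifier input.

## The PNN classifier

The PNN is a Parzen-window density classifier: no iterative training,
just pattern storage. Architecture: input layer of P neurons with unit
weights, pattern layer of one Gaussian kernel exp(−d²/2σ²) per stored
example, summation layer averaging activations within each class, output
layer taking the argmax with exactly one positive decision.

Numerical and design choices:

* **Standardization.** Features are z-scored with training mean/SD
  before kernel evaluation. GLCM features span orders of magnitude
  (contrast ~1e-2 vs energy ~1), so unstandardized Euclidean kernels
  would be dominated by one dimension. Zero-variance dimensions get
  scale 1 with a warning.
* **sigma** (default 0.5 on the standardized scale): the kernel width.
  Small sigma approaches 1-nearest-neighbor behavior; large sigma
  approaches the class prior (here: the tie-break class, since classes
  are averaged). A leave-one-out grid search over logspace(−2, 1, 20) is
  available via `pnn_tune_sigma()`.
* **Per-class averaging** (1/n_c) rather than summing makes scores
  invariant to duplicating a class's patterns, so unbalanced training
  sets do not bias the decision.
* **Stability at extreme sigma.** Decisions are computed from
  log-shifted kernels, so they remain well defined when raw kernels
  underflow (sigma -> 0); reported scores are the raw activations.
  Scores within a relative 1e-9 of the maximum are treated as tied and
  resolved to the earliest declared class — this covers both exact
  geometric ties and the large-sigma regime where scores converge to
  equality up to rounding.
* Models serialize to versioned JSON (patterns, labels, sigma,
  standardization), portable across platforms.

## The phantom generator

Each phantom is an elliptical "brain" (default semi-axes 48x40 px in a
128x128 image) at mean intensity 120, filled with a smooth random
texture, optionally containing a brighter tumor ellipse (default
semi-axes 12x9 px, +80 gray levels), then degraded with additive
Gaussian noise (SD 5) and 2% salt-and-pepper impulses. The texture is
white noise blurred at a 3 px correlation length and scaled to SD 5 gray
levels; a flat background would give degenerate single-cell GLCMs, so
some texture is essential for the feature stage to be meaningfully
exercised. The texture amplitude is deliberately kept below the
region-growing tolerance (delta = 10): intra-region variation larger
than delta would make the segmentation stage systematically
under-segment regardless of contrast, violating the intended contrast
condition (tumor/background offset >= 50 gray levels, noise SD <= 5)
under which area recovery within 15% is guaranteed.

Ground truth is by construction: the mask is the exact tumor ellipse and
the label depends only on tumor presence, never on segmentation success.
Everything is deterministic given the spec's seed, and dataset
generation jitters tumor position (±6 px), semi-axes (8–14 px) and
offset (60–100 gray levels) from a master seed.

What the phantoms do **not** emulate: skull and extracranial tissue,
gray/white matter classes, CSF, bias fields, partial-volume effects,
anisotropic resolution, 3D structure, or MRI acquisition physics. A
passing phantom experiment demonstrates that the pipeline's stages
compose correctly and that its statistics behave as designed — not that
the defaults transfer to clinical data, where delta, the seeding rule
and sigma would all need re-examination.

## Problem sizes and runtime choices

The test suite and the acceptance script are sized for quick desk runs:
GLCM oracles on 50 random 16x16 images across all four angles; wavelet
round trips on 64x64 inputs at depths 1–4; region-growing oracles on
32x32 images; the end-to-end experiment on 60 training and 20 test
phantoms of 128x128 px (balanced classes), which completes in well under
a minute per run. These sizes exercise every code path, including
boundary handling, at scales where the brute-force oracles remain exact
and fast.

## Known limitations

* Single 2D frames only; no volumes, no multi-frame DICOM.
* The DICOM reader handles uncompressed little-endian single-frame
  files; compressed transfer syntaxes and sequence elements of undefined
  length are rejected.
* Region growing examines each pixel once; a pixel rejected early under
  a running mean is not revisited even if the mean later drifts toward
  it.
* The segmentation targets a single region (the largest cleaned
  component); multifocal lesions are out of scope.
* Resubstitution ("training") accuracy is reported alongside held-out
  accuracy for completeness but is optimistic by construction; model
  selection should use the held-out figure or the leave-one-out tuner.
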