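---
title: "Methods: texture-descriptor fusion for brain-MRI classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-descriptor fusion for brain-MRI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotexfusion)
```

## The problem and the model

The package implements a hybrid classification pipeline for four-class
brain-MRI slices (glioma, meningioma, pituitary, no tumor).  The premise is
that handcrafted texture statistics and learned features are complementary:
deep pooling tends to smooth away exactly the fine intensity texture that
distinguishes tumor tissue, while second-order statistics capture it
directly.  The pipeline is therefore:

1. **Preprocessing** — bilinear resize to a common side (default 128 px),
   min–max normalization to $[0,1]$, optional global histogram
   equalization, and self-guided (guided-image) filtering for
   edge-preserving denoising.
2. **Segmentation** — K-means clustering of pixel intensities
   (Lloyd's algorithm, $J=\sum_j\sum_{i\in j}(x_i-ct_j)^2$) isolates a
   region of interest (ROI); the brightest cluster is taken as the ROI
   because the targeted lesions are hyperintense.  Reconstruction fidelity
   is scored with RMSE and PSNR of the centroid-quantized image.
3. **Descriptors** — three texture descriptors on the ROI-masked frame:
   * **GLCM**: normalized co-occurrence matrices of ordered gray-level
     pairs at a fixed displacement; energy $\sum f^2$, contrast
     $\sum(u-v)^2f$, correlation
     $(\sum uv\,f-\mu_u\mu_v)/(\sigma_u\sigma_v)$ and homogeneity
     $\sum f/(1+|u-v|^2)$ per direction.
   * **LTP**: per-pixel ternary codes ($+1$ if a neighbor exceeds the
     center by at least $t$, $-1$ if it falls below by at least $t$, else
     0), split into upper/lower binary patterns and histogrammed — 512
     values, twice the dimensionality of a plain LBP histogram.
   * **CCV**: intensities quantized into 27 equal-width bins; a pixel is
     *coherent* if its 8-connected same-bin component has at least
     $\tau = \lceil 0.01\,HW \rceil$ pixels.  Interleaved
     coherent/incoherent counts give 54 values.
4. **Fusion** — descriptor blocks are concatenated in the fixed order
   GLCM → LTP → CCV, z-score standardized with training-set statistics,
   and projected onto a PCA basis fitted **on training rows only**.  This
   fit/apply separation is the leakage boundary of the whole pipeline and
   is enforced by tests that bit-compare fitted models before and after
   test-set perturbation.
5. **Classification** — a small densely-connected network: the pooled
   image feeds three dense blocks whose outputs are concatenated (each
   block sees the input and all previous block outputs); this deep-feature
   vector is concatenated with the PCA-optimized descriptor vector, passed
   through dropout and a final dense softmax over the four classes.
   Training uses Adam (learning rate 0.001), mini-batches of 64 with
   per-epoch shuffling, dropout 0.5, categorical cross-entropy, and early
   stopping with a validation patience of 5 epochs, restoring the
   best-validation weights.
6. **Evaluation** — confusion-matrix metrics (overall accuracy; per-class
   one-vs-rest precision, recall/sensitivity, specificity, accuracy, F1)
   and one-vs-rest ROC curves with trapezoidal AUC.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `target_side` | 128 | px | common input side for all stages |
| `gif_radius`, `gif_epsilon` | 4, 1e-4 | px, squared intensity | common edge-preserving defaults on $[0,1]$ data |
| `equalize` | off | — | equalization is an illustration-grade enhancement, not a mandated stage |
| `k` (K-means) | 4 | clusters | background, two tissue bands, hyperintense lesion |
| `nstart` | 4 | restarts | Lloyd is a local optimizer; a few seeded restarts are standard |
| `glcm_levels` | 32 | gray levels | standard re-quantization that avoids sparse 256×256 matrices on 128 px frames |
| `glcm_directions` | E, NE, N, NW at offset 1 | — | the four opposite directions duplicate these only under symmetrization, which is off (pairs are ordered) |
| `ltp_t` | 5 on 0–255, 0.02 on $[0,1]$ | intensity | the customary LTP band width on 8-bit data, rescaled for normalized input |
| `ccv_bins`, `tau` | 27, 1 % of pixels | bins, px | grayscale adaptation of hue-based coherence binning |
| `n_components` | 249 | components | the fusion dimensionality target; capped at the matrix rank, with a `var_retain` alternative |
| training protocol | lr 0.001, batch 64, dropout 0.5, patience 5, max 100 epochs | — | the pipeline's fixed protocol; `max_epochs` is a safety cap |

## What the phantom generator emulates — and what it does not

`generate_phantom()` produces a seeded, bit-reproducible 2-D "brain": an
ellipse of mid-gray tissue carrying band-limited texture (Gaussian-smoothed
white noise) on a dark background, plus additive pixel noise
(`noise_sigma = 0.02`).  Class-specific lesions are painted with logistic
radial profiles:

* **glioma** — large (radius 26 px at 128 px side), angularly irregular
  boundary, soft 6 px edge, strong intra-lesion heterogeneity
  (amplitude 0.30 of high-frequency texture): high GLCM contrast.
* **meningioma** — compact (12 px), sharp 0.8 px edge, nearly homogeneous,
  placed peripherally at a random angle: a large coherent bright CCV
  component with crisp LTP transitions.
* **pituitary** — small (6.5 px) bright central blob: a small coherent
  bright mass.
* **no_tumor** — no lesion; intensities inside the brain stay well below
  the lesion range.

These parameters are the package's fixed study conditions.  They make the
classes separable through exactly the statistics the descriptors measure
(lesion area, edge sharpness, heterogeneity, intensity), which is what the
end-to-end experiment exercises.  The phantoms are deliberately *not*
anatomically realistic: no gyri/sulci, no skull or CSF compartments, no
bias fields, no scanner-dependent contrast, no 3-D structure, and
class-conditional variability far below that of clinical MRI.  Passing the
phantom experiment therefore demonstrates that the pipeline's machinery is
correct and leakage-free — not that clinical accuracy would reach any
particular level.

## Numerical choices and degenerate inputs

* **Quantization** — equal-width binning maps $[0,\mathrm{peak}]$ onto
  $\{0,\dots,N-1\}$ with the top edge in the top level; PNG export rounds
  half-up after scaling by 255 so files round-trip exactly.
* **K-means** — centroid-ascending label canonicalization; empty clusters
  re-seeded to the pixel farthest from its centroid; constant images
  converge with $J=0$; the objective trace is stored and asserted
  non-increasing.  `rmse^2 \cdot N = J` is an identity of the centroid
  reconstruction and is asserted to $10^{-9}$.
* **PSNR** — identical images return `Inf` as a documented sentinel.  The
  peak defaults to 255 for integer-range data and 1.0 for $[0,1]$ data;
  reconstruction scores on normalized images are therefore on the
  1.0-peak scale.
* **Guided filter** — box means via border-normalized integral images, so
  constants are fixed points exactly; output clipped to $[0,1]$.  As
  $\varepsilon \to \infty$ the local linear model degenerates to the box
  mean of the box mean (the window coefficients are themselves averaged) —
  the relevant limit check in the tests compares against that double box
  filter.
* **GLCM** — correlation is defined as 0 when a marginal sd vanishes
  (constant image), avoiding a silent NaN.  For a diagonal co-occurrence
  matrix homogeneity equals the total mass 1, per its formula.
* **PCA** — SVD of the standardized training matrix; constant columns are
  dropped with a warning (zero-variance features carry no information and
  would divide by zero); component signs pinned so each component's
  largest-magnitude loading is positive; requested components are capped
  at the numerical rank.
* **Metrics** — 0/0 rates are reported as 0 with an `undefined` flag;
  AUC for a class absent from the truth is `NA`, never 0.
* **Ties** — argmax prediction ties break toward the lowest class index in
  the fixed order (glioma, meningioma, pituitary, no_tumor); equal ROC
  scores are grouped into a single operating point.

## Design decisions where the design was open

* **Stage order** is fixed as resize → min–max normalize → (equalize) →
  guided filter; equalization defaults to off.
* **ROI semantics**: descriptors are computed on the ROI-masked full frame
  by default, which keeps descriptor dimensionality constant across
  images; bounding-box cropping and no-ROI modes are available
  (`apply_roi`).
* **Per-class split counts** use round-half-up of
  $0.8\,n_{\text{class}}$ — the only rounding rule consistent with the
  published per-class train counts (e.g. 1297 from 1621 and 1406
  from 1757).
* **Ten-fold cross-validation** (`crossvalidate()`) operates inside the
  training 80 % only, refitting the fusion model per fold; the 20 % test
  set is evaluated exactly once.  This reconciles an 80/20 hold-out with a
  10-fold protocol.
* **Classifier backend**: the package ships its own dense-block network
  and Adam trainer as plain matrix code.  The network is intentionally
  small (three dense blocks, growth 16 on a 16×16 pooled image) so the
  full experiment trains on one CPU core in seconds; the
  `densenet121_pretrained` backbone mode is declared in the configuration
  surface but errors cleanly because no pretrained convolutional weights
  are bundled.
* **A published fidelity pair is inconsistent**: a PSNR of 38.39 dB with
  an RMSE of 0.23436 cannot both hold under any single intensity scale
  ($20\log_{10}(1/0.23436)\approx 12.6$ dB;
  $20\log_{10}(255/0.23436)\approx 60.7$ dB).  The package implements the
  standard formulas and documents the discrepancy instead of
  reverse-engineering a scale that reproduces both numbers.

## Problem sizes

The end-to-end experiment in the test suite and the acceptance script uses
100 phantoms per class at 128×128 (320 training / 80 test images after the
80/20 split), PCA capped at 249 components, and the default training
protocol.  Unit tests use smaller sides (32–64 px) and the descriptor
oracle suites run on random images up to 16×16, where brute-force
enumeration is exact and fast.

## Known limitations

* Phantoms are 2-D and statistically simple; results on them bound nothing
  about clinical MRI (see above).
* JPEG input is not supported (no JPEG reader among the package's
  dependencies); PNG is the native format, TIFF optional.
* The image branch is a dense network on a pooled image, not a
  convolutional DenseNet-121; the pretrained mode is a declared but
  unavailable backend.
* Group-aware splitting handles subject-level integrity but makes no
  attempt at optimal group packing; when exact per-class counts are
  unattainable it warns and returns the nearest feasible split.
* K-means segmentation assumes hyperintense lesions; hypointense lesions
  would require a different ROI rule (`roi_largest_component` and the
  cluster labels are exposed for that purpose).
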