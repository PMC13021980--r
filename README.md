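# neurotexfusion

Texture-descriptor fusion for four-class brain-MRI tumor classification
(glioma, meningioma, pituitary, no tumor) on 2-D grayscale slices, built
for people who need the full pipeline — segmentation, handcrafted texture
features, leakage-safe dimensionality reduction, classifier, metrics — as
tested, reproducible R functions rather than a notebook.

The pipeline:

* **Preprocessing** — bilinear resize (default 128×128), min–max
  normalization, optional histogram equalization, self-guided
  (guided-image) filtering.
* **Segmentation** — K-means on pixel intensities minimizing
  $J=\sum_j\sum_{i\in j}(x_i-ct_j)^2$, ROI = brightest cluster, fidelity
  scored by PSNR/RMSE of the centroid reconstruction.
* **Descriptors** — GLCM statistics (energy $\sum f^2$, contrast
  $\sum(u-v)^2f$, correlation, homogeneity $\sum f/(1+|u-v|^2)$ over 4
  directions), local ternary patterns (upper/lower 256-bin histograms,
  512 values), and a grayscale color coherence vector (27 intensity bins,
  coherent = 8-connected component ≥ 1 % of pixels, 54 values).
* **Fusion** — z-score standardization + PCA (default 249 components)
  fitted on **training rows only**; the fitted model is provably untouched
  by test data (bit-compared in the tests).
* **Classifier** — a small densely-connected network combining a pooled
  image branch with the PCA-optimized feature vector, trained with Adam
  (lr 0.001), batch 64, dropout 0.5, categorical cross-entropy and early
  stopping (patience 5).
* **Evaluation** — confusion matrix, per-class one-vs-rest metrics, macro
  averages, ROC/AUC; `tidy()`, `glance()` and `autoplot()` methods on
  every result object.

A seeded phantom generator produces four-class synthetic brain-like images
with class-distinct texture statistics, so everything above runs and is
testable with no external data.

## Worked example

```r
library(neurotexfusion)

# one phantom through the front half of the pipeline
img <- generate_phantom("glioma", image_side = 128, seed = 42)
pre <- preprocess_image(img)
seg <- kmeans_segment(pre, k = 4, seed = 1)
seg
#> K-means segmentation: k = 4, 44 iterations, J = 33.7693
#> centroids: 0.03181, 0.4133, 0.5939, 0.8622
#> ROI: 818 px (5.0%)
```

The four centroids are the dark background, two tissue bands and the
hyperintense lesion; the ROI (5 % of the frame) is the lesion cluster.
Reconstruction fidelity of the segmentation and the GLCM statistics of the
ROI-masked frame:

```r
segmentation_fidelity(pre, seg)
#> # A tibble: 1 × 4
#>    psnr   rmse objective     k
#>   <dbl>  <dbl>     <dbl> <dbl>
#> 1  26.9 0.0454      33.8     4

round(glcm_descriptor(pre * seg$roi_mask, peak = 1)[1:4], 4)
#>      glcm_energy_a0    glcm_contrast_a0 glcm_correlation_a0 glcm_homogeneity_a0
#>              0.8751             18.4564              0.7385              0.9518
```

A full desk-scale experiment — generate phantoms, extract descriptors,
split 80/20, fuse with PCA, train, evaluate — comparing a single
descriptor against the tri-fusion:

```r
res <- run_pipeline(n_per_class = 25, image_side = 64, seed = 1,
                    combos = list("glcm", c("glcm", "ltp", "ccv")),
                    n_components = 40,
                    cfg = train_config(max_epochs = 40, batch_size = 32))
res
#> Pipeline run (seed 1): 100 images, combos: glcm; glcm+ltp+ccv
#>   glcm           accuracy 0.6000  macro F1 0.5595
#>   glcm+ltp+ccv   accuracy 0.8500  macro F1 0.8453
```

Held-out accuracy is measured on the 20 test images the fusion model and
classifier never saw; fusing all three descriptors lifts accuracy from
0.60 to 0.85 here, the qualitative ordering the pipeline is built around
(at the full study scale of 100 phantoms per class at 128×128 the
tri-fusion separates the classes completely).  `tidy(res)` returns the
per-class metric table, `autoplot(res$reports[[1]])` the ROC curves, and
`autoplot(res$classifiers[[1]])` the training curves.

A thin CLI over the same functions ships in `inst/cli/neurotexfusion`
(subcommands `generate`, `extract`, `pipeline`, `evaluate`, `report`).

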