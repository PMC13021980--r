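#' Extract descriptor features for a manifest of images
#'
#' Runs the per-image pipeline — preprocess, K-means ROI segmentation,
#' descriptor computation — over a manifest and returns one tidy row per
#' image: `path`, `label`, then the named descriptor columns (16 GLCM + 512
#' LTP + 54 CCV = 582 with the defaults).
#'
#' Descriptors are computed on the ROI-masked full frame by default (pixels
#' outside the ROI set to 0, so descriptor dimensionality is constant across
#' images); `apply_roi = "none"` uses the whole preprocessed image and
#' `"crop"` the ROI bounding box.
#'
#' @param manifest tibble with columns `path` and `label`; images are read
#'   from `path` unless an `image` list-column is present (as produced by
#'   [generate_dataset()] with `out_dir = NULL`).
#' @param descriptors subset of `c("glcm", "ltp", "ccv")`.
#' @param target_side preprocessing side in pixels.
#' @param equalize,gif_radius,gif_epsilon see [preprocess_image()].
#' @param k,seed K-means segmentation parameters; the per-image seed is
#'   derived from `seed` and the row index.
#' @param apply_roi `"mask"` (default), `"crop"`, or `"none"`.
#' @param glcm_levels,glcm_directions,glcm_offset GLCM parameters.
#' @param ltp_t LTP threshold on the \code{[0,1]} scale.
#' @param ccv_bins CCV bin count.
#' @return tibble: `path`, `label`, one column per descriptor value.
#' @examples
#' \donttest{
#' manifest <- generate_dataset(2, image_side = 64, seed = 1)
#' feats <- extract_features(manifest, descriptors = "glcm", target_side = 64)
#' dim(feats)
#' }
#' @export
extract_features <- function(manifest,
                             descriptors = c("glcm", "ltp", "ccv"),
                             target_side = 128, equalize = FALSE,
                             gif_radius = 4, gif_epsilon = 1e-4,
                             k = 4, seed = 1,
                             apply_roi = c("mask", "crop", "none"),
                             glcm_levels = 32, glcm_directions = 1:4,
                             glcm_offset = 1, ltp_t = 0.02, ccv_bins = 27) {
  if (!all(c("path", "label") %in% names(manifest)))
    abort("`manifest` needs `path` and `label` columns.")
  descriptors <- match.arg(descriptors, c("glcm", "ltp", "ccv"),
                           several.ok = TRUE)
  apply_roi <- match.arg(apply_roi)
  has_mem <- "image" %in% names(manifest)

  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    img <- if (has_mem) manifest$image[[i]] else read_gray(manifest$path[i])
    pre <- preprocess_image(img, target_side, equalize, gif_radius, gif_epsilon)
    seg <- kmeans_segment(pre, k = k, seed = derive_seed(seed, i))
    work <- switch(apply_roi,
      none = pre,
      mask = pre * seg$roi_mask,
      crop = {
        idx <- which(seg$roi_mask, arr.ind = TRUE)
        pre[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]),
            drop = FALSE]
      })
    out <- list()
    if ("glcm" %in% descriptors)
      out$glcm <- glcm_descriptor(work, n_levels = glcm_levels,
                                  directions = glcm_directions,
                                  offset = glcm_offset, peak = 1)
    if ("ltp" %in% descriptors)
      out$ltp <- ltp_encode(work, t = ltp_t)$vector
    if ("ccv" %in% descriptors)
      out$ccv <- ccv_compute(work, n_bins = ccv_bins, peak = 1)$vector
    tibble::as_tibble_row(c(list(path = manifest$path[i],
                                 label = manifest$label[i]),
                            as.list(unlist(unname(out)))))
  })
  dplyr::bind_rows(rows)
}

#' Pooled image matrix for the classifier's image branch
#'
#' Average-pools each preprocessed image down to `pool_side` x `pool_side`
#' and flattens it row-wise, producing the dense input consumed by the image
#' branch of [build_classifier()].
#'
#' @inheritParams extract_features
#' @param pool_side side of the pooled image (must divide `target_side`).
#' @return numeric matrix, one row per image, `pool_side^2` columns.
#' @export
pool_images <- function(manifest, target_side = 128, pool_side = 16,
                        equalize = FALSE, gif_radius = 4, gif_epsilon = 1e-4) {
  if (target_side %% pool_side != 0)
    abort("`pool_side` must divide `target_side`.")
  f <- target_side / pool_side
  has_mem <- "image" %in% names(manifest)
  t(vapply(seq_len(nrow(manifest)), function(i) {
    img <- if (has_mem) manifest$image[[i]] else read_gray(manifest$path[i])
    pre <- preprocess_image(img, target_side, equalize, gif_radius, gif_epsilon)
    blk <- matrix(0, pool_side, pool_side)
    for (r in seq_len(pool_side)) for (cc in seq_len(pool_side))
      blk[r, cc] <- mean(pre[((r - 1) * f + 1):(r * f),
                             ((cc - 1) * f + 1):(cc * f)])
    as.numeric(t(blk))
  }, numeric(pool_side^2)))
}
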