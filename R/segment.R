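#' K-means intensity segmentation
#'
#' Lloyd's algorithm on the 1-D pixel-intensity values, minimizing the
#' within-cluster sum of squares \eqn{J = \sum_j \sum_{i \in j} (x_i - ct_j)^2}.
#' Iterations stop when the largest centroid shift falls below `tol` or after
#' `max_iter` sweeps; the per-iteration objective trace is stored and is
#' non-increasing.  Labels are canonicalized so centroid intensity strictly
#' ascends with cluster index.  An emptied cluster is re-seeded to the pixel
#' farthest from its current centroid.  The region of interest is the
#' brightest cluster, optionally restricted to its largest 8-connected
#' component.
#'
#' @param img numeric matrix (preprocessed image).
#' @param k number of clusters (>= 2).
#' @param max_iter maximum Lloyd sweeps.
#' @param tol convergence threshold on the maximum centroid shift.
#' @param seed integer seed for the initialization.
#' @param nstart number of seeded restarts; the run with the lowest final
#'   objective is kept (Lloyd converges to a local optimum, so a few
#'   restarts are standard practice).
#' @param init `"kmeanspp"` (distance-weighted seeding) or `"random"`.
#' @param roi_largest_component keep only the largest 8-connected component
#'   of the brightest cluster as the ROI mask?
#' @return an object of class `"segmentation_result"`: a list with `labels`
#'   (integer matrix, 1-based cluster per pixel), `centroids` (ascending
#'   intensities), `roi_mask` (logical matrix), `objective` (final J),
#'   `objective_trace`, `iterations`, and `sizes`.
#' @examples
#' img <- generate_phantom("meningioma", 64, seed = 2)
#' seg <- kmeans_segment(img, k = 4, seed = 1)
#' seg$centroids
#' @export
kmeans_segment <- function(img, k = 4, max_iter = 100, tol = 1e-6, seed = 1,
                           nstart = 4, init = c("kmeanspp", "random"),
                           roi_largest_component = FALSE) {
  stopifnot_gray(img)
  if (k < 2) abort("`k` must be at least 2.")
  init <- match.arg(init)
  best <- NULL
  for (r in seq_len(max(1L, nstart))) {
    run <- kmeans_once(img, k, max_iter, tol, derive_seed(seed, 23, r), init)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  lab <- best$lab; centers <- best$centers
  labels <- matrix(lab, nrow = nrow(img))
  roi <- labels == k
  if (roi_largest_component && any(roi)) {
    comp <- label_components(roi)
    sizes <- tabulate(comp[roi])
    roi <- comp == which.max(sizes)
  }
  structure(list(
    labels = labels, centroids = centers, roi_mask = roi,
    objective = best$objective, objective_trace = best$trace,
    iterations = length(best$trace), sizes = tabulate(lab, nbins = k), k = k
  ), class = "segmentation_result")
}

# One seeded Lloyd run on the flattened intensities.
kmeans_once <- function(img, k, max_iter, tol, seed, init) {
  x <- as.numeric(img)
  n <- length(x)
  ux <- unique(x)
  if (length(ux) < k) {
    # degenerate: fewer distinct intensities than clusters; pad with
    # duplicate centers so every distinct value gets its own cluster
    centers <- sort(c(ux, rep(ux[1], k - length(ux))))
  } else {
    centers <- with_local_seed(seed, {
      if (init == "random") sort(sample(ux, k))
      else { # kmeans++-like seeding on the distinct intensities
        cs <- numeric(k)
        cs[1] <- ux[sample.int(length(ux), 1)]
        for (j in 2:k) {
          d2 <- vapply(ux, function(v) min((v - cs[1:(j - 1)])^2), numeric(1))
          cs[j] <- if (sum(d2) == 0) ux[sample.int(length(ux), 1)]
                   else ux[sample.int(length(ux), 1, prob = d2)]
        }
        sort(cs)
      }
    })
  }

  assign_labels <- function(centers) {
    d <- outer(x, centers, function(a, b) (a - b)^2)
    max.col(-d, ties.method = "first")
  }
  trace <- numeric(0)
  lab <- assign_labels(centers)
  for (it in seq_len(max_iter)) {
    # empty-cluster repair: re-seed to the pixel farthest from its centroid
    for (j in seq_len(k)) {
      if (!any(lab == j)) {
        far <- which.max((x - centers[lab])^2)
        centers[j] <- x[far]
        lab[far] <- j
      }
    }
    new_centers <- vapply(seq_len(k), function(j) mean(x[lab == j]), numeric(1))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    lab <- assign_labels(centers)
    trace <- c(trace, sum((x - centers[lab])^2))
    if (shift < tol) break
  }

  # canonical order: centroid intensity ascends with cluster index
  ord <- order(centers)
  centers <- centers[ord]
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  lab <- relabel[lab]
  list(lab = lab, centers = centers, trace = trace,
       objective = sum((x - centers[lab])^2))
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("K-means segmentation: k = %d, %d iterations, J = %.6g\n",
              x$k, x$iterations, x$objective))
  cat("centroids:", paste(signif(x$centroids, 4), collapse = ", "), "\n")
  cat(sprintf("ROI: %d px (%.1f%%)\n", sum(x$roi_mask),
              100 * mean(x$roi_mask)))
  invisible(x)
}

#' @export
tidy.segmentation_result <- function(x, ...) {
  tibble(cluster = seq_along(x$centroids),
         centroid = x$centroids,
         size = x$sizes,
         is_roi = seq_along(x$centroids) == x$k)
}

#' Peak signal-to-noise ratio
#'
#' \eqn{20 \log_{10}(peak / rmse)} between two same-shaped images.  Identical
#' images have zero RMSE; by convention the function then returns `Inf`
#' (documented sentinel for "no distortion").
#'
#' @param reference,approx numeric matrices of identical shape.
#' @param peak peak intensity; defaults to 255 for integer-range data and 1
#'   for \code{[0,1]} data.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(reference, approx, peak = gray_peak(reference)) {
  if (!all(dim(reference) == dim(approx)))
    abort("`reference` and `approx` must have the same shape.")
  r <- rmse(reference, approx)
  if (r == 0) return(Inf)
  20 * log10(peak / r)
}

#' @rdname psnr
#' @export
rmse <- function(reference, approx) {
  if (!all(dim(reference) == dim(approx)))
    abort("`reference` and `approx` must have the same shape.")
  sqrt(mean((reference - approx)^2))
}

#' Segmentation fidelity scores
#'
#' Reconstructs the image by replacing every pixel with its assigned cluster
#' centroid and scores the reconstruction against the original with RMSE and
#' PSNR.  `rmse^2 * n_pixels` equals the K-means objective J by construction.
#'
#' @param img the segmented image.
#' @param seg a [kmeans_segment()] result for `img`.
#' @param peak PSNR peak, defaulting per the image's value range.
#' @return tibble with columns `psnr`, `rmse`, `objective`, `k`.
#' @export
segmentation_fidelity <- function(img, seg, peak = gray_peak(img)) {
  stopifnot_gray(img)
  recon <- matrix(seg$centroids[seg$labels], nrow = nrow(img))
  r <- rmse(img, recon)
  tibble(psnr = psnr(img, recon, peak), rmse = r,
         objective = seg$objective, k = seg$k)
}

# 8-connected component labeling of a logical mask: 0 outside the mask,
# component id inside (ids shared with the background components are
# harmless — callers only compare ids of in-mask pixels).
label_components <- function(mask, connectivity = 8) {
  comp <- same_value_components(matrix(as.integer(mask), nrow(mask)),
                                connectivity)
  comp[!mask] <- 0L
  comp
}
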