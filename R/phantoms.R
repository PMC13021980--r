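#' @rdname generate_phantom
#' @export
phantom_classes <- c("glioma", "meningioma", "pituitary", "no_tumor")

#' Per-class lesion geometry defaults
#'
#' Geometry and texture parameters of the synthetic lesion painted by
#' [generate_phantom()], on a 128-px reference side (radii scale linearly with
#' `image_side`).  Fields: `radius` and `softness` (logistic edge width) in
#' pixels, `amplitude` (lesion brightness added above tissue, \code{[0,1]}
#' scale), `heterogeneity` (amplitude of the high-frequency intra-lesion
#' texture), `center` (normalized x/y offset from image center; `NA` means a
#' random peripheral placement), `jitter` (uniform center jitter in pixels)
#' and `irregular` (angularly modulated boundary).
#'
#' @param class_label one of `phantom_classes`.
#' @return named list of lesion parameters (empty for `"no_tumor"`).
#' @export
phantom_blob_params <- function(class_label) {
  switch(match.arg(class_label, phantom_classes),
    glioma = list(radius = 26, softness = 6, amplitude = 0.30,
                  heterogeneity = 0.30, center = c(0.25, 0.12),
                  jitter = 8, irregular = TRUE),
    meningioma = list(radius = 12, softness = 0.8, amplitude = 0.45,
                      heterogeneity = 0.04, center = c(NA, NA),
                      jitter = 6, irregular = FALSE),
    pituitary = list(radius = 6.5, softness = 2, amplitude = 0.50,
                     heterogeneity = 0.04, center = c(0, 0.10),
                     jitter = 3, irregular = FALSE),
    no_tumor = list()
  )
}

#' Generate a synthetic brain-like phantom image
#'
#' Produces a seeded, deterministic 2-D grayscale phantom: an elliptical
#' "brain" of mid-gray tissue with band-limited texture on a dark background,
#' plus a class-specific lesion.  The four classes are texture-separable by
#' construction: glioma phantoms carry a large, irregular, strongly
#' heterogeneous bright region; meningioma a compact sharp-edged peripheral
#' mass; pituitary a small central bright blob; no-tumor phantoms have no
#' lesion.  The same `(class_label, image_side, seed, noise_sigma,
#' blob_params)` always yields a bit-identical image.
#'
#' @param class_label one of `"glioma"`, `"meningioma"`, `"pituitary"`,
#'   `"no_tumor"`.
#' @param image_side side of the square image in pixels (at least 32).
#' @param seed integer seed; fully determines the image.
#' @param noise_sigma sd of the additive pixel noise on the \code{[0,1]} scale.
#' @param blob_params lesion geometry, see [phantom_blob_params()]; defaults
#'   to the class's parameters.
#' @return numeric `image_side` x `image_side` matrix with values in
#'   \code{[0,1]}.
#' @examples
#' img <- generate_phantom("glioma", seed = 1)
#' range(img)
#' @export
generate_phantom <- function(class_label, image_side = 128, seed = 1,
                             noise_sigma = 0.02,
                             blob_params = phantom_blob_params(class_label)) {
  if (!is.character(class_label) || length(class_label) != 1 ||
      !class_label %in% phantom_classes)
    abort(sprintf("unknown class_label %s; must be one of: %s",
                  deparse(class_label), paste(phantom_classes, collapse = ", ")))
  if (image_side < 32) abort("`image_side` must be at least 32 pixels.")
  s <- as.integer(image_side)
  px_scale <- s / 128

  with_local_seed(seed, {
    # normalized coordinates in [-1, 1], x along columns, y along rows
    yc <- (matrix(seq_len(s), s, s) - (s + 1) / 2) / (s / 2)
    xc <- t(yc)
    brain <- (xc / 0.80)^2 + (yc / 0.92)^2 <= 1

    tissue_tex <- standardize_field(
      smooth_field(matrix(rnorm(s * s), s, s), sigma = 3 * px_scale))
    img <- 0.03 + brain * (0.38 + 0.04 * tissue_tex)

    if (class_label != "no_tumor") {
      p <- blob_params
      if (anyNA(p$center)) { # peripheral placement at a random angle
        th <- runif(1, 0, 2 * pi)
        p$center <- c(0.55 * cos(th) * 0.80, 0.55 * sin(th) * 0.92)
      }
      jit <- runif(2, -p$jitter, p$jitter) / (s / 2)
      cx <- p$center[1] + jit[1]
      cy <- p$center[2] + jit[2]
      dx <- (xc - cx) * (s / 2)
      dy <- (yc - cy) * (s / 2)
      r <- sqrt(dx^2 + dy^2)
      radius <- p$radius * px_scale
      if (isTRUE(p$irregular)) {
        th <- atan2(dy, dx)
        ph <- runif(2, 0, 2 * pi)
        radius <- radius * (1 + 0.18 * sin(3 * th + ph[1]) +
                                0.12 * sin(5 * th + ph[2]))
      }
      m <- brain * stats::plogis((radius - r) / (p$softness * px_scale))
      lesion_tex <- standardize_field(
        smooth_field(matrix(rnorm(s * s), s, s), sigma = 1.2 * px_scale))
      img <- img + p$amplitude * m + p$heterogeneity * m * lesion_tex
    }

    img <- img + rnorm(s * s, sd = noise_sigma)
    clamp01(img)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_per_class` 8-bit PNG phantoms per class into class-named
#' subfolders of `out_dir` plus a `manifest.csv` (`path,label`), and returns
#' the manifest.  Per-image seeds are derived deterministically from `seed`,
#' so two runs with the same arguments produce byte-identical files.
#'
#' @param n_per_class images per class (at least 1).
#' @param image_side image side in pixels.
#' @param seed run seed.
#' @param out_dir output directory, created if missing; `NULL` keeps the
#'   images in memory (list-column `image` instead of files on disk).
#' @param noise_sigma,classes forwarded to [generate_phantom()].
#' @return tibble manifest with columns `path`, `label` (and `image` when
#'   `out_dir` is `NULL`).
#' @export
generate_dataset <- function(n_per_class, image_side = 128, seed = 1,
                             out_dir = NULL, noise_sigma = 0.02,
                             classes = phantom_classes) {
  if (n_per_class < 1) abort("`n_per_class` must be at least 1.")
  on_disk <- !is.null(out_dir)
  if (on_disk) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(out_dir)) abort(sprintf("cannot create out_dir: %s", out_dir))
  }
  rows <- purrr::imap(classes, function(cl, ci) {
    purrr::map(seq_len(n_per_class), function(i) {
      img <- generate_phantom(cl, image_side,
                              seed = derive_seed(seed, ci, i),
                              noise_sigma = noise_sigma)
      if (on_disk) {
        dir.create(file.path(out_dir, cl), showWarnings = FALSE)
        p <- file.path(out_dir, cl, sprintf("%s_%04d.png", cl, i))
        write_gray_png(img, p)
        tibble(path = p, label = cl)
      } else {
        tibble(path = sprintf("%s_%04d", cl, i), label = cl, image = list(img))
      }
    })
  })
  manifest <- dplyr::bind_rows(rows)
  if (on_disk)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
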