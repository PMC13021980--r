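#' Bilinear resize
#'
#' Resamples a grayscale image to `target_side` x `target_side` with bilinear
#' interpolation under the pixel-center convention (output pixel centers map
#' to source coordinates `(i + 0.5) * h_src / h_tgt - 0.5`, clamped at the
#' borders).  Constant images stay constant and the declared value range is
#' preserved.
#'
#' @param img numeric matrix.
#' @param target_side output side in pixels.
#' @return `target_side` x `target_side` numeric matrix.
#' @export
resize_bilinear <- function(img, target_side = 128) {
  stopifnot_gray(img)
  if (target_side < 1) abort("`target_side` must be positive.")
  h <- nrow(img); w <- ncol(img); n <- as.integer(target_side)
  map_axis <- function(src, tgt) {
    x <- (seq_len(tgt) - 0.5) * src / tgt - 0.5
    x <- pmin(pmax(x, 0), src - 1)
    i0 <- pmin(floor(x), src - 2); i0 <- pmax(i0, 0)
    list(lo = as.integer(i0) + 1L, frac = x - i0)
  }
  if (h == 1 && w == 1) return(matrix(img[1, 1], n, n))
  ry <- map_axis(h, n); rx <- map_axis(w, n)
  if (h == 1) { ry <- list(lo = rep(1L, n), frac = rep(0, n)) }
  if (w == 1) { rx <- list(lo = rep(1L, n), frac = rep(0, n)) }
  hi_y <- pmin(ry$lo + 1L, h); hi_x <- pmin(rx$lo + 1L, w)
  fy <- matrix(ry$frac, n, n); fx <- matrix(rx$frac, n, n, byrow = TRUE)
  a <- img[ry$lo, rx$lo, drop = FALSE]; b <- img[ry$lo, hi_x, drop = FALSE]
  c_ <- img[hi_y, rx$lo, drop = FALSE]; d <- img[hi_y, hi_x, drop = FALSE]
  (1 - fy) * ((1 - fx) * a + fx * b) + fy * ((1 - fx) * c_ + fx * d)
}

#' Intensity normalization
#'
#' `minmax01` maps the observed min to 0 and max to 1; a constant image maps
#' to all zeros (documented convention).  `zscore` centers to mean 0 and
#' scales to population sd 1; a constant image likewise maps to all zeros.
#'
#' @param img numeric matrix.
#' @param mode `"minmax01"` or `"zscore"`.
#' @return numeric matrix.
#' @export
normalize_gray <- function(img, mode = c("minmax01", "zscore")) {
  stopifnot_gray(img)
  mode <- match.arg(mode)
  if (mode == "minmax01") {
    rg <- range(img)
    if (rg[1] == rg[2]) return(img * 0)
    (img - rg[1]) / (rg[2] - rg[1])
  } else {
    standardize_field(img)
  }
}

#' Global histogram equalization
#'
#' Standard CDF-based equalization on 256 integer gray levels; output values
#' lie in \code{{0, ..., 255}}.  Inputs on \code{[0,1]} are first quantized to
#' 8 bits.  The mapping is `round(255 * (cdf(v) - cdf_min) / (n - cdf_min))`
#' with `cdf_min` the CDF at the lowest occupied level, so a constant image is
#' returned unchanged (as level 0).
#'
#' @param img numeric matrix, integer gray levels or \code{[0,1]} reals.
#' @return numeric matrix of equalized integer levels in \code{{0..255}}.
#' @export
hist_equalize <- function(img) {
  stopifnot_gray(img)
  v <- if (gray_peak(img) == 1) floor(clamp01(img) * 255 + 0.5) else round(img)
  v <- pmin(pmax(v, 0), 255)
  counts <- tabulate(v + 1, nbins = 256)
  cdf <- cumsum(counts)
  cdf_min <- cdf[which(counts > 0)[1]]
  n <- length(v)
  denom <- n - cdf_min
  lut <- if (denom == 0) seq(0, 255) * 0 else
    floor(255 * (cdf - cdf_min) / denom + 0.5)
  matrix(lut[v + 1], nrow = nrow(img))
}

# Box mean over square windows of side 2*radius+1, border-normalized via
# integral images: each output is the mean over the intersection of the
# window with the image, so constants are preserved exactly at the borders.
box_mean <- function(img, radius) {
  h <- nrow(img); w <- ncol(img); r <- as.integer(radius)
  cs <- function(m) apply(apply(m, 2, cumsum), 1, cumsum) # t(integral image)
  I <- rbind(0, cbind(0, t(cs(img))))                     # (h+1) x (w+1)
  Cnt <- rbind(0, cbind(0, t(cs(matrix(1, h, w)))))
  y0 <- pmax(seq_len(h) - r, 1L); y1 <- pmin(seq_len(h) + r, h)
  x0 <- pmax(seq_len(w) - r, 1L); x1 <- pmin(seq_len(w) + r, w)
  S <- I[y1 + 1L, x1 + 1L, drop = FALSE] - I[y0, x1 + 1L, drop = FALSE] -
       I[y1 + 1L, x0, drop = FALSE] + I[y0, x0, drop = FALSE]
  N <- Cnt[y1 + 1L, x1 + 1L, drop = FALSE] - Cnt[y0, x1 + 1L, drop = FALSE] -
       Cnt[y1 + 1L, x0, drop = FALSE] + Cnt[y0, x0, drop = FALSE]
  S / N
}

#' Self-guided edge-preserving filter
#'
#' Guided image filter with the input as its own guide, in the standard local
#' linear model formulation: per window `a = var / (var + epsilon)`,
#' `b = (1 - a) * mean`, then the per-pixel averages of `a` and `b` give
#' `out = mean_a * img + mean_b`.  Windows are squares of side
#' `2 * radius + 1` (border-cropped).  Large `epsilon` degenerates to a box
#' mean filter; `epsilon -> 0` returns the input.  Output is clipped to
#' \code{[0,1]}.
#'
#' @param img numeric matrix on \code{[0,1]}.
#' @param radius window radius in pixels (>= 1).
#' @param epsilon regularizer on the squared-intensity scale (> 0).
#' @return filtered numeric matrix on \code{[0,1]}.
#' @export
guided_filter <- function(img, radius = 4, epsilon = 1e-4) {
  stopifnot_gray(img)
  if (radius < 1) abort("`radius` must be at least 1.")
  if (radius > min(dim(img)) / 2)
    abort("`radius` larger than half the image side.")
  if (epsilon <= 0) abort("`epsilon` must be positive.")
  mu <- box_mean(img, radius)
  var_i <- box_mean(img * img, radius) - mu^2
  var_i <- pmax(var_i, 0)
  a <- var_i / (var_i + epsilon)
  b <- (1 - a) * mu
  out <- box_mean(a, radius) * img + box_mean(b, radius)
  clamp01(out)
}

#' Preprocessing pipeline for one image
#'
#' Applies, in order: bilinear resize to `target_side`, min-max normalization
#' to \code{[0,1]}, optional global histogram equalization (rescaled back to
#' \code{[0,1]}), and self-guided filtering.  This is the fixed stage order
#' used ahead of segmentation; equalization defaults to off.
#'
#' @param img numeric matrix (any size / range).
#' @param target_side output side in pixels.
#' @param equalize apply histogram equalization?
#' @param gif_radius,gif_epsilon guided-filter parameters.
#' @return `target_side` x `target_side` matrix on \code{[0,1]}.
#' @export
preprocess_image <- function(img, target_side = 128, equalize = FALSE,
                             gif_radius = 4, gif_epsilon = 1e-4) {
  out <- resize_bilinear(img, target_side)
  out <- normalize_gray(out, "minmax01")
  if (equalize) out <- hist_equalize(out) / 255
  guided_filter(out, radius = gif_radius, epsilon = gif_epsilon)
}
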