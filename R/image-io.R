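#' Read a grayscale image
#'
#' Reads a PNG (or, when the \pkg{tiff} package is available, TIFF) file and
#' returns a numeric matrix of intensities on \code{[0,1]}.  RGB(A) inputs are
#' collapsed to luminance \code{Y = 0.299 R + 0.587 G + 0.114 B}.
#'
#' @param path file path to a `.png`, `.tif` or `.tiff` image.
#' @return numeric matrix with values in \code{[0,1]}.
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        abort("reading TIFF requires the 'tiff' package.")
      tiff::readTIFF(path)
    },
    abort(sprintf("unsupported image format '.%s' (PNG/TIFF supported).", ext))
  )
  if (length(dim(x)) == 3) {
    if (dim(x)[3] >= 3) x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    else x <- x[, , 1]
  }
  clamp01(matrix(as.numeric(x), nrow = nrow(x)))
}

#' Write a grayscale image as an 8-bit PNG
#'
#' Intensities on \code{[0,1]} are scaled by 255 and rounded half-up to an
#' integer gray level before export, so the file round-trips bit-exactly
#' through [read_gray()].
#'
#' @param img numeric matrix with values in \code{[0,1]}.
#' @param path output path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  stopifnot_gray(img)
  v <- floor(clamp01(img) * 255 + 0.5)
  png::writePNG(v / 255, target = path)
  invisible(path)
}

#' Quantize intensities to integer gray levels
#'
#' Maps values on \code{[0, peak]} to \code{{0, ..., n_levels - 1}} by
#' equal-width binning (the top edge maps to the top level).
#'
#' @param img numeric matrix.
#' @param n_levels number of gray levels.
#' @param peak upper end of the intensity range; guessed from the data by
#'   default (255 when any value exceeds 1, else 1).
#' @return integer matrix with values in \code{{0, ..., n_levels - 1}}.
#' @export
quantize_gray <- function(img, n_levels, peak = gray_peak(img)) {
  stopifnot_gray(img)
  if (n_levels < 2) abort("`n_levels` must be at least 2.")
  q <- floor(pmin(pmax(img, 0), peak) / peak * n_levels)
  q[q == n_levels] <- n_levels - 1
  matrix(as.integer(q), nrow = nrow(img))
}
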