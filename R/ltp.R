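# Neighbor offsets read clockwise from the top-left corner; the first
# neighbor carries the most significant bit of the 8-bit pattern code.
ltp_neighbors <- rbind(
  TL = c(-1L, -1L), T = c(-1L, 0L), TR = c(-1L, 1L), R = c(0L, 1L),
  BR = c(1L, 1L), B = c(1L, 0L), BL = c(1L, -1L), L = c(0L, -1L))

#' Local ternary pattern descriptor
#'
#' For every interior pixel with center value `a`, each of its 8 neighbors
#' `p` receives a ternary code: 1 when `p >= a + t`, -1 when `p <= a - t`,
#' and 0 inside the tolerance band.  The ternary pattern is split into an
#' upper binary pattern (the +1 positions) and a lower binary pattern (the
#' -1 positions); each is read clockwise from the top-left neighbor, most
#' significant bit first, into an 8-bit code, and the two 256-bin code
#' histograms are concatenated into a 512-value descriptor.  With `t = 0`
#' the upper pattern reduces to the local binary pattern under the `>=`
#' comparison.
#'
#' @param img numeric matrix, at least 3 x 3; any intensity scale (the
#'   threshold is in the same units as the image).
#' @param t tolerance half-width (>= 0); default 5 on the 0..255 integer
#'   scale or 0.02 on \code{[0,1]} data.
#' @return an object of class `"ltp_descriptor"`: list with `upper_hist`
#'   and `lower_hist` (256 counts each), `vector` (512 named values,
#'   upper then lower), `t` and `n_interior`.
#' @export
ltp_encode <- function(img, t = if (gray_peak(img) == 1) 0.02 else 5) {
  stopifnot_gray(img)
  if (nrow(img) < 3 || ncol(img) < 3) abort("`img` must be at least 3 x 3.")
  if (t < 0) abort("`t` must be non-negative.")
  h <- nrow(img); w <- ncol(img)
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  a <- img[ri, ci, drop = FALSE]
  upper <- matrix(0L, length(ri), length(ci))
  lower <- matrix(0L, length(ri), length(ci))
  for (b in seq_len(8)) {
    d <- ltp_neighbors[b, ]
    p <- img[ri + d[1], ci + d[2], drop = FALSE]
    wgt <- bitwShiftL(1L, 8L - b)
    upper <- upper + wgt * (p >= a + t)
    lower <- lower + wgt * (p <= a - t)
  }
  uh <- tabulate(upper + 1L, nbins = 256)
  lh <- tabulate(lower + 1L, nbins = 256)
  vec <- setNames(c(uh, lh),
                  c(sprintf("ltp_u%03d", 0:255), sprintf("ltp_l%03d", 0:255)))
  structure(list(upper_hist = uh, lower_hist = lh, vector = vec,
                 t = t, n_interior = length(a)),
            class = "ltp_descriptor")
}

#' @export
print.ltp_descriptor <- function(x, ...) {
  cat(sprintf("LTP descriptor: t = %g, %d interior pixels, 512 bins\n",
              x$t, x$n_interior))
  invisible(x)
}
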