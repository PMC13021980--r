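# Connected-component labeling where two adjacent pixels are connected iff
# they hold the same integer value; every pixel receives a component id.
# Adjacency is 8-connected (edges + diagonals) or 4-connected.
same_value_components <- function(vals, connectivity = 8) {
  h <- nrow(vals); w <- ncol(vals); n <- h * w
  shifts <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
  row_i <- rep(seq_len(h), times = w)
  col_i <- rep(seq_len(w), each = h)
  edges <- purrr::map(shifts, function(s) {
    r2 <- row_i + s[1]; c2 <- col_i + s[2]
    ok <- r2 >= 1 & r2 <= h & c2 >= 1 & c2 <= w
    from <- which(ok); to <- (c2[ok] - 1L) * h + r2[ok]
    same <- vals[from] == vals[to]
    cbind(from[same], to[same])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  matrix(as.integer(igraph::components(g)$membership), h, w)
}

#' Grayscale color coherence vector
#'
#' Quantizes intensities into `n_bins` equal-width bins, labels the
#' 8-connected components of each bin's pixel set, and splits every bin's
#' pixel count into a coherent part (pixels in a component of size at least
#' `tau`) and an incoherent part.  `tau` defaults to 1\% of the pixel count,
#' rounded up.  The descriptor interleaves the per-bin coherent and
#' incoherent counts, giving `2 * n_bins` values (54 with the default 27
#' bins); their sum equals the number of pixels.
#'
#' @param img numeric matrix (raw intensities).
#' @param n_bins number of intensity bins (default 27).
#' @param tau coherence threshold in pixels; `NULL` for
#'   `ceiling(0.01 * n_pixels)`.
#' @param peak intensity peak for the equal-width binning.
#' @param connectivity 8 (default) or 4.
#' @return an object of class `"ccv_descriptor"`: list with `alpha`
#'   (coherent counts), `beta` (incoherent counts), `vector`
#'   (`ccv_a01, ccv_b01, ...`), `tau`, `n_bins`.
#' @export
ccv_compute <- function(img, n_bins = 27, tau = NULL, peak = gray_peak(img),
                        connectivity = 8) {
  stopifnot_gray(img)
  if (n_bins < 2) abort("`n_bins` must be at least 2.")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  n_px <- length(img)
  if (is.null(tau)) tau <- ceiling(0.01 * n_px)
  if (n_bins > 256)
    warn("`n_bins` exceeds the representable 8-bit levels; proceeding.")
  bins <- quantize_gray(img, n_bins, peak)
  comp <- same_value_components(bins, connectivity)
  sizes <- tabulate(comp)
  coherent <- sizes[comp] >= tau
  alpha <- vapply(seq_len(n_bins) - 1L,
                  function(b) sum(bins == b & coherent), numeric(1))
  beta <- vapply(seq_len(n_bins) - 1L,
                 function(b) sum(bins == b & !coherent), numeric(1))
  vec <- as.numeric(rbind(alpha, beta))
  names(vec) <- as.vector(rbind(sprintf("ccv_a%02d", seq_len(n_bins)),
                                sprintf("ccv_b%02d", seq_len(n_bins))))
  structure(list(alpha = alpha, beta = beta, vector = vec,
                 tau = tau, n_bins = n_bins, connectivity = connectivity),
            class = "ccv_descriptor")
}

#' @export
print.ccv_descriptor <- function(x, ...) {
  cat(sprintf("CCV descriptor: %d bins, tau = %d px, %d coherent / %d incoherent\n",
              x$n_bins, x$tau, sum(x$alpha), sum(x$beta)))
  invisible(x)
}
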