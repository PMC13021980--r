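# Unit displacements (drow, dcol) of the 8 co-occurrence directions,
# indexed 1..8 = E, NE, N, NW, W, SW, S, SE (counter-clockwise from east).
glcm_directions <- rbind(
  E = c(0L, 1L), NE = c(-1L, 1L), N = c(-1L, 0L), NW = c(-1L, -1L),
  W = c(0L, -1L), SW = c(1L, -1L), S = c(1L, 0L), SE = c(1L, 1L))

glcm_angles <- c(0L, 45L, 90L, 135L, 180L, 225L, 270L, 315L)

#' Gray-level co-occurrence matrix
#'
#' Counts ordered pairs of gray levels `(img[p], img[p + d])` where `d` is the
#' chosen direction's unit displacement times `offset`, with pairs clipped at
#' the image border, and normalizes by the total pair count.  Alongside the
#' normalized matrix `f`, the marginal distributions, their means and standard
#' deviations, and the sum/difference distributions are populated — these are
#' the ingredients of the second-order texture statistics.
#'
#' @param img integer matrix with values in \code{{0, ..., n_levels - 1}}
#'   (see [quantize_gray()]).
#' @param n_levels number of gray levels N.
#' @param direction 1..8 (E, NE, N, NW, W, SW, S, SE).
#' @param offset pixel distance between the pair members (>= 1).
#' @param symmetric also count each pair in the reverse order?  Off by
#'   default: pairs are ordered.
#' @return an object of class `"glcm_matrix"`: list with `f` (N x N
#'   probabilities), `counts`, `n_levels`, `direction`, `offset`, marginals
#'   `P_u`/`P_v`, `mu_u`/`mu_v`, `sigma_u`/`sigma_v`, and the sum/difference
#'   distributions `P_sum` (indices 0..2(N-1)) and `P_diff` (indices
#'   0..N-1, over `|u - v|`).
#' @export
glcm_compute <- function(img, n_levels, direction = 1, offset = 1,
                         symmetric = FALSE) {
  stopifnot_gray(img)
  if (any(img < 0) || any(img >= n_levels) || any(img != floor(img)))
    abort("`img` must hold integer levels in {0, ..., n_levels - 1}; quantize first.")
  if (!direction %in% 1:8) abort("`direction` must be in 1..8.")
  if (offset < 1) abort("`offset` must be at least 1.")
  h <- nrow(img); w <- ncol(img)
  d <- glcm_directions[direction, ] * as.integer(offset)
  r0 <- max(1L, 1L - d[1]):min(h, h - d[1])
  c0 <- max(1L, 1L - d[2]):min(w, w - d[2])
  if (length(r0) == 0 || length(c0) == 0)
    abort("`offset` too large: no pixel pairs fit inside the image.")
  u <- img[r0, c0, drop = FALSE]
  v <- img[r0 + d[1], c0 + d[2], drop = FALSE]
  counts <- matrix(tabulate(as.integer(u) * n_levels + as.integer(v) + 1L,
                            nbins = n_levels * n_levels),
                   n_levels, n_levels, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  f <- counts / sum(counts)

  lev <- seq_len(n_levels) - 1
  P_u <- rowSums(f); P_v <- colSums(f)
  mu_u <- sum(lev * P_u); mu_v <- sum(lev * P_v)
  sigma_u <- sqrt(sum((lev - mu_u)^2 * P_u))
  sigma_v <- sqrt(sum((lev - mu_v)^2 * P_v))
  sum_idx <- outer(lev, lev, `+`)
  diff_idx <- abs(outer(lev, lev, `-`))
  P_sum <- vapply(0:(2 * (n_levels - 1)), function(l) sum(f[sum_idx == l]),
                  numeric(1))
  P_diff <- vapply(0:(n_levels - 1), function(l) sum(f[diff_idx == l]),
                   numeric(1))
  structure(list(f = f, counts = counts, n_levels = n_levels,
                 direction = direction, offset = offset,
                 P_u = P_u, P_v = P_v, mu_u = mu_u, mu_v = mu_v,
                 sigma_u = sigma_u, sigma_v = sigma_v,
                 P_sum = setNames(P_sum, 0:(2 * (n_levels - 1))),
                 P_diff = setNames(P_diff, 0:(n_levels - 1))),
            class = "glcm_matrix")
}

#' Second-order texture statistics of a co-occurrence matrix
#'
#' Energy \eqn{E = \sum\sum f(u,v)^2}, contrast
#' \eqn{C = \sum\sum (u-v)^2 f(u,v)}, correlation
#' \eqn{(\sum\sum u v f(u,v) - \mu_u \mu_v) / (\sigma_u \sigma_v)} and
#' homogeneity \eqn{H = \sum\sum f(u,v) / (1 + |u-v|^2)}.  A constant image
#' has E = 1, C = 0, H = 1; correlation is reported as 0 when either marginal
#' sd is zero (documented convention for the degenerate 0/0 case).
#'
#' @param m a [glcm_compute()] result.
#' @return tibble with one row: `energy`, `contrast`, `correlation`,
#'   `homogeneity`.
#' @export
glcm_features <- function(m) {
  if (!inherits(m, "glcm_matrix")) abort("`m` must come from glcm_compute().")
  lev <- seq_len(m$n_levels) - 1
  dif2 <- outer(lev, lev, `-`)^2
  uv <- outer(lev, lev, `*`)
  corr <- if (m$sigma_u * m$sigma_v == 0) 0 else
    (sum(uv * m$f) - m$mu_u * m$mu_v) / (m$sigma_u * m$sigma_v)
  tibble(energy = sum(m$f^2),
         contrast = sum(dif2 * m$f),
         correlation = corr,
         homogeneity = sum(m$f / (1 + dif2)))
}

#' GLCM descriptor vector for one image
#'
#' Quantizes the image to `n_levels` gray levels, computes one co-occurrence
#' matrix per requested direction at the given offset, and concatenates the
#' four texture statistics of each.  With the defaults (4 directions at
#' offset 1) the descriptor has 16 named values.
#'
#' @param img numeric matrix (raw intensities; quantized internally).
#' @param n_levels gray-level count used for quantization.
#' @param directions subset of 1..8; default the 4 canonical directions
#'   E, NE, N, NW (0/45/90/135 degrees).
#' @param offset pair distance in pixels.
#' @param peak intensity peak for quantization (guessed from the data).
#' @return named numeric vector, e.g. `glcm_energy_a0`, ...,
#'   `glcm_homogeneity_a135`.
#' @export
glcm_descriptor <- function(img, n_levels = 32, directions = 1:4, offset = 1,
                            peak = gray_peak(img)) {
  q <- quantize_gray(img, n_levels, peak)
  out <- purrr::map(directions, function(d) {
    feats <- glcm_features(glcm_compute(q, n_levels, direction = d,
                                        offset = offset))
    setNames(as.numeric(feats),
             sprintf("glcm_%s_a%d", names(feats), glcm_angles[d]))
  })
  unlist(out)
}
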