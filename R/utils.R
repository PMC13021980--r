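# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's RNG stream.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic derivation of per-stage / per-image seeds from one run seed,
# kept strictly below 2^31 so set.seed() always accepts it.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 131071 + as.double(k) * 8191 + 1) %% 2147483647
  as.integer(s)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopifnot_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    abort(sprintf("`%s` must be a numeric matrix (grayscale image).", arg))
  if (nrow(img) < 1 || ncol(img) < 1)
    abort(sprintf("`%s` must have at least one row and one column.", arg))
  invisible(img)
}

# Value range of an image: 255-peak integer convention if any value
# exceeds 1, otherwise the [0,1] real convention.
gray_peak <- function(img) if (max(img) > 1) 255 else 1

# Row-normalized 1-D Gaussian smoothing operator (n x n); truncated at
# 3 sigma with renormalized borders, so constants are preserved exactly.
gauss_operator <- function(n, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- k[ok] / sum(k[ok])
  }
  M
}

# Separable Gaussian smoothing of a matrix field.
smooth_field <- function(m, sigma) {
  Gr <- gauss_operator(nrow(m), sigma)
  Gc <- if (ncol(m) == nrow(m)) Gr else gauss_operator(ncol(m), sigma)
  Gr %*% m %*% t(Gc)
}

# Standardize a field to mean 0, sd 1 (population sd); all-zero if constant.
standardize_field <- function(m) {
  s <- sqrt(mean((m - mean(m))^2))
  if (s == 0) return(m * 0)
  (m - mean(m)) / s
}
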