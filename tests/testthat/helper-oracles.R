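# Brute-force reference implementations, deliberately written as plain
# double loops so they stay independent of the package's vectorized code
# paths.  All expected values in the suite derived from these oracles were
# computed here, at test time.

random_level_image <- function(h, w, n_levels) {
  matrix(sample(0:(n_levels - 1), h * w, replace = TRUE), h, w)
}

oracle_glcm_counts <- function(img, n_levels, direction, offset) {
  # direction table repeated here on purpose (independent of the package's)
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  d <- dirs[[direction]] * offset
  counts <- matrix(0, n_levels, n_levels)
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img)) {
        u <- img[r, c] + 1; v <- img[r2, c2] + 1
        counts[u, v] <- counts[u, v] + 1
      }
    }
  }
  counts
}

oracle_glcm_features <- function(f) {
  N <- nrow(f)
  E <- 0; C <- 0; H <- 0; uvf <- 0
  for (u in 0:(N - 1)) for (v in 0:(N - 1)) {
    p <- f[u + 1, v + 1]
    E <- E + p^2
    C <- C + (u - v)^2 * p
    H <- H + p / (1 + (u - v)^2)
    uvf <- uvf + u * v * p
  }
  Pu <- rowSums(f); Pv <- colSums(f)
  mu_u <- sum((0:(N - 1)) * Pu); mu_v <- sum((0:(N - 1)) * Pv)
  s_u <- sqrt(sum(((0:(N - 1)) - mu_u)^2 * Pu))
  s_v <- sqrt(sum(((0:(N - 1)) - mu_v)^2 * Pv))
  corr <- if (s_u * s_v == 0) 0 else (uvf - mu_u * mu_v) / (s_u * s_v)
  list(energy = E, contrast = C, correlation = corr, homogeneity = H)
}

oracle_ltp <- function(img, t) {
  # neighbors clockwise from top-left, MSB first
  nb <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
             c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  uh <- numeric(256); lh <- numeric(256)
  for (r in 2:(nrow(img) - 1)) {
    for (c in 2:(ncol(img) - 1)) {
      a <- img[r, c]; up <- 0; lo <- 0
      for (b in 1:8) {
        p <- img[r + nb[[b]][1], c + nb[[b]][2]]
        if (p >= a + t) up <- up + 2^(8 - b)
        if (p <= a - t) lo <- lo + 2^(8 - b)
      }
      uh[up + 1] <- uh[up + 1] + 1
      lh[lo + 1] <- lh[lo + 1] + 1
    }
  }
  list(upper = uh, lower = lh)
}

oracle_lbp <- function(img) {
  # plain LBP with >= comparison, same bit order as oracle_ltp's upper code
  oracle_ltp(img, 0)$upper
}

# stack-based flood fill, no igraph
oracle_ccv <- function(bins, tau, connectivity = 8) {
  h <- nrow(bins); w <- ncol(bins)
  nb <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    nb <- c(nb, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  comp <- matrix(0L, h, w); next_id <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (comp[r0, c0] == 0L) {
      next_id <- next_id + 1L
      stack <- list(c(r0, c0)); comp[r0, c0] <- next_id
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (d in nb) {
          r <- p[1] + d[1]; c <- p[2] + d[2]
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              comp[r, c] == 0L && bins[r, c] == bins[p[1], p[2]]) {
            comp[r, c] <- next_id
            stack[[length(stack) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  sizes <- tabulate(comp)
  n_bins <- max(bins) + 1
  alpha <- numeric(n_bins); beta <- numeric(n_bins)
  for (b in 0:(n_bins - 1)) {
    sel <- bins == b
    alpha[b + 1] <- sum(sel & sizes[comp] >= tau)
    beta[b + 1] <- sum(sel & sizes[comp] < tau)
  }
  list(alpha = alpha, beta = beta)
}

# AUC as the Mann-Whitney pair statistic: P(score_pos > score_neg) + ties/2
oracle_auc <- function(pos_scores, neg_scores) {
  tot <- 0
  for (p in pos_scores) for (n in neg_scores)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos_scores) * length(neg_scores))
}

# small synthetic feature tibble with class-separated means, for classifier
# and fusion tests that do not need images
synthetic_feature_table <- function(n_per_class, n_feat = 12, sep = 3,
                                    seed = 1) {
  classes <- c("glioma", "meningioma", "pituitary", "no_tumor")
  withr::with_seed(seed, {
    rows <- lapply(seq_along(classes), function(ci) {
      mu <- rnorm(n_feat) * sep
      X <- matrix(rnorm(n_per_class * n_feat), n_per_class, n_feat)
      X <- sweep(X, 2, mu, `+`)
      colnames(X) <- sprintf("glcm_f%02d", seq_len(n_feat))
      dplyr::bind_cols(
        tibble::tibble(path = sprintf("%s_%03d", classes[ci],
                                      seq_len(n_per_class)),
                       label = classes[ci]),
        tibble::as_tibble(X))
    })
    dplyr::bind_rows(rows)
  })
}
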