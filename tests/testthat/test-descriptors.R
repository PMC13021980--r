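# GLCM ---------------------------------------------------------------------

test_that("GLCM counts match hand-enumerated pairs on a 2x2 image", {
  img <- rbind(c(0, 0), c(1, 1))
  m <- glcm_compute(img, n_levels = 2, direction = 1, offset = 1) # east
  expect_equal(m$counts, rbind(c(1, 0), c(0, 1)))
  expect_equal(m$f, rbind(c(0.5, 0), c(0, 0.5)))
  feats <- glcm_features(m)
  expect_equal(feats$energy, 0.5)
  expect_equal(feats$contrast, 0)
  # mass sits on the diagonal, so homogeneity is total mass = 1 and the
  # two levels are perfectly linearly dependent
  expect_equal(feats$homogeneity, 1)
  expect_equal(feats$correlation, 1)
})

test_that("constant image gives the degenerate single-cell GLCM", {
  m <- glcm_compute(matrix(3, 6, 6), n_levels = 8, direction = 2)
  expect_equal(sum(m$f), 1)
  expect_equal(m$f[4, 4], 1)
  expect_equal(m$mu_u, 3); expect_equal(m$mu_v, 3)
  expect_equal(m$sigma_u, 0)
  feats <- glcm_features(m)
  expect_equal(feats$energy, 1)
  expect_equal(feats$contrast, 0)
  expect_equal(feats$homogeneity, 1)
  expect_equal(feats$correlation, 0) # documented 0/0 convention
})

test_that("GLCM marginals and sum/difference distributions normalize", {
  withr::with_seed(5, {
    img <- random_level_image(8, 8, 4)
    for (d in 1:8) {
      m <- glcm_compute(img, 4, direction = d)
      expect_equal(sum(m$f), 1, tolerance = 1e-12)
      expect_equal(m$P_u, rowSums(m$f), tolerance = 1e-12)
      expect_equal(m$P_v, colSums(m$f), tolerance = 1e-12)
      expect_equal(sum(m$P_sum), 1, tolerance = 1e-12)
      expect_equal(sum(m$P_diff), 1, tolerance = 1e-12)
    }
  })
})

test_that("GLCM features match the brute-force oracle on random images", {
  withr::with_seed(17, {
    for (i in 1:20) {
      img <- random_level_image(sample(3:8, 1), sample(3:8, 1), sample(2:6, 1))
      d <- sample(1:8, 1)
      m <- glcm_compute(img, max(img) + 1, direction = d)
      oc <- oracle_glcm_counts(img, max(img) + 1, d, 1)
      expect_equal(m$counts, oc, ignore_attr = TRUE)
      of <- oracle_glcm_features(oc / sum(oc))
      feats <- glcm_features(m)
      expect_equal(feats$energy, of$energy, tolerance = 1e-12)
      expect_equal(feats$contrast, of$contrast, tolerance = 1e-12)
      expect_equal(feats$correlation, of$correlation, tolerance = 1e-12)
      expect_equal(feats$homogeneity, of$homogeneity, tolerance = 1e-12)
    }
  })
})

test_that("transposing the image flips direction semantics consistently", {
  withr::with_seed(3, {
    img <- random_level_image(7, 9, 4)
    east <- glcm_compute(img, 4, direction = 1)       # (0, +1)
    south_t <- glcm_compute(t(img), 4, direction = 7) # (+1, 0) on transpose
    expect_equal(east$f, south_t$f)
  })
})

test_that("the default GLCM descriptor has 16 named values in (valid) range", {
  img <- generate_phantom("glioma", 48, seed = 1)
  v <- glcm_descriptor(img, peak = 1)
  expect_length(v, 16)
  expect_true(all(grepl("^glcm_", names(v))))
  e <- v[grepl("energy", names(v))]; h <- v[grepl("homogeneity", names(v))]
  expect_true(all(e > 0 & e <= 1))
  expect_true(all(h > 0 & h <= 1))
  expect_true(all(v[grepl("contrast", names(v))] >= 0))
  expect_true(all(abs(v[grepl("correlation", names(v))]) <= 1 + 1e-12))
})

# LTP ----------------------------------------------------------------------

test_that("LTP degenerate patterns follow the ternary rule", {
  d <- ltp_encode(matrix(100, 5, 5), t = 5)
  expect_equal(d$upper_hist[1], 9)   # all-zero code for all 9 interior pixels
  expect_equal(d$lower_hist[1], 9)
  expect_equal(sum(d$upper_hist), 9); expect_equal(sum(d$lower_hist), 9)

  img <- matrix(120, 3, 3); img[2, 2] <- 100
  d2 <- ltp_encode(img, t = 10)
  expect_equal(which(d2$upper_hist == 1) - 1, 255) # all neighbors >= a + t
  expect_equal(which(d2$lower_hist == 1) - 1, 0)
  expect_error(ltp_encode(matrix(0, 2, 3)), "3 x 3")
})

test_that("LTP matches the brute-force oracle and conserves mass", {
  withr::with_seed(23, {
    for (i in 1:15) {
      img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
      t <- sample(c(0, 3, 10), 1)
      d <- ltp_encode(img, t = t)
      o <- oracle_ltp(img, t)
      expect_equal(d$upper_hist, o$upper)
      expect_equal(d$lower_hist, o$lower)
      expect_equal(sum(d$upper_hist), 36)
      expect_equal(sum(d$lower_hist), 36)
      expect_length(d$vector, 512)
    }
  })
})

test_that("a neighbor never sets both upper and lower bits when t > 0", {
  withr::with_seed(29, {
    img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
    t <- 4
    h <- nrow(img)
    for (r in 2:(h - 1)) for (c in 2:(h - 1)) {
      a <- img[r, c]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        p <- img[r + dr, c + dc]
        expect_false(p >= a + t && p <= a - t)
      }
    }
  })
})

test_that("at t = 0 the upper pattern is the >=-comparison LBP", {
  withr::with_seed(31, {
    for (i in 1:20) {
      img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
      expect_equal(ltp_encode(img, t = 0)$upper_hist, oracle_lbp(img))
    }
  })
})

# CCV ----------------------------------------------------------------------

test_that("a uniform 128x128 image is fully coherent in one bin", {
  d <- ccv_compute(matrix(0.5, 128, 128), n_bins = 27, peak = 1)
  expect_equal(d$tau, 164) # ceil(0.01 * 16384)
  expect_equal(sum(d$alpha), 16384)
  expect_equal(sum(d$alpha > 0), 1)
  expect_equal(sum(d$beta), 0)
  expect_length(d$vector, 54)
})

test_that("1-px checkerboard coherence pins the 8-connectivity default", {
  side <- 16
  cb <- outer(1:side, 1:side, function(r, c) (r + c) %% 2) * 255
  # under 8-connectivity diagonal same-bin neighbors connect: all coherent
  d8 <- ccv_compute(cb, n_bins = 2, peak = 255)
  expect_equal(sum(d8$alpha), side^2)
  # under 4-connectivity every pixel is isolated: all incoherent
  d4 <- ccv_compute(cb, n_bins = 2, peak = 255, connectivity = 4)
  expect_equal(sum(d4$beta), side^2)
})

test_that("CCV matches the flood-fill oracle exactly on random images", {
  withr::with_seed(37, {
    for (i in 1:10) {
      img <- matrix(sample(0:2, 256, replace = TRUE), 16, 16)
      tau <- sample(2:6, 1)
      conn <- sample(c(4, 8), 1)
      d <- ccv_compute(img, n_bins = 3, tau = tau, peak = 3,
                       connectivity = conn)
      o <- oracle_ccv(img, tau, conn)
      expect_equal(d$alpha, o$alpha)
      expect_equal(d$beta, o$beta)
      expect_equal(sum(d$alpha + d$beta), 256)
    }
  })
})

test_that("coherent mass is non-increasing in tau", {
  img <- generate_phantom("meningioma", 48, seed = 4)
  taus <- c(1, 5, 20, 80, 400)
  mass <- vapply(taus, function(tt)
    sum(ccv_compute(img, tau = tt, peak = 1)$alpha), numeric(1))
  expect_true(all(diff(mass) <= 0))
})
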