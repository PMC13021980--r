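test_that("confusion matrix counts land in the right cells", {
  cls <- c("glioma", "meningioma", "pituitary", "no_tumor")
  y <- rep(cls, each = 3)
  cm <- confusion(y, y)
  expect_equal(diag(unclass(cm)), setNames(rep(3L, 4), cls))
  expect_equal(sum(cm) - sum(diag(unclass(cm))), 0L)
  cm1 <- confusion("pituitary", "glioma")
  expect_equal(sum(cm1), 1L)
  expect_equal(cm1["pituitary", "glioma"], 1L)
  expect_error(confusion("glioma", "sarcoma"), "unknown label")
  expect_error(confusion(c("glioma", "glioma"), "glioma"), "equal length")
})

test_that("a reported per-class row reproduces its totals", {
  # pituitary: 344 correct, 2 to glioma, 10 to meningioma, out of 356
  y_true <- rep("pituitary", 356)
  y_pred <- c(rep("pituitary", 344), rep("glioma", 2), rep("meningioma", 10))
  cm <- confusion(y_true, y_pred)
  expect_equal(sum(cm["pituitary", ]), 356L)
  expect_equal(cm["pituitary", "pituitary"], 344L)
  m <- confusion_metrics(cm)
  expect_equal(m$per_class$recall[m$per_class$class == "pituitary"], 344 / 356)
})

test_that("metrics on perfect predictions are all 1", {
  y <- rep(c("glioma", "meningioma", "pituitary", "no_tumor"), times = c(4, 3, 2, 1))
  m <- confusion_metrics(confusion(y, y))
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$f1 == 1))
  expect_true(all(m$per_class$specificity == 1))
  expect_equal(m$macro$f1, 1)
})

test_that("per-class metrics follow their confusion-matrix definitions", {
  y_true <- c(rep("glioma", 5), rep("meningioma", 5))
  y_pred <- c("glioma", "glioma", "glioma", "meningioma", "meningioma",
              "meningioma", "meningioma", "meningioma", "meningioma", "glioma")
  m <- confusion_metrics(confusion(y_true, y_pred))
  g <- m$per_class[m$per_class$class == "glioma", ]
  expect_equal(g$precision, 3 / 4)       # TP 3, FP 1
  expect_equal(g$recall, 3 / 5)          # FN 2
  expect_equal(g$specificity, 4 / 5)     # TN 4, FP 1
  expect_equal(g$accuracy, 7 / 10)       # (TP + TN) / total
  expect_equal(g$f1, 2 * (3 / 4) * (3 / 5) / (3 / 4 + 3 / 5))
  # macro F1 bounded by the per-class extremes
  expect_gte(m$macro$f1, min(m$per_class$f1))
  expect_lte(m$macro$f1, max(m$per_class$f1))
  # absent classes flagged, not NaN
  expect_true(all(m$per_class$undefined[m$per_class$class %in%
                                          c("pituitary", "no_tumor")]))
  expect_false(any(is.nan(unlist(m$per_class[, -1]))))
})

test_that("f1_score matches the harmonic-mean identity on any scale", {
  expect_equal(f1_score(0.5, 0.5), 0.5)
  expect_equal(f1_score(0, 0), 0)
  expect_equal(f1_score(62.96, 76.58) / 100,
               2 * 0.6296 * 0.7658 / (0.6296 + 0.7658), tolerance = 1e-12)
})

test_that("ROC/AUC handles separation, ties, and the pair-counting oracle", {
  cls <- c("glioma", "meningioma", "pituitary", "no_tumor")
  onehotish <- function(p_glioma) cbind(p_glioma, (1 - p_glioma) / 3,
                                        (1 - p_glioma) / 3, (1 - p_glioma) / 3)
  # perfect separation
  y <- c(rep("glioma", 5), rep("meningioma", 5))
  P <- onehotish(c(rep(0.9, 5), rep(0.1, 5))); colnames(P) <- cls
  expect_equal(roc_auc(y, P)$auc[["glioma"]], 1)
  # all-equal scores: single operating point, AUC 1/2
  P2 <- onehotish(rep(0.4, 10)); colnames(P2) <- cls
  expect_equal(roc_auc(y, P2)$auc[["glioma"]], 0.5)
  # absent class: NA, not 0
  expect_true(is.na(roc_auc(y, P)$auc[["pituitary"]]))
  # exhaustive Mann-Whitney pair comparison on random scores with ties
  withr::with_seed(41, {
    for (i in 1:5) {
      y20 <- sample(c("glioma", "no_tumor"), 20, replace = TRUE,
                    prob = c(0.4, 0.6))
      if (length(unique(y20)) < 2) next
      s <- round(runif(20), 1) # coarse grid forces ties
      P3 <- onehotish(s); colnames(P3) <- cls
      got <- roc_auc(y20, P3)$auc[["glioma"]]
      expect_equal(got, oracle_auc(s[y20 == "glioma"], s[y20 != "glioma"]))
      # invariance under strictly monotone transform of the scores
      P4 <- onehotish(plogis(5 * s)); colnames(P4) <- cls
      expect_equal(roc_auc(y20, P4)$auc[["glioma"]], got)
    }
  })
})

test_that("evaluate_predictions bundles metrics, ROC and tidiers", {
  withr::with_seed(43, {
    cls <- c("glioma", "meningioma", "pituitary", "no_tumor")
    y <- sample(cls, 40, replace = TRUE)
    P <- matrix(runif(160), 40, 4); P <- P / rowSums(P); colnames(P) <- cls
    pred <- cls[max.col(P)]
    rep <- evaluate_predictions(y, pred, prob_matrix = P)
    expect_s3_class(rep, "eval_report")
    expect_equal(rep$n, 40)
    expect_equal(rep$accuracy, mean(y == pred))
    td <- tidy(rep)
    expect_true("auc" %in% names(td))
    gl <- glance(rep)
    expect_true(all(c("accuracy", "macro_f1") %in% names(gl)))
    expect_s3_class(autoplot(rep), "ggplot")
    expect_s3_class(plot_confusion(rep), "ggplot")
  })
})

test_that("report tables order combos with tri-fusion last and round-trip", {
  y <- rep(c("glioma", "meningioma", "pituitary", "no_tumor"), each = 5)
  mk <- function(flip) {
    p <- y; if (flip) p[1] <- "no_tumor"
    evaluate_predictions(y, p)
  }
  reports <- list("glcm+ltp+ccv" = mk(TRUE), glcm = mk(FALSE),
                  "glcm+ccv" = mk(TRUE))
  tab <- report_tables(reports)
  expect_equal(nrow(tab), 12)
  expect_equal(tab$combo[1], "glcm")
  expect_equal(tab$combo[nrow(tab)], "glcm+ltp+ccv")
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric),
                                             ~ round(.x, 4))), f,
            row.names = FALSE)
  back <- read.csv(f)
  expect_equal(back$f1_score, round(tab$f1_score, 4), tolerance = 1e-12)
})
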