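make_split_features <- function(n_per_class = 20, sep = 3, seed = 1) {
  tb <- synthetic_feature_table(n_per_class, sep = sep, seed = seed)
  s <- stratified_split(tb, 0.8, seed = seed)
  list(train = tb[s$split == "train", ], test = tb[s$split == "test", ],
       all = tb, split = s$split)
}

test_that("prediction contract: normalized rows, ties, equivariance", {
  d <- make_split_features(8)
  cfg <- train_config(max_epochs = 3, batch_size = 8, seed = 1)
  clf <- train_classifier(as.matrix(d$train[, -(1:2)]), d$train$label,
                          as.matrix(d$test[, -(1:2)]), d$test$label, cfg)
  X <- as.matrix(d$test[, -(1:2)])
  pr <- predict(clf, X)
  P <- as.matrix(dplyr::select(pr, dplyr::starts_with(".prob_")))
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  # eval-mode determinism
  expect_identical(pr, predict(clf, X))
  # batch equivariance
  perm <- rev(seq_len(nrow(X)))
  expect_identical(pr[perm, ], predict(clf, X[perm, , drop = FALSE]))
  # all-zero head weights: uniform probabilities, tie broken to class 1
  clf0 <- clf
  clf0$weights$Wh[] <- 0; clf0$weights$bh[] <- 0
  pr0 <- predict(clf0, X)
  expect_equal(unname(as.matrix(pr0[, -1])[1, ]), rep(0.25, 4),
               tolerance = 1e-12)
  expect_true(all(pr0$.pred_class == "glioma"))
  # contract violations error
  expect_error(predict(clf, X[, -1, drop = FALSE]), "does not match")
  expect_error(train_classifier(as.matrix(d$train[, -(1:2)]),
                                c("tumorX", d$train$label[-1]),
                                as.matrix(d$test[, -(1:2)]), d$test$label,
                                cfg),
               "outside the class set")
})

test_that("analytic gradients agree with numerical differentiation", {
  ns <- asNamespace("neurotexfusion")
  withr::with_seed(1, {
    Xi <- matrix(rnorm(5 * 6), 5, 6)
    Xf <- matrix(rnorm(5 * 3), 5, 3)
    Y <- diag(4)[sample(1:4, 5, replace = TRUE), ]
    w <- ns$init_weights(6, 3, 4, growth = 4, seed = 2)
    act <- ns$forward_pass(w, Xi, Xf)
    g <- ns$backward_pass(w, act, Xf, Y)
    for (nm in names(g)) {
      wn <- w
      for (k in sample(seq_along(w[[nm]]), min(5, length(w[[nm]])))) {
        eps <- 1e-6
        wn[[nm]] <- w[[nm]]; wn[[nm]][k] <- w[[nm]][k] + eps
        up <- ns$cross_entropy(ns$forward_pass(wn, Xi, Xf)$P, Y)
        wn[[nm]][k] <- w[[nm]][k] - eps
        dn <- ns$cross_entropy(ns$forward_pass(wn, Xi, Xf)$P, Y)
        expect_equal(g[[nm]][k], (up - dn) / (2 * eps), tolerance = 1e-5)
      }
    }
  })
})

test_that("training learns a separable feature-only task to 100%", {
  d <- make_split_features(15, sep = 4, seed = 3)
  cfg <- train_config(learning_rate = 0.05, batch_size = 16, dropout = 0.1,
                      max_epochs = 50, patience = 50, seed = 1)
  clf <- train_classifier(as.matrix(d$train[, -(1:2)]), d$train$label,
                          as.matrix(d$test[, -(1:2)]), d$test$label, cfg)
  expect_equal(max(clf$history$train_acc), 1)
  expect_lte(nrow(clf$history), 50)
  # loss goes down over training
  expect_lt(clf$history$train_loss[nrow(clf$history)],
            clf$history$train_loss[1])
})

test_that("early stopping halts within patience of the best epoch", {
  d <- make_split_features(15, sep = 2, seed = 5)
  cfg <- train_config(learning_rate = 0.05, batch_size = 16, dropout = 0.2,
                      max_epochs = 100, patience = 5, seed = 2)
  clf <- train_classifier(as.matrix(d$train[, -(1:2)]), d$train$label,
                          as.matrix(d$test[, -(1:2)]), d$test$label, cfg)
  n_epochs <- nrow(clf$history)
  if (n_epochs < 100)
    expect_lte(n_epochs, clf$best_epoch + 5)
  expect_equal(clf$history$val_loss[clf$best_epoch],
               min(clf$history$val_loss))
})

test_that("fixed seed reproduces training bit-for-bit", {
  d <- make_split_features(10, seed = 7)
  cfg <- train_config(max_epochs = 5, batch_size = 8, seed = 9)
  run <- function() train_classifier(as.matrix(d$train[, -(1:2)]),
                                     d$train$label,
                                     as.matrix(d$test[, -(1:2)]),
                                     d$test$label, cfg)
  expect_identical(serialize(run(), NULL), serialize(run(), NULL))
})

test_that("the pretrained backbone mode fails with guidance", {
  d <- make_split_features(8)
  cfg <- train_config(backbone = "densenet121_pretrained", max_epochs = 2)
  expect_error(train_classifier(as.matrix(d$train[, -(1:2)]), d$train$label,
                                as.matrix(d$test[, -(1:2)]), d$test$label,
                                cfg),
               "tiny_dense")
})

test_that("cross-validation partitions rows and refits fusion per fold", {
  tb <- synthetic_feature_table(15, seed = 11)
  cfg <- train_config(learning_rate = 0.05, max_epochs = 3, batch_size = 16,
                      dropout = 0.2, seed = 4)
  cv <- crossvalidate(tb, cfg, k = 3, n_components = 5)
  expect_length(cv$reports, 3)
  # every row held out exactly once
  expect_equal(sort(unique(cv$fold_assignment)), 1:3)
  expect_equal(sum(vapply(cv$reports, function(r) r$n, numeric(1))), nrow(tb))
  # per-fold fusion models differ on heterogeneous data
  blobs <- lapply(cv$reports, function(r) serialize(r$fusion_model, NULL))
  expect_false(identical(blobs[[1]], blobs[[2]]))
  expect_false(identical(blobs[[2]], blobs[[3]]))
  expect_equal(nrow(cv$summary), 3)
})

test_that("history tidiers and plots expose the training record", {
  d <- make_split_features(8)
  cfg <- train_config(max_epochs = 4, batch_size = 8, seed = 1)
  clf <- train_classifier(as.matrix(d$train[, -(1:2)]), d$train$label,
                          as.matrix(d$test[, -(1:2)]), d$test$label, cfg)
  td <- tidy(clf)
  expect_true(all(c("epoch", "train_loss", "val_acc") %in% names(td)))
  gl <- glance(clf)
  expect_equal(gl$epochs, nrow(td))
  expect_s3_class(autoplot(clf), "ggplot")
})
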