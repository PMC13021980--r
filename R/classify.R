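#' Training configuration for the classifier head
#'
#' Defaults follow the pipeline's training protocol: Adam with initial
#' learning rate 0.001, mini-batches of 64 with per-epoch shuffling, dropout
#' 0.5 before the final dense layer, categorical cross-entropy loss, and
#' early stopping with a validation patience of 5 epochs (best-validation
#' weights restored).  `max_epochs` caps training at 100 epochs.
#'
#' The `tiny_dense` backbone is a small densely-connected network on the
#' pooled image: three dense blocks in which every block receives the
#' concatenation of the pooled input and all previous block outputs,
#' emitting `growth` units each; the concatenated block outputs form the
#' deep-feature vector that is fused with the PCA-optimized descriptor
#' vector ahead of the dropout + softmax head.  The
#' `densenet121_pretrained` mode requires pretrained convolutional weights,
#' which this package does not ship; requesting it raises an error that
#' points at `tiny_dense`.
#'
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param dropout dropout rate in (0, 1) applied before the final layer.
#' @param patience early-stopping patience in epochs.
#' @param max_epochs maximum number of epochs.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @param backbone `"tiny_dense"` or `"densenet121_pretrained"`.
#' @param growth units per dense block of the tiny_dense image branch.
#' @param pool_side side of the average-pooled image fed to the image branch.
#' @param shuffle reshuffle the training rows every epoch?
#' @return a list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 64,
                         dropout = 0.5, patience = 5, max_epochs = 100,
                         seed = 1,
                         backbone = c("tiny_dense", "densenet121_pretrained"),
                         growth = 16, pool_side = 16, shuffle = TRUE) {
  backbone <- match.arg(backbone)
  if (dropout <= 0 || dropout >= 1) abort("`dropout` must be in (0, 1).")
  if (batch_size < 1) abort("`batch_size` must be at least 1.")
  if (patience < 1) abort("`patience` must be at least 1.")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 dropout = dropout, patience = patience,
                 max_epochs = max_epochs, seed = seed, backbone = backbone,
                 growth = growth, pool_side = pool_side, shuffle = shuffle),
            class = "train_config")
}

tumor_classes <- c("glioma", "meningioma", "pituitary", "no_tumor")

relu <- function(x) x * (x > 0)

softmax_rows <- function(L) {
  e <- exp(L - apply(L, 1, max))
  e / rowSums(e)
}

# He-initialized weight list for the two-branch model.  n_image_inputs = 0
# drops the image branch (feature-only head).
init_weights <- function(n_image_inputs, n_feature_inputs, n_classes,
                         growth, seed) {
  with_local_seed(seed, {
    he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                     nin, nout)
    w <- list()
    head_in <- n_feature_inputs
    if (n_image_inputs > 0) {
      d0 <- n_image_inputs
      w$W1 <- he(d0, growth);               w$b1 <- numeric(growth)
      w$W2 <- he(d0 + growth, growth);      w$b2 <- numeric(growth)
      w$W3 <- he(d0 + 2 * growth, growth);  w$b3 <- numeric(growth)
      head_in <- head_in + 3 * growth
    }
    w$Wh <- he(head_in, n_classes)
    w$bh <- numeric(n_classes)
    w
  })
}

# Forward pass.  `drop_mask` (same shape as the head input) enables
# inverted dropout; NULL = evaluation mode.  Returns activations needed by
# the backward pass.
forward_pass <- function(w, X_img, X_feat, dropout = 0, drop_mask = NULL) {
  act <- list()
  parts <- list()
  if (!is.null(w$W1)) {
    Z0 <- X_img
    act$A1 <- sweep(Z0 %*% w$W1, 2, w$b1, `+`);            act$H1 <- relu(act$A1)
    act$Z1 <- cbind(Z0, act$H1)
    act$A2 <- sweep(act$Z1 %*% w$W2, 2, w$b2, `+`);        act$H2 <- relu(act$A2)
    act$Z2 <- cbind(act$Z1, act$H2)
    act$A3 <- sweep(act$Z2 %*% w$W3, 2, w$b3, `+`);        act$H3 <- relu(act$A3)
    parts$img <- cbind(act$H1, act$H2, act$H3)
    act$Z0 <- Z0
  }
  Fh <- if (is.null(parts$img)) X_feat else cbind(parts$img, X_feat)
  if (!is.null(drop_mask)) Fh <- Fh * drop_mask / (1 - dropout)
  act$Fh <- Fh
  act$P <- softmax_rows(sweep(Fh %*% w$Wh, 2, w$bh, `+`))
  act
}

cross_entropy <- function(P, Y) -mean(rowSums(Y * log(pmax(P, 1e-12))))

# Gradients of the mean cross-entropy w.r.t. every weight.
backward_pass <- function(w, act, X_feat, Y, dropout = 0, drop_mask = NULL) {
  n <- nrow(Y)
  dL <- (act$P - Y) / n
  g <- list(Wh = t(act$Fh) %*% dL, bh = colSums(dL))
  dF <- dL %*% t(w$Wh)
  if (!is.null(drop_mask)) dF <- dF * drop_mask / (1 - dropout)
  if (is.null(w$W1)) return(g)
  gr <- ncol(w$W1)
  d0 <- ncol(act$Z0)
  dH1 <- dF[, 1:gr, drop = FALSE]
  dH2 <- dF[, gr + 1:gr, drop = FALSE]
  dH3 <- dF[, 2 * gr + 1:gr, drop = FALSE]

  dA3 <- dH3 * (act$A3 > 0)
  g$W3 <- t(act$Z2) %*% dA3; g$b3 <- colSums(dA3)
  dZ2 <- dA3 %*% t(w$W3)
  dH2 <- dH2 + dZ2[, d0 + gr + 1:gr, drop = FALSE]
  dZ1_acc <- dZ2[, 1:(d0 + gr), drop = FALSE]

  dA2 <- dH2 * (act$A2 > 0)
  g$W2 <- t(act$Z1) %*% dA2; g$b2 <- colSums(dA2)
  dZ1_acc <- dZ1_acc + dA2 %*% t(w$W2)
  dH1 <- dH1 + dZ1_acc[, d0 + 1:gr, drop = FALSE]

  dA1 <- dH1 * (act$A1 > 0)
  g$W1 <- t(act$Z0) %*% dA1; g$b1 <- colSums(dA1)
  g
}

#' Train the fusion classifier head
#'
#' Mini-batch Adam on categorical cross-entropy over the four tumor classes,
#' with per-epoch shuffling, inverted dropout before the final dense layer,
#' and patience-based early stopping on the validation loss (the weights of
#' the best validation epoch are restored).  Inputs are the PCA-optimized
#' descriptor vectors and, unless `train_images` is `NULL`, the pooled image
#' matrix consumed by the tiny_dense image branch.
#'
#' @param train_features numeric matrix of optimized feature vectors
#'   (rows = samples).
#' @param train_labels character/factor labels among the four classes.
#' @param val_features,val_labels held-out validation inputs used only for
#'   early stopping (disjoint from the training rows).
#' @param cfg a [train_config()].
#' @param train_images,val_images optional pooled image matrices (see
#'   [pool_images()]); `NULL` trains a feature-only head.
#' @param class_order fixed class order serialized with the model.
#' @return an object of class `"texture_classifier"`: weights, `class_order`,
#'   input contract (`n_feature_inputs`, `n_image_inputs`), `history`
#'   (per-epoch tibble), `best_epoch`, `cfg`.
#' @export
train_classifier <- function(train_features, train_labels,
                             val_features, val_labels,
                             cfg = train_config(),
                             train_images = NULL, val_images = NULL,
                             class_order = tumor_classes) {
  if (cfg$backbone == "densenet121_pretrained")
    abort(paste("backbone 'densenet121_pretrained' needs pretrained",
                "convolutional weights, which are not bundled;",
                "use backbone = 'tiny_dense'."))
  train_features <- as.matrix(train_features)
  val_features <- as.matrix(val_features)
  if (nrow(train_features) == 0 || nrow(val_features) == 0)
    abort("empty training or validation set.")
  bad <- setdiff(unique(c(train_labels, val_labels)), class_order)
  if (length(bad) > 0)
    abort(sprintf("labels outside the class set: %s", paste(bad, collapse = ", ")))
  one_hot <- function(lab) {
    Y <- matrix(0, length(lab), length(class_order))
    Y[cbind(seq_along(lab), match(lab, class_order))] <- 1
    Y
  }
  Ytr <- one_hot(train_labels); Yva <- one_hot(val_labels)
  n_img <- if (is.null(train_images)) 0L else ncol(train_images)

  w <- init_weights(n_img, ncol(train_features), length(class_order),
                    cfg$growth, derive_seed(cfg$seed, 11))
  mom <- purrr::map(w, ~ .x * 0); vel <- mom; t_step <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  n <- nrow(train_features)
  best <- list(loss = Inf, epoch = 0L, w = w)
  hist <- vector("list", cfg$max_epochs)
  with_local_seed(derive_seed(cfg$seed, 13), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- if (cfg$shuffle) sample.int(n) else seq_len(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1, n)]
        Xf <- train_features[idx, , drop = FALSE]
        Xi <- if (n_img > 0) train_images[idx, , drop = FALSE] else NULL
        head_dim <- ncol(Xf) + if (n_img > 0) 3 * cfg$growth else 0
        mask <- matrix(runif(length(idx) * head_dim) >= cfg$dropout,
                       length(idx), head_dim)
        act <- forward_pass(w, Xi, Xf, cfg$dropout, mask)
        g <- backward_pass(w, act, Xf, Ytr[idx, , drop = FALSE],
                           cfg$dropout, mask)
        t_step <- t_step + 1
        for (nm in names(g)) {
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1^t_step)
          vhat <- vel[[nm]] / (1 - b2^t_step)
          w[[nm]] <- w[[nm]] - cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      eval_split <- function(Xf, Xi, Y) {
        P <- forward_pass(w, Xi, Xf)$P
        c(loss = cross_entropy(P, Y),
          acc = mean(max.col(P, ties.method = "first") == max.col(Y)))
      }
      tr <- eval_split(train_features,
                       if (n_img > 0) train_images else NULL, Ytr)
      va <- eval_split(val_features,
                       if (n_img > 0) val_images else NULL, Yva)
      hist[[epoch]] <- tibble(epoch = epoch,
                              train_loss = tr[["loss"]], train_acc = tr[["acc"]],
                              val_loss = va[["loss"]], val_acc = va[["acc"]])
      if (va["loss"] < best$loss - 1e-9) {
        best <- list(loss = va["loss"], epoch = epoch, w = w)
      } else if (epoch - best$epoch >= cfg$patience) break
    }
  })
  structure(list(weights = best$w, class_order = class_order,
                 n_feature_inputs = ncol(train_features),
                 n_image_inputs = n_img,
                 history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch, cfg = cfg),
            class = "texture_classifier")
}

#' Predict class probabilities and labels
#'
#' Evaluation-mode forward pass: dropout disabled, deterministic, row order
#' equivariant.  Argmax ties are broken toward the lowest class index.
#'
#' @param object a [train_classifier()] model.
#' @param features numeric matrix of optimized feature vectors.
#' @param images pooled image matrix when the model has an image branch.
#' @param ... unused.
#' @return tibble with `.pred_class` and one `.prob_<class>` column per
#'   class; probabilities sum to 1 per row.
#' @export
predict.texture_classifier <- function(object, features, images = NULL, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$n_feature_inputs)
    abort(sprintf("feature vector length %d does not match the model's %d.",
                  ncol(features), object$n_feature_inputs))
  if (object$n_image_inputs > 0) {
    if (is.null(images) || ncol(images) != object$n_image_inputs)
      abort("this model needs pooled images with matching dimensionality.")
  }
  P <- forward_pass(object$weights,
                    if (object$n_image_inputs > 0) images else NULL,
                    features)$P
  colnames(P) <- paste0(".prob_", object$class_order)
  cls <- object$class_order[max.col(P, ties.method = "first")]
  dplyr::bind_cols(tibble(.pred_class = cls), as_tibble(P))
}

#' @export
print.texture_classifier <- function(x, ...) {
  cat(sprintf(
    "texture_classifier: %s backbone, %d feature + %d image inputs, best epoch %d\n",
    x$cfg$backbone, x$n_feature_inputs, x$n_image_inputs, x$best_epoch))
  invisible(x)
}

#' @describeIn train_classifier per-epoch training history.
#' @param x a `texture_classifier`.
#' @export
tidy.texture_classifier <- function(x, ...) x$history

#' @describeIn train_classifier one-row summary (epochs run, best epoch,
#'   best validation loss/accuracy).
#' @export
glance.texture_classifier <- function(x, ...) {
  h <- x$history
  tibble(epochs = nrow(h), best_epoch = x$best_epoch,
         best_val_loss = h$val_loss[x$best_epoch],
         best_val_acc = h$val_acc[x$best_epoch])
}

#' Training-history curves
#'
#' @param object a `texture_classifier`.
#' @param ... unused.
#' @return a ggplot of loss and accuracy per epoch for train and validation.
#' @export
autoplot.texture_classifier <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  color = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}

#' Stratified k-fold cross-validation with per-fold fusion refits
#'
#' Partitions the rows into `k` stratified folds; for every fold, the
#' standardization + PCA fusion model is refitted on the other `k - 1` folds
#' only (extending the leakage contract to cross-validation), a classifier
#' is trained with an inner stratified validation split for early stopping,
#' and the held-out fold is scored.  Intended to run inside the training
#' portion of an outer 80/20 split, leaving the final test set untouched.
#'
#' @param features feature tibble (`path`, `label`, descriptor columns).
#' @param cfg a [train_config()].
#' @param k number of folds (default 10).
#' @param n_components PCA components for the per-fold fusion model.
#' @param images optional pooled image matrix aligned with `features` rows.
#' @param inner_val_fraction fraction of each fold-training set held out for
#'   early stopping.
#' @return list with `reports` (per-fold [eval_report] objects), `summary`
#'   (tibble of per-fold accuracy and macro F1 with mean and sd), and
#'   `fold_assignment`.
#' @export
crossvalidate <- function(features, cfg = train_config(), k = 10,
                          n_components = 249, images = NULL,
                          inner_val_fraction = 0.15) {
  if (k < 2) abort("`k` must be at least 2.")
  lab <- features$label
  if (any(table(lab) < k))
    abort("every class needs at least `k` members for stratified folds.")
  fold <- integer(nrow(features))
  with_local_seed(derive_seed(cfg$seed, 17), {
    for (cl in unique(lab)) {
      idx <- sample(which(lab == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  reports <- purrr::map(seq_len(k), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    fm <- fit_fusion_model(features[tr, ], n_components = n_components)
    inner <- stratified_split(features[tr, ], 1 - inner_val_fraction,
                              seed = derive_seed(cfg$seed, 19, f))
    fit_idx <- tr[inner$split == "train"]; val_idx <- tr[inner$split == "test"]
    clf <- train_classifier(
      apply_fusion_model(fm, features[fit_idx, ]), lab[fit_idx],
      apply_fusion_model(fm, features[val_idx, ]), lab[val_idx],
      cfg = cfg,
      train_images = if (!is.null(images)) images[fit_idx, , drop = FALSE],
      val_images = if (!is.null(images)) images[val_idx, , drop = FALSE])
    pr <- predict(clf, apply_fusion_model(fm, features[te, ]),
                  images = if (!is.null(images)) images[te, , drop = FALSE])
    rep <- evaluate_predictions(lab[te], pr)
    rep$fusion_model <- fm
    rep
  })
  summary <- dplyr::bind_rows(purrr::imap(reports, function(r, f)
    tibble(fold = f, accuracy = r$accuracy, macro_f1 = r$macro$f1)))
  list(reports = reports, summary = summary, fold_assignment = fold)
}
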