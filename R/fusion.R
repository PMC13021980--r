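#' Stratified train/test split
#'
#' Splits a labeled manifest into train and test sets per class, with the
#' per-class training count equal to round-half-up of
#' `train_fraction * n_class` and deterministic sampling under `seed`.  With
#' a `group_by` column (e.g. subject id) no group spans both sets: whole
#' groups are assigned to the training set in shuffled order until the
#' per-class target is reached as closely as possible (a warning reports any
#' unattainable exact count).
#'
#' @param manifest tibble with a `label` column (and optionally the grouping
#'   column).
#' @param train_fraction fraction of each class assigned to training.
#' @param seed integer seed.
#' @param group_by optional name of a grouping column.
#' @return the manifest with an added `split` column (`"train"` / `"test"`).
#' @examples
#' m <- tibble::tibble(path = as.character(1:10), label = rep("a", 10))
#' table(stratified_split(m, seed = 1)$split)
#' @export
stratified_split <- function(manifest, train_fraction = 0.8, seed = 1,
                             group_by = NULL) {
  if (!"label" %in% names(manifest)) abort("`manifest` needs a `label` column.")
  if (train_fraction <= 0 || train_fraction >= 1)
    abort("`train_fraction` must be in (0, 1).")
  split <- character(nrow(manifest))
  with_local_seed(derive_seed(seed, 971), {
    for (cl in unique(manifest$label)) {
      idx <- which(manifest$label == cl)
      n_train <- floor(train_fraction * length(idx) + 0.5) # round half up
      if (is.null(group_by)) {
        tr <- sample(idx, n_train)
      } else {
        grp <- manifest[[group_by]][idx]
        gs <- sample(unique(grp))
        tr <- integer(0)
        for (g in gs) {
          mem <- idx[grp == g]
          if (length(tr) + length(mem) <= n_train ||
              abs(length(tr) + length(mem) - n_train) < abs(length(tr) - n_train))
            tr <- c(tr, mem)
          if (length(tr) >= n_train) break
        }
        if (length(tr) != n_train)
          warn(sprintf(
            "class '%s': group constraint allows %d training rows, not %d.",
            cl, length(tr), n_train))
      }
      split[idx] <- "test"
      split[tr] <- "train"
    }
  })
  manifest[["split"]] <- split # direct assignment: input may already carry a split column
  manifest
}

#' Fuse descriptor feature tables
#'
#' Column-binds per-descriptor feature tables in the fixed order GLCM, LTP,
#' CCV (restricted to `combo`), checking that rows align by `path`.  Tables
#' produced by [extract_features()] already carry prefixed column names, so
#' fusion is a keyed join plus column selection.
#'
#' @param features either one table holding all descriptor columns, or a
#'   named list of tables (names among `glcm`, `ltp`, `ccv`), each with
#'   `path` and `label`.
#' @param combo character subset of `c("glcm", "ltp", "ccv")`.
#' @return tibble: `path`, `label`, then the selected descriptor columns in
#'   combo-fixed order.
#' @export
fuse_features <- function(features, combo = c("glcm", "ltp", "ccv")) {
  combo <- match.arg(combo, c("glcm", "ltp", "ccv"), several.ok = TRUE)
  combo <- intersect(c("glcm", "ltp", "ccv"), combo) # fixed order
  if (is.data.frame(features)) {
    keep <- purrr::map(combo, ~ names(features)[startsWith(names(features),
                                                           paste0(.x, "_"))])
    missing <- combo[lengths(keep) == 0]
    if (length(missing) > 0)
      abort(sprintf("no columns found for descriptor(s): %s",
                    paste(missing, collapse = ", ")))
    return(dplyr::select(features, dplyr::all_of(c("path", "label",
                                                   unlist(keep)))))
  }
  if (!all(combo %in% names(features)))
    abort("`features` list must have tables named after the combo members.")
  out <- features[[combo[1]]]
  for (d in combo[-1]) {
    tb <- features[[d]]
    if (!identical(out$path, tb$path))
      abort("descriptor tables are not row-aligned by `path`.")
    out <- dplyr::bind_cols(out, dplyr::select(tb, -dplyr::any_of(c("path", "label"))))
  }
  out
}

#' Fit the standardization + PCA fusion model (training rows only)
#'
#' Learns per-column z-score parameters and a PCA basis from the training
#' feature rows, and nothing else — this is the leakage boundary: the fitted
#' model is a pure function of its input table.  Constant columns are dropped
#' with a warning.  PCA is computed by singular value decomposition of the
#' standardized matrix; each component's sign is fixed so its
#' largest-magnitude loading is positive, making the basis deterministic.
#' The number of components kept is `min(n_components, rank)`; alternatively
#' `var_retain` keeps the smallest count reaching that fraction of total
#' variance.
#'
#' @param train_features tibble of training rows from [fuse_features()] /
#'   [extract_features()] (non-feature columns `path`, `label`, `split` are
#'   ignored).
#' @param n_components target component count (default 249).
#' @param var_retain optional variance-retention fraction in (0, 1]; when
#'   given, overrides `n_components`.
#' @return an object of class `"fusion_model"`: list with `combo_columns`,
#'   `kept_columns`, `center`, `scale`, `rotation` (columns = components),
#'   `explained_variance`, `n_components`.
#' @export
fit_fusion_model <- function(train_features, n_components = 249,
                             var_retain = NULL) {
  X <- feature_matrix(train_features)
  if (nrow(X) < 2) abort("need at least 2 training rows to fit PCA.")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- scl > 0
  if (any(!keep))
    warn(sprintf("dropping %d constant feature column(s).", sum(!keep)))
  if (!any(keep)) abort("all feature columns are constant.")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-12)
  k <- if (!is.null(var_retain)) {
    if (var_retain <= 0 || var_retain > 1) abort("`var_retain` must be in (0, 1].")
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    max(1L, which(cum >= var_retain)[1])
  } else {
    if (n_components < 1) abort("`n_components` must be at least 1.")
    min(n_components, rank)
  }
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, "*")
  structure(list(
    combo_columns = colnames(X), kept_columns = colnames(X)[keep],
    center = ctr[keep], scale = scl[keep], rotation = rot,
    explained_variance = pc$sdev[seq_len(k)]^2,
    total_variance = sum(pc$sdev^2), n_components = k
  ), class = "fusion_model")
}

#' Project features through a fitted fusion model
#'
#' Standardizes with the model's training means/sds and projects onto its
#' PCA basis.  Never refits: applying the model to any table, including the
#' test set, leaves the model untouched.
#'
#' @param model a [fit_fusion_model()] object.
#' @param features tibble with the same feature columns the model was
#'   fitted on.
#' @return numeric matrix, one row per input row, `model$n_components`
#'   columns named `PC1, PC2, ...`.
#' @export
apply_fusion_model <- function(model, features) {
  if (!inherits(model, "fusion_model")) abort("`model` must be a fusion_model.")
  X <- feature_matrix(features)
  if (!all(model$kept_columns %in% colnames(X)))
    abort("`features` is missing columns the model was fitted on.")
  X <- X[, model$kept_columns, drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  scores <- Xs %*% model$rotation
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

# Numeric feature matrix from a feature tibble (drops bookkeeping columns).
feature_matrix <- function(features) {
  drop <- intersect(c("path", "label", "split", "image"), names(features))
  X <- as.matrix(dplyr::select(features, -dplyr::all_of(drop)))
  if (!is.numeric(X)) abort("feature columns must be numeric.")
  X
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("Fusion model: %d features -> %d components (%.1f%% variance)\n",
              length(x$kept_columns), x$n_components,
              100 * sum(x$explained_variance) / x$total_variance))
  invisible(x)
}

#' @describeIn fit_fusion_model one row per component: sdev, variance,
#'   proportion and cumulative proportion of variance explained.
#' @param x a `fusion_model`.
#' @param ... unused.
#' @export
tidy.fusion_model <- function(x, ...) {
  tibble(component = seq_len(x$n_components),
         std_dev = sqrt(x$explained_variance),
         variance = x$explained_variance,
         prop_variance = x$explained_variance / x$total_variance,
         cum_variance = cumsum(x$explained_variance) / x$total_variance)
}

#' @describeIn fit_fusion_model one-row model summary.
#' @export
glance.fusion_model <- function(x, ...) {
  tibble(n_features = length(x$combo_columns),
         n_kept = length(x$kept_columns),
         n_components = x$n_components,
         var_retained = sum(x$explained_variance) / x$total_variance)
}
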