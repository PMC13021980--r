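#' Run the full pipeline end to end
#'
#' Orchestrates the stages: phantom generation (or a user manifest) →
#' preprocessing → K-means ROI segmentation → descriptor extraction →
#' stratified 80/20 split → per-combo standardization + PCA fusion fitted on
#' training rows only → classifier training (inner validation split for
#' early stopping) → evaluation on the untouched test rows.  All stage seeds
#' derive deterministically from the single run seed, so a rerun with the
#' same arguments reproduces the same report.
#'
#' @param manifest labeled image manifest (`path`, `label`, optional
#'   `image` list-column); `NULL` generates phantoms.
#' @param n_per_class phantoms per class when generating.
#' @param image_side image side in pixels.
#' @param seed run seed; every stochastic stage derives its own seed from it.
#' @param combos list of descriptor combinations to fuse and evaluate;
#'   each a subset of `c("glcm", "ltp", "ccv")`.
#' @param n_components PCA components for the fusion model.
#' @param train_fraction outer split fraction.
#' @param cfg a [train_config()]; its seed is re-derived from `seed`.
#' @param use_images feed the pooled image branch alongside the optimized
#'   feature vector?
#' @param inner_val_fraction fraction of the training rows held out for
#'   early stopping.
#' @param fidelity_sample number of images on which segmentation fidelity
#'   (PSNR/RMSE) is scored for the run record.
#' @param out_dir optional directory; when given, `features.csv`,
#'   `split.csv`, per-combo `history_<combo>.csv` and a byte-stable
#'   `report.json` are written there.
#' @param ... forwarded to [extract_features()] (descriptor parameters).
#' @return an object of class `"pipeline_result"`: `reports` (named per-combo
#'   [evaluate_predictions()] objects), `fusion_models`, `classifiers`,
#'   `split` (tibble `path,label,split`), `fidelity` (tibble), `seed`,
#'   `combos`.
#' @examples
#' \donttest{
#' res <- run_pipeline(n_per_class = 8, image_side = 64, seed = 1,
#'                     cfg = train_config(max_epochs = 5, batch_size = 16))
#' glance(res$reports[[1]])
#' }
#' @export
run_pipeline <- function(manifest = NULL, n_per_class = 20, image_side = 128,
                         seed = 1, combos = list(c("glcm", "ltp", "ccv")),
                         n_components = 249, train_fraction = 0.8,
                         cfg = train_config(), use_images = TRUE,
                         inner_val_fraction = 0.15, fidelity_sample = 8,
                         out_dir = NULL, ...) {
  if (!is.list(combos)) combos <- list(combos)
  if (is.null(manifest))
    manifest <- generate_dataset(n_per_class, image_side,
                                 seed = derive_seed(seed, 1))
  needed <- Reduce(union, combos)
  target_side <- min(image_side, 128)

  features <- extract_features(manifest, descriptors = needed,
                               target_side = target_side,
                               seed = derive_seed(seed, 2), ...)
  split_tbl <- stratified_split(features, train_fraction,
                                seed = derive_seed(seed, 3))
  pooled <- if (use_images)
    pool_images(manifest, target_side = target_side,
                pool_side = if (target_side %% 16 == 0) 16 else 8)

  # segmentation fidelity record on a deterministic subsample
  fid_idx <- unique(round(seq(1, nrow(manifest),
                              length.out = min(fidelity_sample, nrow(manifest)))))
  has_mem <- "image" %in% names(manifest)
  fidelity <- dplyr::bind_rows(purrr::map(fid_idx, function(i) {
    img <- if (has_mem) manifest$image[[i]] else read_gray(manifest$path[i])
    pre <- preprocess_image(img, target_side)
    seg <- kmeans_segment(pre, k = 4, seed = derive_seed(seed, 2, i))
    dplyr::bind_cols(tibble(path = manifest$path[i]),
                     segmentation_fidelity(pre, seg))
  }))

  tr <- which(split_tbl$split == "train"); te <- which(split_tbl$split == "test")
  inner <- stratified_split(split_tbl[tr, ], 1 - inner_val_fraction,
                            seed = derive_seed(seed, 4))
  fit_idx <- tr[inner$split == "train"]; val_idx <- tr[inner$split == "test"]

  run_combo <- function(combo) {
    fused <- fuse_features(features, combo)
    fm <- fit_fusion_model(fused[fit_idx, ], n_components = n_components)
    cfg_run <- cfg; cfg_run$seed <- derive_seed(seed, 5)
    clf <- train_classifier(
      apply_fusion_model(fm, fused[fit_idx, ]), fused$label[fit_idx],
      apply_fusion_model(fm, fused[val_idx, ]), fused$label[val_idx],
      cfg = cfg_run,
      train_images = if (use_images) pooled[fit_idx, , drop = FALSE],
      val_images = if (use_images) pooled[val_idx, , drop = FALSE])
    pr <- predict(clf, apply_fusion_model(fm, fused[te, ]),
                  images = if (use_images) pooled[te, , drop = FALSE])
    list(fm = fm, clf = clf,
         report = evaluate_predictions(fused$label[te], pr))
  }
  combo_names <- vapply(combos, paste, character(1), collapse = "+")
  runs <- purrr::map(combos, run_combo)
  names(runs) <- combo_names

  res <- structure(list(
    reports = purrr::map(runs, "report"),
    fusion_models = purrr::map(runs, "fm"),
    classifiers = purrr::map(runs, "clf"),
    split = dplyr::select(split_tbl, dplyr::all_of(c("path", "label", "split"))),
    fidelity = fidelity, seed = seed, combos = combos
  ), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_artifacts(res, features, out_dir)
  res
}

# Serialize the run's tabular artifacts plus a byte-stable JSON report
# (sorted keys, fixed digits) under out_dir.
write_pipeline_artifacts <- function(res, features, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(res$split, file.path(out_dir, "split.csv"), row.names = FALSE)
  write.csv(res$fidelity, file.path(out_dir, "fidelity.csv"), row.names = FALSE)
  for (nm in names(res$classifiers))
    write.csv(res$classifiers[[nm]]$history,
              file.path(out_dir, sprintf("history_%s.csv", gsub("\\+", "_", nm))),
              row.names = FALSE)
  report <- purrr::map(res$reports, function(r) {
    out <- list(accuracy = round(r$accuracy, 10),
                macro = purrr::map(as.list(r$macro), round, 10),
                per_class = purrr::map(
                  split(r$per_class, r$per_class$class),
                  ~ purrr::map(as.list(dplyr::select(.x, -dplyr::any_of(c("class", "undefined")))),
                               round, 10)),
                confusion = unclass(r$confusion))
    if (!is.null(r$roc)) out$auc <- purrr::map(as.list(r$roc$auc), round, 10)
    out
  })
  report <- report[order(names(report))]
  jsonlite::write_json(list(seed = res$seed, combos = names(res$reports),
                            results = report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %s): %d images, combos: %s\n", x$seed,
              nrow(x$split), paste(names(x$reports), collapse = "; ")))
  for (nm in names(x$reports)) {
    r <- x$reports[[nm]]
    cat(sprintf("  %-14s accuracy %.4f  macro F1 %.4f\n", nm,
                r$accuracy, r$macro$f1))
  }
  invisible(x)
}

#' @describeIn run_pipeline per-combo, per-class metric table (see
#'   [report_tables()]).
#' @param x a `pipeline_result`.
#' @param ... unused.
#' @export
tidy.pipeline_result <- function(x, ...) report_tables(x$reports)

#' @describeIn run_pipeline one row per combo: test accuracy and macro
#'   metrics.
#' @export
glance.pipeline_result <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$reports, function(r, nm)
    dplyr::bind_cols(tibble(combo = nm), glance(r))))
}
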