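#' Confusion matrix over the fixed class order
#'
#' `counts[i, j]` is the number of samples whose true class is `i` and
#' predicted class is `j`.
#'
#' @param true_labels,pred_labels equal-length label vectors over `classes`.
#' @param classes class order (rows and columns).
#' @return an integer matrix of class `"confusion_matrix"` with dimnames
#'   `true` x `predicted`.
#' @export
confusion <- function(true_labels, pred_labels, classes = tumor_classes) {
  if (length(true_labels) != length(pred_labels))
    abort("label vectors must have equal length.")
  bad <- setdiff(unique(c(true_labels, pred_labels)), classes)
  if (length(bad) > 0)
    abort(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  cm <- table(factor(true_labels, levels = classes),
              factor(pred_labels, levels = classes))
  out <- matrix(as.integer(cm), length(classes), length(classes),
                dimnames = list(true = classes, predicted = classes))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Confusion-matrix classification metrics
#'
#' Overall accuracy is the matrix trace over the total.  Per class
#' (one-vs-rest): precision = TP/(TP+FP), recall = sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), per-class accuracy = (TP+TN)/total, and
#' F1 = 2PR/(P+R).  Degenerate 0/0 rates are reported as 0 and flagged in
#' the `undefined` column.  Macro averages are unweighted class means.
#'
#' @param cm a [confusion()] matrix.
#' @return list of class `"eval_metrics"`: `accuracy`, `per_class` tibble
#'   (class, accuracy, precision, recall, sensitivity, specificity, f1,
#'   undefined), `macro` (one-row tibble).
#' @export
confusion_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) abort("`cm` must come from confusion().")
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix.")
  classes <- rownames(cm)
  per <- purrr::map(seq_along(classes), function(i) {
    tp <- cm[i, i]; fn <- sum(cm[i, -i]); fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    safe <- function(num, den) if (den == 0) 0 else num / den
    p <- safe(tp, tp + fp); r <- safe(tp, tp + fn)
    tibble(class = classes[i],
           accuracy = (tp + tn) / total,
           precision = p, recall = r, sensitivity = r,
           specificity = safe(tn, tn + fp),
           f1 = if (p + r == 0) 0 else 2 * p * r / (p + r),
           undefined = (tp + fp == 0) || (tp + fn == 0))
  })
  per <- dplyr::bind_rows(per)
  macro <- dplyr::summarise(per, dplyr::across(c("accuracy", "precision",
                                                 "recall", "sensitivity",
                                                 "specificity", "f1"), mean))
  structure(list(accuracy = sum(diag(cm)) / total, per_class = per,
                 macro = macro), class = "eval_metrics")
}

#' F1 score from precision and recall
#'
#' \eqn{F1 = 2 P R / (P + R)}; 0 when both are 0.  Accepts rates on
#' \code{[0,1]} or percentages (both arguments must use the same scale).
#'
#' @param precision,recall numeric vectors.
#' @return numeric vector on the same scale as the inputs.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps the thresholds over the unique predicted scores of
#' that class (equal scores grouped into a single operating point), computing
#' TPR against FPR, and integrates the AUC by the trapezoidal rule.  A class
#' absent from `true_labels` has no defined curve; its AUC is reported as
#' `NA`.
#'
#' @param true_labels label vector.
#' @param prob_matrix numeric matrix of row-normalized class probabilities,
#'   columns in `classes` order (the `.prob_*` columns of
#'   [predict.texture_classifier()] are accepted).
#' @param classes class order.
#' @return list with `curves` (tibble: class, fpr, tpr, threshold) and `auc`
#'   (named numeric).
#' @export
roc_auc <- function(true_labels, prob_matrix, classes = tumor_classes) {
  prob_matrix <- as.matrix(prob_matrix)
  colnames(prob_matrix) <- sub("^\\.prob_", "", colnames(prob_matrix))
  if (is.null(colnames(prob_matrix))) colnames(prob_matrix) <- classes
  curves <- list(); auc <- setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    pos <- true_labels == cl
    if (!any(pos) || all(pos)) next
    s <- prob_matrix[, cl]
    ord <- order(s, decreasing = TRUE)
    s_ord <- s[ord]; pos_ord <- pos[ord]
    grp_last <- c(s_ord[-1] != s_ord[-length(s_ord)], TRUE)
    tp <- cumsum(pos_ord)[grp_last]; fp <- cumsum(!pos_ord)[grp_last]
    tpr <- c(0, tp / sum(pos)); fpr <- c(0, fp / sum(!pos))
    auc[cl] <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    curves[[cl]] <- tibble(class = cl, fpr = fpr, tpr = tpr,
                           threshold = c(Inf, s_ord[grp_last]))
  }
  list(curves = dplyr::bind_rows(curves), auc = auc)
}

#' Full evaluation report for one experiment
#'
#' Bundles the confusion matrix, scalar metrics and (when probabilities are
#' supplied) one-vs-rest ROC/AUC into a single report object.
#'
#' @param true_labels label vector.
#' @param predictions either the tibble returned by
#'   [predict.texture_classifier()] or a vector of predicted labels.
#' @param prob_matrix optional probability matrix when `predictions` is a
#'   label vector.
#' @param classes class order.
#' @return an object of class `"eval_report"`: `confusion`, `accuracy`,
#'   `per_class`, `macro`, `roc` (possibly `NULL`), `n`.
#' @export
evaluate_predictions <- function(true_labels, predictions,
                                 prob_matrix = NULL,
                                 classes = tumor_classes) {
  if (is.data.frame(predictions)) {
    prob_matrix <- as.matrix(dplyr::select(predictions,
                                           dplyr::starts_with(".prob_")))
    predictions <- predictions$.pred_class
  }
  cm <- confusion(true_labels, predictions, classes)
  m <- confusion_metrics(cm)
  roc <- if (!is.null(prob_matrix) && ncol(prob_matrix) == length(classes))
    roc_auc(true_labels, prob_matrix, classes) else NULL
  structure(list(confusion = cm, accuracy = m$accuracy,
                 per_class = m$per_class, macro = m$macro, roc = roc,
                 n = length(true_labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d samples: accuracy %.4f, macro F1 %.4f\n",
              x$n, x$accuracy, x$macro$f1))
  print(x$confusion)
  if (!is.null(x$roc))
    cat("AUC:", paste(sprintf("%s %.3f", names(x$roc$auc), x$roc$auc),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn evaluate_predictions per-class metric rows (plus AUC when
#'   available).
#' @param x an `eval_report`.
#' @param ... unused.
#' @export
tidy.eval_report <- function(x, ...) {
  out <- x$per_class
  if (!is.null(x$roc))
    out <- dplyr::left_join(out, tibble(class = names(x$roc$auc),
                                        auc = unname(x$roc$auc)),
                            by = "class")
  out
}

#' @describeIn evaluate_predictions one-row summary: n, accuracy, macro
#'   metrics.
#' @export
glance.eval_report <- function(x, ...) {
  dplyr::bind_cols(tibble(n = x$n, accuracy = x$accuracy),
                   dplyr::rename_with(x$macro, ~ paste0("macro_", .x)))
}

#' ROC curves of an evaluation report
#'
#' @param object an `eval_report` with ROC data.
#' @param ... unused.
#' @return a ggplot of the one-vs-rest ROC curves.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$roc)) abort("report has no ROC data (no probabilities).")
  ggplot2::ggplot(object$roc$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               color = .data$class)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap
#'
#' @param report an `eval_report`.
#' @return a ggplot tile plot of the confusion counts.
#' @export
plot_confusion <- function(report) {
  df <- as_tibble(as.table(unclass(report$confusion)))
  names(df) <- c("true", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::theme_minimal()
}

#' Side-by-side comparison table of evaluation reports
#'
#' Renders per-combo, per-class metric rows in the conventional column
#' layout (class, accuracy, precision, F1, sensitivity, specificity), with
#' the tri-fusion combo sorted last.
#'
#' @param reports named list of `eval_report` objects (names = combo labels,
#'   e.g. `"glcm+ltp+ccv"`).
#' @return tibble with columns `combo`, `class_no`, `class`, `accuracy`,
#'   `precision`, `f1_score`, `sensitivity`, `specificity`.
#' @export
report_tables <- function(reports) {
  if (length(reports) == 0) abort("need at least one report.")
  nm <- names(reports)
  n_desc <- vapply(strsplit(nm, "\\+"), length, integer(1))
  ord <- order(n_desc, nm)
  dplyr::bind_rows(purrr::map(ord, function(i) {
    pc <- reports[[i]]$per_class
    tibble(combo = nm[i], class_no = seq_len(nrow(pc)), class = pc$class,
           accuracy = pc$accuracy, precision = pc$precision,
           f1_score = pc$f1, sensitivity = pc$sensitivity,
           specificity = pc$specificity)
  }))
}
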