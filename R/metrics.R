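#' Confusion matrix for multi-class predictions
#'
#' Rows index the true class, columns the predicted class:
#' `counts[a, b]` is the number of samples of true class a predicted as b.
#'
#' @param truth Character vector of true class labels.
#' @param predicted Character vector of predicted labels, same length.
#' @param class_names Optional class universe fixing row/column order;
#'   defaults to the sorted union of observed labels. Every label must
#'   appear in it.
#' @return Integer matrix of class `confusion_matrix` with class-name
#'   dimnames.
#' @examples
#' confusion_matrix(c("A", "B", "C", "A"), c("A", "B", "C", "A"))
#' @export
confusion_matrix <- function(truth, predicted, class_names = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop_dims("predicted", length(truth), length(predicted))
  if (is.null(class_names)) class_names <- sort(unique(c(truth, predicted)))
  unknown <- setdiff(unique(c(truth, predicted)), class_names)
  if (length(unknown) > 0)
    stop("label(s) not in class_names: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cm <- table(factor(truth, levels = class_names),
              factor(predicted, levels = class_names))
  m <- matrix(as.integer(cm), nrow = length(class_names),
              dimnames = list(true = class_names, predicted = class_names))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Multiclass Matthews correlation coefficient
#'
#' Computed from the M-class confusion matrix marginals as
#' `(n_c * n_s - sum_j p_j t_j) /
#'  sqrt((n_s^2 - sum_j p_j^2) * (n_s^2 - sum_j t_j^2))`
#' where `t_j` is the true count of class j, `p_j` its predicted count,
#' `n_c` the number of correct predictions and `n_s` the total. For two
#' classes this reduces to the classical binary MCC. The maximum is +1
#' (perfect prediction); when either factor under the square root is zero
#' (e.g. all predictions in one class) the statistic is undefined and 0 is
#' returned by convention.
#'
#' @param confusion A [confusion_matrix()] (rows = true, cols = predicted),
#'   or any square numeric matrix of counts.
#' @return Scalar in \[-1, 1\].
#' @export
multiclass_mcc <- function(confusion) {
  cm <- unclass(as.matrix(confusion))
  if (length(cm) == 0 || sum(cm) == 0)
    stop("confusion matrix is empty", call. = FALSE)
  t_j <- rowSums(cm)   # times class j truly occurs (rows = true)
  p_j <- colSums(cm)   # times class j is predicted (cols = predicted)
  n_c <- sum(diag(cm)); n_s <- sum(cm)
  num <- n_c * n_s - sum(p_j * t_j)
  den2 <- (n_s^2 - sum(p_j^2)) * (n_s^2 - sum(t_j^2))
  if (den2 <= 0) return(0)
  num / sqrt(den2)
}

#' Multi-class cross-entropy (log loss)
#'
#' Mean negative natural-log probability assigned to each sample's true
#' class: `-(1/n) sum_j sum_m y_jm * log(p_jm)` with `y` the one-hot truth
#' indicator. Because one-vs-rest sigmoid outputs do not sum to one per
#' sample, rows are renormalized to sum to 1 before evaluation (disable
#' with `normalize = FALSE` for already-calibrated probabilities), and
#' probabilities are clipped to `[eps, 1 - eps]` so a confident mistake
#' yields a large finite penalty instead of infinity. A perfect model has
#' log loss 0.
#'
#' @param truth Character vector of true labels, length n.
#' @param proba Numeric n-by-M matrix of class probabilities.
#' @param class_names Class name per column of `proba` (defaults to its
#'   column names).
#' @param normalize Renormalize rows to sum to 1 (default TRUE).
#' @param eps Clipping constant, default 1e-15.
#' @return Nonnegative scalar.
#' @export
log_loss <- function(truth, proba, class_names = colnames(proba),
                     normalize = TRUE, eps = 1e-15) {
  proba <- as.matrix(proba)
  truth <- as.character(truth)
  if (is.null(class_names)) stop("class_names required", call. = FALSE)
  if (length(truth) != nrow(proba)) stop_dims("truth", nrow(proba), length(truth))
  if (length(class_names) != ncol(proba))
    stop_dims("class_names", ncol(proba), length(class_names))
  if (any(proba < 0)) stop("negative probabilities", call. = FALSE)
  col <- match(truth, class_names)
  if (anyNA(col))
    stop("label(s) not in class_names: ",
         paste(unique(truth[is.na(col)]), collapse = ", "), call. = FALSE)
  if (normalize) {
    rs <- rowSums(proba)
    rs[rs == 0] <- 1          # an all-zero row becomes uniform after clipping
    proba <- proba / rs
  }
  p_true <- pmin(pmax(proba[cbind(seq_along(truth), col)], eps), 1 - eps)
  -mean(log(p_true))
}

#' Per-class precision, recall and F1
#'
#' From the confusion matrix: `precision_k = C_kk / p_k`,
#' `recall_k = C_kk / t_k`, F1 their harmonic mean. A class never
#' predicted (or absent from the truth) gets 0 for the undefined ratio,
#' with a warning. Macro aggregates are unweighted means; weighted
#' aggregates weight by true class support `t_k`.
#'
#' @param confusion A [confusion_matrix()].
#' @return List with `per_class` (data frame: class, precision, recall,
#'   f1, support), `accuracy`, `macro` and `weighted` (named vectors of
#'   precision/recall/f1).
#' @export
per_class_prf <- function(confusion) {
  cm <- unclass(as.matrix(confusion))
  if (sum(cm) == 0) stop("confusion matrix is empty", call. = FALSE)
  classes <- rownames(cm)
  tp <- diag(cm)
  t_k <- rowSums(cm)          # support (true occurrences)
  p_k <- colSums(cm)          # predicted occurrences
  if (any(p_k == 0 & t_k > 0))
    warning("class(es) never predicted; precision set to 0: ",
            paste(classes[p_k == 0 & t_k > 0], collapse = ", "), call. = FALSE)
  precision <- ifelse(p_k > 0, tp / p_k, 0)
  recall <- ifelse(t_k > 0, tp / t_k, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, support = as.integer(t_k),
                          row.names = NULL, stringsAsFactors = FALSE)
  w <- t_k / sum(t_k)
  list(per_class = per_class,
       accuracy = sum(tp) / sum(cm),
       macro = c(precision = mean(precision), recall = mean(recall),
                 f1 = mean(f1)),
       weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                    f1 = sum(w * f1)))
}

#' One-vs-rest ROC and precision-recall curves
#'
#' For each class, samples are scored by that class's probability column
#' and thresholds are placed at each distinct score (equal scores grouped
#' into one threshold). ROC points are (FPR, TPR) with AUC by the
#' trapezoid rule over the exact step curve; PR points are
#' (recall, precision) starting from recall 0 at precision 1. Classes
#' absent from the truth are omitted with a warning.
#'
#' @param truth Character vector of true labels.
#' @param proba Numeric n-by-M probability (score) matrix.
#' @param class_names Class per column of `proba`.
#' @return Named list per class: `roc` (data frame fpr/tpr), `auc`,
#'   `pr` (data frame recall/precision).
#' @export
ovr_curves <- function(truth, proba, class_names = colnames(proba)) {
  proba <- as.matrix(proba)
  truth <- as.character(truth)
  if (is.null(class_names)) stop("class_names required", call. = FALSE)
  if (length(class_names) != ncol(proba))
    stop_dims("class_names", ncol(proba), length(class_names))
  out <- list()
  for (i in seq_along(class_names)) {
    cl <- class_names[i]
    pos <- truth == cl
    if (!any(pos)) {
      warning("class '", cl, "' absent from truth; curves omitted",
              call. = FALSE)
      next
    }
    out[[cl]] <- binary_curves(pos, proba[, i])
  }
  out
}

# ROC + PR for one binary problem; thresholds at distinct descending scores.
#' @noRd
binary_curves <- function(pos, score) {
  ord <- order(score, decreasing = TRUE)
  pos <- pos[ord]; score <- score[ord]
  P <- sum(pos); N <- sum(!pos)
  # collapse tied scores: cumulative counts at the last index of each group
  last <- which(!duplicated(score, fromLast = TRUE))
  tp <- cumsum(pos)[last]
  fp <- cumsum(!pos)[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, if (N > 0) fp / N else rep(0, length(fp)))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- c(0, tp / P)
  precision <- c(1, tp / (tp + fp))
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       pr = data.frame(recall = recall, precision = precision))
}

#' Full evaluation report for multi-class probabilistic predictions
#'
#' Combines the confusion matrix, accuracy, multiclass MCC, log loss,
#' per-class precision/recall/F1 with macro and weighted aggregates, and
#' one-vs-rest ROC/PR curves into one object.
#'
#' @param truth Character vector of true labels.
#' @param proba Numeric n-by-M matrix of one-vs-rest probabilities.
#' @param class_names Class per column of `proba`.
#' @return Object of class `evaluation_report`.
#' @export
evaluate_predictions <- function(truth, proba, class_names = colnames(proba)) {
  proba <- as.matrix(proba)
  if (is.null(class_names)) stop("class_names required", call. = FALSE)
  pred <- predict_labels(proba, class_names)
  all_classes <- sort(unique(c(as.character(truth), class_names)))
  cm <- confusion_matrix(truth, pred$label, all_classes)
  prf <- per_class_prf(cm)
  structure(list(confusion = cm,
                 accuracy = prf$accuracy,
                 mcc = multiclass_mcc(cm),
                 log_loss = log_loss(truth, proba, class_names),
                 per_class = prf$per_class,
                 macro = prf$macro,
                 weighted = prf$weighted,
                 curves = ovr_curves(truth, proba, class_names),
                 low_confidence_rate = mean(pred$low_confidence)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d samples, %d classes\n",
              sum(x$confusion), nrow(x$confusion)))
  cat(sprintf("  accuracy %.4f | MCC %.4f | log loss %.4f\n",
              x$accuracy, x$mcc, x$log_loss))
  cat(sprintf("  macro    P %.4f R %.4f F1 %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("  weighted P %.4f R %.4f F1 %.4f\n",
              x$weighted["precision"], x$weighted["recall"], x$weighted["f1"]))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' Curves are summarized to their AUCs in the JSON; use
#' [write_curves_tsv()] for the full point sets.
#'
#' @param report An [evaluate_predictions()] result.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  out <- list(accuracy = report$accuracy, mcc = report$mcc,
              log_loss = report$log_loss,
              macro = as.list(report$macro),
              weighted = as.list(report$weighted),
              low_confidence_rate = report$low_confidence_rate,
              per_class = report$per_class,
              auc = lapply(report$curves, `[[`, "auc"),
              confusion = list(class_names = rownames(report$confusion),
                               counts = unclass(report$confusion)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Write a confusion matrix as TSV with class-name headers
#'
#' @param confusion A [confusion_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_confusion_tsv <- function(confusion, path) {
  m <- unclass(as.matrix(confusion))
  utils::write.table(cbind(true_class = rownames(m), as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ROC and PR points as a long-format TSV
#'
#' Columns: class, curve ("roc"/"pr"), x (FPR or recall), y (TPR or
#' precision) -- ready for external plotting.
#'
#' @param curves An [ovr_curves()] result (or `report$curves`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curves_tsv <- function(curves, path) {
  rows <- do.call(rbind, lapply(names(curves), function(cl) {
    rbind(data.frame(class = cl, curve = "roc",
                     x = curves[[cl]]$roc$fpr, y = curves[[cl]]$roc$tpr),
          data.frame(class = cl, curve = "pr",
                     x = curves[[cl]]$pr$recall, y = curves[[cl]]$pr$precision))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
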