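# Evaluation surface for imbalanced binary classification: confusion matrix,
# correct classification rate (CCR), minimum sensitivity (MS), ROC/AUC and
# precision-recall. Class order is fixed as (treated = 1, untreated = 0);
# all rates are fractions in [0, 1], formatted as percentages only for
# display.

check_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be coded 0/1")
  as.integer(labels)
}

#' Confusion matrix with fixed class order (treated, untreated)
#'
#' `n_ij` counts rows with true class `i` predicted as class `j`; row and
#' column 1 are the treated (positive) class, row and column 2 the untreated
#' class.
#'
#' @param truth true 0/1 labels (1 = treated).
#' @param predicted predicted 0/1 labels.
#' @return 2 x 2 integer matrix of class `confusion_matrix`.
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 1))
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- check_labels(truth); predicted <- check_labels(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  lev <- c(treated = 1L, untreated = 0L)
  cm <- matrix(0L, 2, 2, dimnames = list(true = names(lev),
                                         predicted = names(lev)))
  for (i in 1:2) for (j in 1:2)
    cm[i, j] <- sum(truth == lev[i] & predicted == lev[j])
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion_matrix (rows: true, cols: predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Correct classification rate
#'
#' Diagonal sum of the confusion matrix over the total count.
#' @param cm a `confusion_matrix` (any square count matrix works).
#' @return fraction in \[0, 1\].
#' @export
ccr <- function(cm) {
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(as.matrix(cm))) / n
}

#' Per-class sensitivities
#'
#' `S_j = n_jj / N_j`: the fraction of class-`j` rows classified as class
#' `j`.
#' @param cm a `confusion_matrix`.
#' @return named numeric vector of per-class sensitivities.
#' @export
sensitivities <- function(cm) {
  cm <- as.matrix(cm)
  nj <- rowSums(cm)
  if (any(nj == 0))
    stop("sensitivity undefined: class(es) absent from the true labels: ",
         paste(rownames(cm)[nj == 0], collapse = ", "))
  stats::setNames(diag(cm) / nj, rownames(cm))
}

#' Minimum sensitivity
#'
#' The smaller of the per-class sensitivities; 0 means one class was
#' completely misclassified. Guards the minority (untreated) class on
#' imbalanced cohorts, where CCR alone is misleading.
#' @param cm a `confusion_matrix`.
#' @return fraction in \[0, 1\].
#' @export
min_sensitivity <- function(cm) min(sensitivities(cm))

check_scores <- function(truth, scores) {
  truth <- check_labels(truth)
  if (length(truth) != length(scores)) stop("labels and scores differ in length")
  if (any(!is.finite(scores))) stop("scores must be finite")
  if (length(unique(truth)) < 2L)
    stop("both classes must be present to build a ROC curve")
  truth
}

# Cumulative TP/FP counts at each distinct-score threshold, sweeping from the
# highest score down; tied scores collapse into a single threshold step.
roc_steps <- function(truth, scores) {
  ord <- order(scores, decreasing = TRUE)
  t_sorted <- truth[ord]; s_sorted <- scores[ord]
  last_of_group <- cumsum(rle(s_sorted)$lengths)
  tp <- cumsum(t_sorted)[last_of_group]
  fp <- cumsum(1 - t_sorted)[last_of_group]
  list(tp = tp, fp = fp, P = sum(truth), N = sum(1 - truth))
}

#' ROC points
#'
#' (FPR, TPR) pairs swept over all distinct score thresholds, tied scores
#' grouped into one step; always starts at (0, 0) and ends at (1, 1), both
#' coordinates non-decreasing.
#'
#' @param truth true 0/1 labels (1 = positive/treated).
#' @param scores classifier scores (higher = more positive).
#' @return data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(truth, scores) {
  truth <- check_scores(truth, scores)
  st <- roc_steps(truth, scores)
  data.frame(fpr = c(0, st$fp / st$N), tpr = c(0, st$tp / st$P))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the tie-grouped ROC curve; algebraically equal to
#' the Mann-Whitney statistic with half weight on cross-class score ties.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
auc <- function(truth, scores) {
  r <- roc_points(truth, scores)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Precision-recall points and PR-AUC
#'
#' Precision and recall at every distinct-score threshold (ties grouped),
#' integrated by the same trapezoidal convention as the ROC curve. The
#' returned points are prepended with (recall 0, precision of the first
#' step) so the curve starts at recall 0.
#'
#' @inheritParams roc_points
#' @return list with `points` (data frame `recall`, `precision`) and
#'   `pr_auc`.
#' @export
pr_points_and_auc <- function(truth, scores) {
  truth <- check_labels(truth)
  if (sum(truth) == 0) stop("positive class absent; PR curve undefined")
  if (length(unique(truth)) < 2L) {
    # degenerate all-positive input: precision 1 at every recall
    pts <- data.frame(recall = c(0, 1), precision = c(1, 1))
    return(list(points = pts, pr_auc = 1))
  }
  st <- roc_steps(truth, scores)
  recall <- st$tp / st$P
  precision <- st$tp / (st$tp + st$fp)
  pts <- data.frame(recall = c(0, recall), precision = c(precision[1], precision))
  pr_auc <- sum(diff(pts$recall) *
                  (utils::head(pts$precision, -1) + utils::tail(pts$precision, -1)) / 2)
  list(points = pts, pr_auc = pr_auc)
}

#' Full metrics report for one model on one dataset
#'
#' Bundles the confusion matrix at the 0.5 threshold with CCR, per-class
#' sensitivities, minimum sensitivity, ROC-AUC, PR-AUC, the curve point
#' lists and the genome's connection count.
#'
#' @param truth true 0/1 labels.
#' @param probabilities predicted probabilities of the treated class.
#' @param n_connections optional connection count of the model.
#' @param threshold hard-label threshold (default 0.5).
#' @return a `metrics_report`.
#' @export
metrics_report <- function(truth, probabilities, n_connections = NA_integer_,
                           threshold = 0.5) {
  cm <- confusion_matrix(truth, as.integer(probabilities >= threshold))
  rep <- list(confusion = cm, ccr = ccr(cm),
              sensitivities = sensitivities(cm),
              ms = min_sensitivity(cm),
              auc = auc(truth, probabilities),
              pr = pr_points_and_auc(truth, probabilities),
              roc = roc_points(truth, probabilities),
              n_connections = n_connections, threshold = threshold)
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report: CCR %.3f | MS %.3f | AUC %.3f | PR-AUC %.3f",
              x$ccr, x$ms, x$auc, x$pr$pr_auc))
  if (!is.na(x$n_connections)) cat(sprintf(" | #conn %d", x$n_connections))
  cat("\n")
  print(x$confusion)
  invisible(x)
}

#' Export a metrics report
#'
#' Writes scalar metrics and the confusion matrix as JSON, and optionally the
#' ROC and PR point lists as CSV.
#' @param report a `metrics_report`.
#' @param path JSON file path.
#' @param roc_path,pr_path optional CSV paths for the curves.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path, roc_path = NULL, pr_path = NULL) {
  doc <- list(ccr = report$ccr, ms = report$ms, auc = report$auc,
              pr_auc = report$pr$pr_auc,
              sensitivities = as.list(report$sensitivities),
              confusion = as.data.frame(as.table(unclass(report$confusion))),
              n_connections = report$n_connections,
              threshold = report$threshold)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc_path)) utils::write.csv(report$roc, roc_path, row.names = FALSE)
  if (!is.null(pr_path)) utils::write.csv(report$pr$points, pr_path, row.names = FALSE)
  invisible(path)
}
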