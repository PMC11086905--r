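# Performance indices for imbalanced binary classification, implemented from
# their definitions: confusion-matrix metrics at a probability threshold,
# AUROC by the Mann-Whitney concordance formulation (half credit for ties),
# AUPRC as step-wise average precision. Plus Cronbach's alpha.

#' Classification metrics report
#'
#' Computes accuracy, precision, recall, balanced accuracy (mean of
#' sensitivity and specificity), AUROC and AUPRC.
#'
#' AUROC uses the rank (Mann-Whitney) formulation with ties receiving half
#' credit. AUPRC is average precision, `sum_n (R_n - R_{n-1}) * P_n` over the
#' descending-score sweep with tied scores grouped -- the step-wise
#' definition, not trapezoidal interpolation (interpolation inflates AUPRC
#' under class imbalance). Precision is reported as 0 when no positives are
#' predicted.
#'
#' If `y` contains a single class the rank metrics are undefined: with
#' `strict_rank_metrics = TRUE` (default) this is an error; otherwise the
#' thresholded metrics are still returned and the rank metrics are `NA`.
#'
#' @param y binary 0/1 labels.
#' @param scores numeric scores; interpreted as probabilities for the
#'   thresholded metrics.
#' @param threshold probability cut-off for the thresholded metrics
#'   (default 0.5).
#' @param strict_rank_metrics error on single-class `y`?
#' @return a `metrics_report` object (named list of the six indices plus the
#'   threshold used).
#' @export
compute_metrics <- function(y, scores, threshold = 0.5,
                            strict_rank_metrics = TRUE) {
  y <- as.numeric(y)
  stop_if(!is_binary(y), "`y` must be binary 0/1")
  stop_if(length(y) != length(scores), "y and scores lengths disagree")
  stop_if(anyNA(scores), "scores contain missing values")

  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  accuracy <- (tp + tn) / length(y)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  specificity <- if (tn + fp > 0) tn / (tn + fp) else 0
  balanced <- (recall + specificity) / 2

  single_class <- length(unique(y)) < 2
  if (single_class && strict_rank_metrics) {
    stop("AUROC/AUPRC are undefined when y contains a single class",
         call. = FALSE)
  }
  auroc_v <- if (single_class) NA_real_ else auroc(y, scores)
  auprc_v <- if (single_class) NA_real_ else auprc(y, scores)

  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 balanced_accuracy = balanced, auroc = auroc_v,
                 auprc = auprc_v, threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> Accuracy %.3f  AUROC %.3f  Precision %.3f  ",
                     "Recall %.3f  Balanced Accuracy %.3f  AUPRC %.3f (threshold %.2f)\n"),
              x$accuracy, x$auroc, x$precision, x$recall,
              x$balanced_accuracy, x$auprc, x$threshold))
  invisible(x)
}

#' Serialize a metrics report as JSON
#' @param report a [compute_metrics()] result.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
metrics_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  out <- list(Accuracy = report$accuracy, AUROC = report$auroc,
              Precision = report$precision, Recall = report$recall,
              `Balanced Accuracy` = report$balanced_accuracy,
              AUPRC = report$auprc)
  if (is.null(path)) {
    jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    invisible(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA))
  }
}

#' Area under the ROC curve (Mann-Whitney, half credit for ties)
#' @param y binary labels (both classes present).
#' @param scores numeric scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(y, scores) {
  y <- as.numeric(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  stop_if(n1 == 0 || n0 == 0, "AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision over the descending-score sweep, with tied
#' scores grouped into single threshold steps.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(y, scores) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  stop_if(n1 == 0 || sum(y == 0) == 0, "AUPRC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  block_end <- cumsum(rle(ss)$lengths)   # last index of each tied block
  tp <- cumsum(ys)[block_end]
  n_pred <- block_end
  prec <- tp / n_pred
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Cronbach's alpha (internal-consistency reliability)
#'
#' `alpha = p/(p-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param responses a [response_matrix()] or numeric matrix with `p >= 2`
#'   columns and nonzero total-score variance.
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(responses) {
  X <- as.matrix(responses)
  storage.mode(X) <- "double"
  p <- ncol(X)
  stop_if(p < 2, "Cronbach's alpha needs at least two items")
  stop_if(anyNA(X), "responses contain missing values")
  total_var <- stats::var(rowSums(X))
  stop_if(total_var == 0, "total score has zero variance; alpha is undefined")
  item_var <- sum(apply(X, 2L, stats::var))
  p / (p - 1) * (1 - item_var / total_var)
}
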