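# AUC by the Mann-Whitney rank statistic (midranks handle ties).
auc_rank <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ROC points: one per distinct threshold, ties grouped, (0,0) prepended.
roc_points <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp <- cumsum(!duplicated(sc))
  tp <- tapply(lab == 1, grp, sum)
  fp <- tapply(lab == 0, grp, sum)
  tibble(
    fpr = c(0, cumsum(as.numeric(fp)) / max(sum(labels == 0), 1)),
    tpr = c(0, cumsum(as.numeric(tp)) / max(sum(labels == 1), 1))
  )
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' Classification metrics for one run
#'
#' AUC via the Mann-Whitney rank statistic; accuracy, precision, recall and
#' F1 at probability threshold 0.5. Precision (and hence F1) is `NA` when
#' no positive predictions are made.
#'
#' @param labels 0/1 vector (both classes must be present for AUC).
#' @param scores predicted probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return tibble (accuracy, auc, precision, recall, f1) with the ROC
#'   curve attached as attribute `"roc"`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  if (length(unique(labels)) < 2) {
    abort("AUC undefined: both classes must be present.")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  out <- tibble(
    accuracy = mean(pred == labels),
    auc = auc_rank(labels, scores),
    precision = precision, recall = recall, f1 = f1
  )
  attr(out, "roc") <- roc_points(labels, scores)
  out
}

new_eval_report <- function(per_repeat, rocs = NULL, extra = list()) {
  structure(
    c(list(per_repeat = per_repeat, rocs = rocs), extra),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(glance(x))
  invisible(x)
}

#' Per-repeat metrics of an evaluation report
#' @param x an `eval_report`.
#' @param ... unused.
#' @return tibble with one row per repeat.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_repeat

#' Mean and SD of metrics over repeats
#' @param x an `eval_report`.
#' @param ... unused.
#' @return one-row tibble of metric means and SDs.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  metrics <- c("accuracy", "auc", "precision", "recall", "f1")
  present <- intersect(metrics, names(x$per_repeat))
  x$per_repeat |>
    summarise(across(
      dplyr::all_of(present),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))
    ))
}
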