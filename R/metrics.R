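#' Confusion matrix from class-code vectors
#'
#' Rows are actual classes, columns predicted classes;
#' `counts[a, p]` is the number of samples of class `a` predicted as `p`.
#' The trace over the total times 100 equals the accuracy computed directly
#' from the predictions.
#'
#' @param actual,predicted Integer class codes in `[0, C)`.
#' @param n_classes Number of classes `C`.
#' @return A `C x C` integer matrix of class `confusion_matrix` with
#'   `actual_*` row names and `pred_*` column names.
#' @export
confusion_from_predictions <- function(actual, predicted, n_classes) {
  actual <- as.integer(actual)
  predicted <- as.integer(predicted)
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length")
  }
  C <- as.integer(n_classes)
  if (any(actual < 0L | actual >= C) || any(predicted < 0L | predicted >= C)) {
    stop("class codes must lie in [0, ", C, ")")
  }
  cm <- matrix(0L, C, C,
               dimnames = list(paste0("actual_", seq_len(C) - 1L),
                               paste0("pred_", seq_len(C) - 1L)))
  for (i in seq_along(actual)) {
    cm[actual[i] + 1L, predicted[i] + 1L] <-
      cm[actual[i] + 1L, predicted[i] + 1L] + 1L
  }
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' Precision, recall, F1 and accuracy from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and F1 (harmonic
#' mean), with the `0/0 := 0` convention, plus unweighted macro averages,
#' accuracy on the 0-100 scale and `error_rate = 100 - accuracy`.
#'
#' @param cm A confusion matrix (rows actual, columns predicted).
#' @return A list: `accuracy`, `error_rate`, `per_class` (data frame with
#'   `class`, `precision`, `recall`, `f1`), `macro_precision`,
#'   `macro_recall`, `macro_f1`.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stop("confusion matrix is empty")
  C <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  accuracy <- 100 * sum(tp) / total
  list(accuracy = accuracy,
       error_rate = 100 - accuracy,
       per_class = data.frame(class = seq_len(C) - 1L,
                              precision = precision, recall = recall,
                              f1 = f1, row.names = NULL),
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_f1 = mean(f1))
}

#' Summary statistics over repeated runs
#'
#' Mean, sample standard deviation (n-1 denominator; 0 for a single value),
#' extremes and quartiles (linear interpolation) of per-run accuracies — the
#' numbers that underlie multi-run comparison tables and boxplots.
#'
#' @param per_run_accuracy Non-empty numeric vector.
#' @return A list: `mean`, `sd`, `min`, `q1`, `median`, `q3`, `max`, `n`.
#' @export
summarize_runs <- function(per_run_accuracy) {
  x <- as.numeric(per_run_accuracy)
  if (length(x) < 1L) stop("per_run_accuracy must be non-empty")
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  list(mean = mean(x),
       sd = if (length(x) > 1L) stats::sd(x) else 0,
       min = min(x), q1 = q[1L], median = q[2L], q3 = q[3L], max = max(x),
       n = length(x))
}
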