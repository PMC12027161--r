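#' Confusion counts for binary case/control predictions
#'
#' The positive class is `case`.
#'
#' @param truth True labels (`"case"`/`"control"`, 0/1 or logical).
#' @param predicted Predicted labels, same encodings accepted.
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  y <- as_case_indicator(truth)
  p <- as_case_indicator(predicted)
  if (length(y) != length(p)) abort("label vectors differ in length")
  tibble(
    tp = sum(y == 1 & p == 1), fp = sum(y == 0 & p == 1),
    tn = sum(y == 0 & p == 0), fn = sum(y == 1 & p == 0)
  )
}

#' Confusion-matrix performance metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy, precision
#' `tp/(tp+fp)` and F1. A ratio with zero denominator is reported as `NaN`
#' with a warning.
#'
#' @param counts One-row tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @return One-row tibble of the five metrics.
#' @export
#' @examples
#' classification_metrics(tibble::tibble(tp = 4, fp = 2, tn = 3, fn = 1))
classification_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (0/0); reported as NaN", what))
      return(NaN)
    }
    num / den
  }
  sens <- safe_div(tp, tp + fn, "sensitivity")
  spec <- safe_div(tn, tn + fp, "specificity")
  prec <- safe_div(tp, tp + fp, "precision")
  f1 <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) {
    if (!is.nan(prec) && !is.nan(sens)) {
      warn("F1 undefined (precision + sensitivity = 0); reported as NaN")
    }
    NaN
  } else 2 * prec * sens / (prec + sens)
  tibble(
    sensitivity = sens, specificity = spec,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    precision = prec, f1 = f1
  )
}

#' ROC curve and tie-corrected AUC
#'
#' The ROC is built by sweeping every distinct probability as a threshold
#' under the inclusive (`>=`) classification rule, plus the endpoints
#' (0, 0) and (1, 1). The AUC is the trapezoid area, which with this
#' construction equals the tie-corrected concordance probability (the
#' Mann-Whitney statistic with half credit for tied case/control pairs) —
#' the appropriate definition for KNN probabilities, which are discrete
#' multiples of 1/k and tie often.
#'
#' @param truth True labels.
#' @param prob Case probabilities in `[0, 1]`.
#' @return List with `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.2))$auc  # 1
roc_auc <- function(truth, prob) {
  y <- as_case_indicator(truth)
  if (any(prob < 0 | prob > 1)) abort("probabilities must be in [0, 1]")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC undefined with a single class", class = "loadrisk_single_class")
  }
  thr <- c(Inf, sort(unique(prob), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(prob >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(prob >= t & y == 0) / n0, numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(roc = tibble(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Sensitivity/specificity over a grid of decision thresholds
#'
#' Classifies with the inclusive (`>=`) rule at each threshold. Sensitivity
#' is non-increasing and specificity non-decreasing in the threshold. The
#' default grid is every multiple of 0.01 in `[0, 1]`.
#'
#' @param truth True labels.
#' @param prob Case probabilities.
#' @param grid Thresholds within `[0, 1]`.
#' @return Tibble of class `threshold_sweep`: `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
threshold_sweep <- function(truth, prob, grid = seq(0, 1, by = 0.01)) {
  y <- as_case_indicator(truth)
  if (any(grid < 0 | grid > 1)) abort("grid must lie within [0, 1]")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  out <- purrr::map_dfr(sort(grid), function(t) {
    pred <- prob >= t
    tibble(threshold = t,
           sensitivity = if (n1) sum(pred & y == 1) / n1 else NaN,
           specificity = if (n0) sum(!pred & y == 0) / n0 else NaN)
  })
  class(out) <- c("threshold_sweep", class(out))
  out
}

#' Pick a decision threshold from a sweep table
#'
#' `"youden"` maximizes Youden's J = sensitivity + specificity - 1;
#' `"max_sensitivity"` returns the smallest threshold whose specificity is
#' at least `min_specificity` — because sensitivity is non-increasing in
#' the threshold, that threshold maximizes sensitivity subject to the
#' specificity floor. Ties resolve to the lower threshold.
#'
#' @param sweep A [threshold_sweep()] table.
#' @param policy `"max_sensitivity"` (constrained, default) or `"youden"`.
#' @param min_specificity Specificity floor for the constrained policy.
#' @return The selected threshold.
#' @export
optimal_threshold <- function(sweep, policy = c("max_sensitivity", "youden"),
                              min_specificity = 0.61) {
  policy <- match.arg(policy)
  if (!nrow(sweep)) abort("empty sweep table")
  sweep <- sweep %>% arrange(.data$threshold)
  if (policy == "youden") {
    j <- sweep$sensitivity + sweep$specificity - 1
    sweep$threshold[which.max(j)]
  } else {
    ok <- which(sweep$specificity >= min_specificity)
    if (!length(ok)) {
      abort(sprintf("no threshold reaches specificity %.2f", min_specificity),
            class = "loadrisk_no_threshold")
    }
    sweep$threshold[ok[1]]
  }
}

#' Full evaluation of probabilistic predictions at a threshold
#'
#' Combines the confusion counts, the derived metrics, the ROC curve and
#' the tie-corrected AUC into a single evaluation object.
#'
#' @param truth True labels.
#' @param prob Case probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return An object of class `knn_eval` with elements `counts`, `metrics`,
#'   `roc`, `auc`, `threshold`, `n_test`; see [glance.knn_eval()],
#'   [tidy.knn_eval()] and [autoplot.knn_eval()].
#' @export
evaluate_predictions <- function(truth, prob, threshold = 0.5) {
  counts <- confusion_counts(truth, classify(prob, threshold))
  ra <- roc_auc(truth, prob)
  structure(list(
    counts = counts,
    metrics = classification_metrics(counts),
    roc = ra$roc, auc = ra$auc,
    threshold = threshold, n_test = length(prob)
  ), class = "knn_eval")
}

#' @export
print.knn_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(paste0(
    "<knn_eval> n = %d, threshold = %.2f\n",
    "  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
    "  precision %.3f  F1 %.3f  AUC %.3f\n"),
    x$n_test, x$threshold, m$sensitivity, m$specificity, m$accuracy,
    m$precision, m$f1, x$auc))
  invisible(x)
}

#' One-row summary of an evaluation
#'
#' @param x A `knn_eval` object.
#' @param ... Unused.
#' @return One-row tibble with the confusion counts, the five metrics, the
#'   AUC, the threshold and the test size.
#' @method glance knn_eval
#' @export
glance.knn_eval <- function(x, ...) {
  dplyr::bind_cols(x$counts, x$metrics,
                   tibble(auc = x$auc, threshold = x$threshold,
                          n_test = x$n_test))
}

#' ROC points of an evaluation
#'
#' @inheritParams glance.knn_eval
#' @return Tibble of ROC points (`threshold`, `fpr`, `tpr`).
#' @method tidy knn_eval
#' @export
tidy.knn_eval <- function(x, ...) x$roc

#' Plot the ROC curve of an evaluation
#'
#' @inheritParams glance.knn_eval
#' @return A ggplot.
#' @method autoplot knn_eval
#' @export
autoplot.knn_eval <- function(x, ...) {
  ggplot2::ggplot(x$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", x$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a threshold sweep
#'
#' Sensitivity and specificity as functions of the decision threshold.
#'
#' @param x A [threshold_sweep()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble(x),
                              all_of(c("sensitivity", "specificity")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(sensitivity = "#c0392b",
                                            specificity = "#2980b9")) +
    ggplot2::labs(x = "Decision threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
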