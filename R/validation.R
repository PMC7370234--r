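# Leave-one-out cross-validation of the predictor and confusion-matrix
# metrics. Each fold refits standardization, PCA and LDA from scratch on the
# remaining samples, so no information from the held-out sample leaks into
# the space it is projected into.

#' Confusion-matrix metrics for two-class predictions
#'
#' The synergistic class is the positive class throughout: sensitivity is
#' the fraction of synergistic responders correctly called, specificity the
#' fraction of low responders correctly called.
#'
#' @param truth,predicted Equal-length character vectors of labels
#'   (`synergistic` / `low`). `NA` predictions (unevaluable samples) are
#'   excluded from every denominator.
#' @return List with counts `tp`, `fp`, `tn`, `fn`, `n_evaluated`, and
#'   fractions `accuracy`, `sensitivity`, `specificity`.
#' @export
#' @examples
#' confusion_metrics(c("synergistic", "low"), c("synergistic", "synergistic"))
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted labels differ in length", call. = FALSE)
  keep <- !is.na(predicted)
  truth <- truth[keep]; predicted <- predicted[keep]
  tp <- sum(truth == "synergistic" & predicted == "synergistic")
  fn <- sum(truth == "synergistic" & predicted == "low")
  tn <- sum(truth == "low" & predicted == "low")
  fp <- sum(truth == "low" & predicted == "synergistic")
  n <- tp + fn + tn + fp
  list(tp = tp, fp = fp, tn = tn, fn = fn, n_evaluated = n,
       accuracy = if (n > 0) (tp + tn) / n else NA_real_,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Leave-one-out cross-validation of the response predictor
#'
#' For each sample, a predictor is trained on the remaining n - 1 samples
#' (fresh standardization, PCA and LDA) and the held-out sample is projected
#' into that training space and classified. A fold whose training set lacks
#' one of the two classes is skipped with a warning and the sample marked
#' unevaluable; aggregate metrics are computed over evaluable samples only.
#'
#' @param panel An [expression_panel()] with at least 3 samples.
#' @param labels A [response_table()] covering the panel.
#' @param config A [run_config()].
#' @return An object of class `"cv_report"`: `per_sample` data frame
#'   (`sample_id`, `truth`, `predicted`, `posterior`, `evaluable`) plus the
#'   [confusion_metrics()] aggregates.
#' @export
loocv <- function(panel, labels, config = run_config()) {
  stopifnot(inherits(panel, "expression_panel"))
  lab <- .align_labels(panel, labels)
  n <- length(panel$sample_ids)
  if (n < 3L) stop("LOOCV requires at least 3 samples", call. = FALSE)
  predicted <- rep(NA_character_, n)
  posterior <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train_lab <- lab[-i]
    if (length(unique(train_lab)) < 2L) {
      warning(sprintf("fold %d: training set lacks a class; sample '%s' unevaluable",
                      i, panel$sample_ids[i]))
      next
    }
    fold_panel <- expression_panel(panel$values[-i, , drop = FALSE],
                                   panel$sample_ids[-i], panel$protein_ids)
    fold_labels <- response_table(panel$sample_ids[-i], train_lab)
    model <- suppressWarnings(train_predictor(fold_panel, fold_labels, config))
    pred <- stats::predict(model, panel$values[i, ])
    predicted[i] <- pred$label
    posterior[i] <- pred$posterior
  }
  per_sample <- data.frame(sample_id = panel$sample_ids, truth = lab,
                           predicted = predicted, posterior = posterior,
                           evaluable = !is.na(predicted),
                           stringsAsFactors = FALSE)
  metrics <- confusion_metrics(lab, predicted)
  structure(c(list(per_sample = per_sample), metrics), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("LOOCV: %d/%d correct (accuracy %.1f%%)\n",
              x$tp + x$tn, x$n_evaluated, 100 * x$accuracy))
  cat(sprintf("sensitivity %.1f%% (synergistic recalled), specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Write a cross-validation report to delimited text
#'
#' Emits the per-sample table followed by aggregate footer lines (prefixed
#' `#`).
#'
#' @param report A [loocv()] report.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  utils::write.table(report$per_sample, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat(sprintf("# accuracy\t%.6f\n# sensitivity\t%.6f\n# specificity\t%.6f\n",
              report$accuracy, report$sensitivity, report$specificity),
      file = path, append = TRUE)
  invisible(path)
}
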