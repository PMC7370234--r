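# Correlation-merit ranking of proteins and iterative predictor reduction.
# The merit of a protein is the absolute Pearson correlation between its
# expression and the binary response class, averaged over the training
# portions of stratified cross-validation folds; the predictor is then
# shrunk by repeatedly dropping the lowest-ranked protein and re-validating.

# Stratified fold assignment: within each class, samples are shuffled
# (seeded) and dealt round-robin into k folds.
.stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  fold <- integer(n)
  .with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Rank proteins by correlation merit
#'
#' Encodes the response class as synergistic = 1, low = 0 and, for each of
#' `cv_folds` stratified folds, computes the absolute Pearson correlation
#' between each protein and the class indicator on the fold's training
#' portion. The merit is the mean over folds; proteins are ranked by
#' descending merit (rank 1 = highest), ties broken by canonical
#' protein-name order. Because Pearson correlation is scale-free, the
#' ranking is invariant to affine rescaling of any protein column.
#'
#' @param panel An [expression_panel()].
#' @param labels A [response_table()] covering the panel; both classes must
#'   be present.
#' @param config A [run_config()]; uses `cv_folds` and `rng_seed`.
#' @param use_cv Set `FALSE` to compute a single full-data correlation per
#'   protein instead of the fold average (comparison mode).
#' @return An object of class `"merit_ranking"`: data frame with columns
#'   `protein`, `merit`, `rank` (sorted by rank) and attributes `folds`
#'   and `seed`.
#' @export
merit_rank <- function(panel, labels, config = run_config(), use_cv = TRUE) {
  stopifnot(inherits(panel, "expression_panel"))
  lab <- .align_labels(panel, labels)
  if (length(unique(lab)) < 2L)
    stop("both response classes must be present", call. = FALSE)
  y <- as.numeric(lab == "synergistic")
  n <- length(y)
  k <- config$cv_folds
  if (use_cv && k > n) stop("cv_folds exceeds the number of samples", call. = FALSE)
  x <- panel$values
  abs_cor <- function(rows) {
    sds <- apply(x[rows, , drop = FALSE], 2L, stats::sd)
    r <- rep(0, ncol(x))
    ok <- sds > 0 & stats::sd(y[rows]) > 0
    if (any(ok))
      r[ok] <- abs(suppressWarnings(
        stats::cor(x[rows, ok, drop = FALSE], y[rows])))
    r
  }
  if (use_cv) {
    fold <- .stratified_folds(lab, k, config$rng_seed)
    per_fold <- vapply(seq_len(k), function(f) abs_cor(which(fold != f)),
                       numeric(ncol(x)))
    merit <- rowMeans(per_fold)
    if (any(merit == 0 & apply(per_fold == 0, 1L, all)))
      warning("protein(s) with zero merit in every training portion: ",
              paste(panel$protein_ids[merit == 0], collapse = ", "))
  } else {
    merit <- abs_cor(seq_len(n))
  }
  # tie-break: canonical panel order first, then alphabetical
  canon_pos <- match(panel$protein_ids, panel_proteins())
  canon_pos[is.na(canon_pos)] <- length(panel_proteins()) + 1L
  ord <- order(-merit, canon_pos, panel$protein_ids)
  out <- data.frame(protein = panel$protein_ids[ord], merit = merit[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(out, class = c("merit_ranking", "data.frame"),
            folds = if (use_cv) k else NA_integer_, seed = config$rng_seed)
}

#' Iteratively reduce the predictor by dropping low-merit proteins
#'
#' Starting from the full panel, the lowest-ranked remaining protein is
#' removed at each iteration and the predictor is re-validated by LOOCV on
#' the sub-panel (with the retained-component cap lowered to the current
#' protein count when necessary); training-set separation accuracy is
#' recorded alongside. The selected subset is the smallest protein set whose
#' LOOCV accuracy is within `tolerance` of the full-panel accuracy.
#'
#' @param panel An [expression_panel()].
#' @param labels A [response_table()] covering the panel.
#' @param ranking A [merit_rank()] ranking covering the panel's proteins.
#' @param config A [run_config()].
#' @param min_proteins Smallest panel size to evaluate; default 2.
#' @param tolerance Allowed LOOCV accuracy drop relative to the full panel
#'   for subset selection; default 0.
#' @return An object of class `"reduction_curve"`: data frame with one row
#'   per iteration (`n_proteins`, `loocv_accuracy`, `training_accuracy`,
#'   `proteins` as a semicolon-joined string) and attribute
#'   `selected_proteins`.
#' @export
reduce_predictor <- function(panel, labels, ranking, config = run_config(),
                             min_proteins = 2L, tolerance = 0) {
  stopifnot(inherits(panel, "expression_panel"),
            inherits(ranking, "merit_ranking"))
  if (!setequal(ranking$protein, panel$protein_ids))
    stop("ranking does not cover the panel's proteins", call. = FALSE)
  current <- ranking$protein[order(ranking$rank)]  # best first
  steps <- list()
  i <- 0L
  while (length(current) >= max(2L, min_proteins)) {
    i <- i + 1L
    sub <- subset_panel(panel, proteins = current)
    cfg <- config
    cfg$n_pcs_max <- min(config$n_pcs_max, length(current))
    cv <- suppressWarnings(loocv(sub, labels, cfg))
    model <- suppressWarnings(train_predictor(sub, labels, cfg))
    train_pred <- stats::predict(model, sub)
    train_acc <- confusion_metrics(.align_labels(sub, labels),
                                   train_pred$label)$accuracy
    steps[[i]] <- data.frame(n_proteins = length(current),
                             loocv_accuracy = cv$accuracy,
                             training_accuracy = train_acc,
                             proteins = paste(current, collapse = ";"),
                             stringsAsFactors = FALSE)
    current <- current[-length(current)]  # drop lowest-ranked
  }
  curve <- do.call(rbind, steps)
  full_acc <- curve$loocv_accuracy[1L]
  ok <- which(curve$loocv_accuracy >= full_acc - tolerance)
  sel <- ok[which.min(curve$n_proteins[ok])]
  structure(curve, class = c("reduction_curve", "data.frame"),
            selected_proteins = strsplit(curve$proteins[sel], ";", fixed = TRUE)[[1L]],
            selected_n = curve$n_proteins[sel])
}

#' @export
print.reduction_curve <- function(x, ...) {
  cat(sprintf("reduction curve: %d iterations, %d -> %d proteins\n",
              nrow(x), x$n_proteins[1L], x$n_proteins[nrow(x)]))
  cat(sprintf("selected subset: %d proteins (LOOCV accuracy %.1f%%)\n",
              attr(x, "selected_n"),
              100 * x$loocv_accuracy[x$n_proteins == attr(x, "selected_n")][1L]))
  invisible(x)
}
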