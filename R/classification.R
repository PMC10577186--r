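#' Assemble the four canonical feature sets
#'
#' Set 1: the 12 microstate temporal features (mean duration, occurrence,
#' coverage for classes A-D). Set 2 adds DAR, Set 3 adds microstate LZC,
#' Set 4 adds both. Column order is fixed: duration A-D, occurrence A-D,
#' coverage A-D, then dar, then lzc.
#'
#' @param table A cohort data.frame with columns `duration_A..D`,
#'   `occurrence_A..D`, `coverage_A..D`, `dar`, `lzc`, `group`.
#' @return List with `set1`..`set4` (numeric matrices) and `y`
#'   (factor group labels).
#' @export
assemble_feature_sets <- function(table) {
  temporal <- as.vector(outer(c("duration", "occurrence", "coverage"),
                              c("A", "B", "C", "D"), paste, sep = "_"))
  temporal <- temporal[order(rep(1:3, 4))]    # duration_A..D, occurrence_A..D, coverage_A..D
  needed <- c(temporal, "dar", "lzc", "group")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(table[needed])) stop("cohort table contains missing values", call. = FALSE)
  m <- function(cols) as.matrix(table[cols])
  list(set1 = m(temporal),
       set2 = m(c(temporal, "dar")),
       set3 = m(c(temporal, "lzc")),
       set4 = m(c(temporal, "dar", "lzc")),
       y = factor(table$group))
}

# Stratified fold assignment: a seeded shuffle within each class followed
# by round-robin fold labels, so the folds (and hence the report) do not
# depend on the row order of the input.
stratified_folds <- function(y, n_folds, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[order(stats::runif(length(idx)))]
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

#' Cross-validated RBF-SVM classification
#'
#' Stratified k-fold cross-validation of a radial-basis-function SVM.
#' Inside every training fold (only): features are z-scored, then
#' optionally projected onto the principal components retaining
#' `pca_variance` of the training variance; the fitted transforms are
#' applied to the held-out fold. Sensitivity is TP/(TP+FN) on the positive
#' class, specificity TN/(TN+FP); the headline AUC pools decision scores
#' across folds (per-fold AUCs are also reported where defined).
#'
#' @param X Numeric feature matrix (rows = recordings).
#' @param y Two-level factor of group labels.
#' @param c SVM cost parameter (default 1).
#' @param n_folds Number of folds (default 10).
#' @param pca_variance Fraction of variance the PCA keeps, or `NULL` to
#'   disable PCA (default 0.95).
#' @param seed RNG seed controlling fold assignment and the SVM.
#' @param positive The positive-class label (default: the second factor
#'   level, e.g. "DOC" against "AW").
#' @return A `classifier_report`: mean `accuracy`, `sensitivity`,
#'   `specificity` in percent, pooled `auc`, `per_fold` data.frame, and a
#'   `config` echo.
#' @export
crossval_classify <- function(X, y, c = 1, n_folds = 10, pca_variance = 0.95,
                              seed = 1, positive = NULL) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) != 2L) stop("`y` must have exactly two classes", call. = FALSE)
  if (any(table(y) < n_folds)) {
    stop(sprintf("stratified %d-fold CV needs >= %d samples per class", n_folds, n_folds),
         call. = FALSE)
  }
  positive <- positive %||% levels(y)[2L]
  if (!positive %in% levels(y)) stop("`positive` is not a level of `y`", call. = FALSE)
  negative <- setdiff(levels(y), positive)
  folds <- stratified_folds(y, n_folds, seed)
  per_fold <- data.frame(fold = seq_len(n_folds), accuracy = NA_real_,
                         sensitivity = NA_real_, specificity = NA_real_,
                         auc = NA_real_)
  scores_all <- numeric(0)
  truth_all <- character(0)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sdev <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sdev[sdev == 0] <- 1
    xtr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdev, "/")
    xte <- sweep(sweep(X[!tr, , drop = FALSE], 2L, mu), 2L, sdev, "/")
    if (!is.null(pca_variance)) {
      pc <- stats::prcomp(xtr, center = FALSE, scale. = FALSE)
      cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
      ncomp <- max(1L, which(cum >= pca_variance)[1L])
      xtr <- pc$x[, seq_len(ncomp), drop = FALSE]
      xte <- xte %*% pc$rotation[, seq_len(ncomp), drop = FALSE]
    }
    gamma <- 1 / (ncol(xtr) * max(stats::var(as.vector(xtr)), .Machine$double.eps))
    fit <- with_seed(seed + f, e1071::svm(xtr, y[tr], kernel = "radial",
                                          cost = c, gamma = gamma, scale = FALSE))
    pred <- stats::predict(fit, xte, decision.values = TRUE)
    dv <- drop(attr(pred, "decision.values"))
    # e1071 names the decision column "first/second": positive values vote
    # for the first class. Orient so larger always means the positive class.
    if (!grepl(paste0("^", positive, "/"), colnames(attr(pred, "decision.values"))[1L])) {
      dv <- -dv
    }
    truth <- as.character(y[!tr])
    tp <- sum(pred == positive & truth == positive)
    fn <- sum(pred != positive & truth == positive)
    tn <- sum(pred == negative & truth == negative)
    fp <- sum(pred != negative & truth == negative)
    per_fold$accuracy[f] <- 100 * (tp + tn) / length(truth)
    per_fold$sensitivity[f] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    per_fold$specificity[f] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    if (length(unique(truth)) == 2L) {
      per_fold$auc[f] <- as.numeric(pROC::auc(
        pROC::roc(truth, dv, levels = c(negative, positive),
                  direction = "<", quiet = TRUE)))
    }
    scores_all <- c(scores_all, dv)
    truth_all <- c(truth_all, truth)
  }
  pooled_auc <- as.numeric(pROC::auc(
    pROC::roc(truth_all, scores_all, levels = c(negative, positive),
              direction = "<", quiet = TRUE)))
  structure(
    list(accuracy = mean(per_fold$accuracy),
         sensitivity = mean(per_fold$sensitivity, na.rm = TRUE),
         specificity = mean(per_fold$specificity, na.rm = TRUE),
         auc = pooled_auc,
         per_fold = per_fold,
         config = list(C = c, kernel = "radial", folds = n_folds,
                       seed = seed, pca_variance = pca_variance,
                       positive = positive)),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "<classifier_report> accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%, AUC %.3f (C = %g, %d-fold)\n",
    x$accuracy, x$sensitivity, x$specificity, x$auc, x$config$C, x$config$folds))
  invisible(x)
}

#' Classify all four feature sets
#'
#' Convenience wrapper running [crossval_classify()] on the feature sets
#' of [assemble_feature_sets()] and tabulating the four metrics.
#'
#' @param table Cohort feature table (see [assemble_feature_sets()]).
#' @inheritParams crossval_classify
#' @return List with `reports` (per set) and `summary` (data.frame:
#'   set, n_features, accuracy, sensitivity, specificity, auc).
#' @export
classify_feature_sets <- function(table, c = 1, n_folds = 10,
                                  pca_variance = 0.95, seed = 1,
                                  positive = NULL) {
  fs <- assemble_feature_sets(table)
  sets <- c("set1", "set2", "set3", "set4")
  reports <- lapply(sets, function(s)
    crossval_classify(fs[[s]], fs$y, c = c, n_folds = n_folds,
                      pca_variance = pca_variance, seed = seed,
                      positive = positive))
  names(reports) <- sets
  summary <- data.frame(
    set = sets,
    n_features = vapply(sets, function(s) ncol(fs[[s]]), 0L),
    accuracy = vapply(reports, `[[`, 0, "accuracy"),
    sensitivity = vapply(reports, `[[`, 0, "sensitivity"),
    specificity = vapply(reports, `[[`, 0, "specificity"),
    auc = vapply(reports, `[[`, 0, "auc"),
    row.names = NULL
  )
  list(reports = reports, summary = summary)
}
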