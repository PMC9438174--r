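#' Evaluate a transcript set by random-forest day classification
#'
#' Trains a random forest to predict the differentiation day of each sample
#' from the expression of a transcript subset, under stratified k-fold
#' cross-validation. With only tens of samples a single fold split carries
#' appreciable split noise, so the cross-validation is repeated `n_repeats`
#' times with seeded re-splits and the pooled out-of-fold class
#' probabilities are averaged across repeats before scoring.
#' Discrimination is summarized as a multi-class one-vs-rest AUC,
#' macro-averaged by default (micro-averaging over all sample-class
#' indicator pairs is available). Better filter stages should yield higher
#' AUC from fewer transcripts.
#'
#' @param ds An `expression_dataset`.
#' @param ids Non-empty transcript subset to use as predictors.
#' @param n_folds Cross-validation folds (default 10); silently reduced with
#'   a warning when a class has fewer samples than folds.
#' @param n_trees Trees per forest (default 500).
#' @param n_repeats Repetitions of the cross-validation with fresh seeded
#'   splits (default 3); probabilities are averaged across repeats.
#' @param seed Integer seed; fold assignment and forests are reproducible.
#' @param stage_name Label carried into reports.
#' @param average `"macro"` (default) or `"micro"` AUC aggregation.
#' @return A `stage_eval` list: `stage_name`, `n_observations` (samples x
#'   transcripts), `auc`, `per_class_auc`, `roc_points` (micro-pooled fpr/tpr
#'   data frame from (0,0) to (1,1)), `n_folds_used`, `seed`.
#' @export
evaluate_stage <- function(ds, ids, n_folds = 10, n_trees = 500,
                           n_repeats = 3, seed = 1, stage_name = "stage",
                           average = c("macro", "micro")) {
  average <- match.arg(average)
  if (!length(ids)) stop("transcript subset must be non-empty")
  sub <- subset_transcripts(ds, ids)
  y <- factor(sub$samples$day)
  if (nlevels(y) < 2) stop("need >= 2 day classes")
  x <- t(sub$values)
  min_class <- min(table(y))
  k <- min(n_folds, min_class)
  if (k < n_folds) {
    warning("reducing folds from ", n_folds, " to ", k,
            " (smallest class has ", min_class, " samples)")
  }
  if (k < 2) stop("smallest class must have >= 2 samples for cross-validation")
  set.seed(seed)
  aucs_by_class <- matrix(NA_real_, n_repeats, nlevels(y),
                          dimnames = list(NULL, levels(y)))
  micro_aucs <- numeric(n_repeats)
  micro_roc <- NULL
  lab <- as.integer(as.vector(outer(y, levels(y), "==")))
  for (rep_i in seq_len(n_repeats)) {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      ix <- which(y == lv)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
    prob <- matrix(0, length(y), nlevels(y),
                   dimnames = list(NULL, levels(y)))
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- randomForest::randomForest(x[tr, , drop = FALSE],
                                        droplevels(y[tr]), ntree = n_trees)
      p <- stats::predict(fit, x[!tr, , drop = FALSE], type = "prob")
      prob[!tr, colnames(p)] <- p
    }
    aucs_by_class[rep_i, ] <- vapply(levels(y), function(cl) {
      resp <- as.integer(y == cl)
      if (length(unique(resp)) < 2) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, prob[, cl], quiet = TRUE,
                                     direction = "<")))
    }, numeric(1))
    rr <- pROC::roc(lab, as.vector(prob), quiet = TRUE, direction = "<")
    micro_aucs[rep_i] <- as.numeric(pROC::auc(rr))
    if (rep_i == 1L) micro_roc <- rr  # ROC curve shown for the first repeat
  }
  per_class <- colMeans(aucs_by_class)
  auc <- if (average == "macro") mean(per_class, na.rm = TRUE) else
    mean(micro_aucs)
  co <- pROC::coords(micro_roc, "all", ret = c("specificity", "sensitivity"),
                     transpose = FALSE)
  roc_points <- data.frame(fpr = rev(1 - co$specificity),
                           tpr = rev(co$sensitivity))
  structure(list(stage_name = stage_name,
                 n_observations = nrow(x) * ncol(x),
                 auc = auc, per_class_auc = per_class,
                 roc_points = roc_points, n_folds_used = k, seed = seed,
                 average = average, n_trees = n_trees,
                 n_repeats = n_repeats),
            class = "stage_eval")
}

#' @export
print.stage_eval <- function(x, ...) {
  cat(sprintf("stage_eval '%s': AUC=%.3f (%s, %d-fold CV, seed %d, %d obs)\n",
              x$stage_name, x$auc, x$average, x$n_folds_used, x$seed,
              x$n_observations))
  invisible(x)
}

#' Compare random-forest evaluations of successive filter stages
#'
#' @param evals List of >= 2 `stage_eval` objects.
#' @return Data frame sorted by AUC descending (ties keep input order):
#'   `stage_name`, `n_observations`, `auc`, `delta_vs_first` (AUC minus the
#'   first *input* stage's AUC).
#' @export
compare_stages <- function(evals) {
  if (length(evals) < 2) stop("compare_stages needs >= 2 stage evaluations")
  tab <- data.frame(
    stage_name = vapply(evals, `[[`, character(1), "stage_name"),
    n_observations = vapply(evals, `[[`, numeric(1), "n_observations"),
    auc = vapply(evals, `[[`, numeric(1), "auc"),
    stringsAsFactors = FALSE)
  tab$delta_vs_first <- tab$auc - tab$auc[1]
  tab <- tab[order(-tab$auc), , drop = FALSE]  # stable: ties keep input order
  rownames(tab) <- NULL
  tab
}
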