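## SVM diagnostic classifier over hub-gene expression: random class-
## stratified train/validation split, linear-kernel SVM with the cost
## chosen by seeded stratified 10-fold cross-validation, confusion /
## ROC / AUC evaluation, external-cohort prediction, resampling stability
## and covariate comparison between predicted groups. GDM is the positive
## class throughout.

#' Randomly split samples into training and validation sets
#'
#' Uniform draw without replacement within each class; everything not
#' drawn goes to the validation set. Deterministic given the seed.
#'
#' @param samples Data frame with `sample_id` and `condition`.
#' @param train_counts Named vector of per-class training counts, e.g.
#'   `c(GDM = 15, control = 12)`.
#' @param seed Integer seed.
#' @return A list of class `split_spec` with `train`, `validation`
#'   (character id vectors) and `seed`.
#' @export
split_samples <- function(samples, train_counts = c(GDM = 15, control = 12),
                          seed = 1L) {
  stopifnot(all(c("sample_id", "condition") %in% colnames(samples)))
  classes <- names(train_counts)
  totals <- table(samples$condition)[classes]
  if (anyNA(totals) || any(train_counts > totals) || any(train_counts < 1)) {
    abort("split_samples: requested counts infeasible for the class totals")
  }
  if (all(train_counts == totals)) {
    abort("split_samples: validation set would be empty")
  }
  train <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      ids <- samples$sample_id[samples$condition == cl]
      ids[sample.int(length(ids), train_counts[[cl]])]
    }))
  })
  validation <- setdiff(samples$sample_id, train)
  vcond <- samples$condition[match(validation, samples$sample_id)]
  if (length(unique(vcond)) < 2) {
    warnf("split_samples: validation set lacks one class")
  }
  structure(list(train = train, validation = validation, seed = seed),
            class = "split_spec")
}

## Seeded stratified fold assignment: within each class, cycle fold labels
## over a random permutation of the class members.
stratified_folds <- function(labels, folds, seed) {
  with_seed(seed, {
    assignment <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      assignment[idx[sample.int(length(idx))]] <-
        rep_len(seq_len(folds), length(idx))
    }
    assignment
  })
}

#' Train the SVM diagnostic classifier
#'
#' Features are z-scored with parameters learned on the training data
#' only. A linear-kernel SVM is used (appropriate when features are few
#' relative to their reliability and keeps the decision function
#' interpretable); the cost parameter is selected from `cost_grid` by the
#' same seeded stratified `folds`-fold cross-validation that reports the
#' final `cv_accuracy` (mean over fold accuracies; ties in cost prefer the
#' smaller value).
#'
#' @param x Numeric matrix, samples in rows, hub genes in columns.
#' @param labels Factor or character of `"GDM"` / `"control"` per row.
#' @param folds Number of cross-validation folds.
#' @param cost_grid Candidate SVM cost values.
#' @param seed Seed for the fold assignment.
#' @return An object of class `gdm_svm`: the fitted e1071 model plus the
#'   gene list, scaler parameters, selected cost, `cv_accuracy` and the
#'   per-cost CV table.
#' @export
train_svm <- function(x, labels, folds = 10,
                      cost_grid = c(0.01, 0.1, 1, 10), seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) abort("train_svm: label length mismatch")
  if (length(unique(labels)) < 2) {
    abort("train_svm: training data contains a single class")
  }
  if (nrow(x) < folds) abort("train_svm: fewer samples than folds")
  y <- factor(labels, levels = c("control", "GDM"))
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  fold_id <- stratified_folds(labels, folds, seed)
  cv_acc <- vapply(cost_grid, function(cost) {
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      te <- !tr
      if (!any(te)) return(NA_real_)
      if (length(unique(y[tr])) < 2) return(NA_real_)
      fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE)
      mean(stats::predict(fit, xs[te, , drop = FALSE]) == y[te])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_acc)   # first max: smaller cost wins ties
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost_grid[best],
                    scale = FALSE)
  structure(list(svm = fit, genes = colnames(x), center = center,
                 scale = scale_, cost = cost_grid[best],
                 cv_accuracy = unname(cv_acc[best]),
                 cv_table = data.frame(cost = cost_grid, cv_accuracy = cv_acc),
                 folds = folds, fold_seed = seed, positive = "GDM"),
            class = "gdm_svm")
}

#' @export
print.gdm_svm <- function(x, ...) {
  cat(sprintf("gdm_svm: linear SVM on %d genes (cost %g), %d-fold CV accuracy %.3f\n",
              length(x$genes), x$cost, x$folds, x$cv_accuracy))
  invisible(x)
}

## Continuous decision scores oriented so that larger means more GDM-like.
decision_scores <- function(model, x) {
  stopifnot(inherits(model, "gdm_svm"))
  x <- as.matrix(x)
  missing_genes <- setdiff(model$genes, colnames(x))
  if (length(missing_genes)) {
    abort("feature alignment: gene(s) absent from the data: %s",
          paste(missing_genes, collapse = ", "))
  }
  x <- x[, model$genes, drop = FALSE]
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  pred <- stats::predict(model$svm, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- dv[, 1]
  ## e1071 labels the decision column "first/second"; positive favors first
  if (!startsWith(colnames(dv)[1], model$positive)) score <- -score
  names(score) <- rownames(x)
  score
}

#' Predict class labels
#'
#' @param object A `gdm_svm` model.
#' @param newdata Numeric matrix, samples in rows, containing the model's
#'   genes as columns.
#' @param ... Unused.
#' @return Character vector of `"GDM"` / `"control"` predictions.
#' @export
predict.gdm_svm <- function(object, newdata, ...) {
  score <- decision_scores(object, newdata)
  ifelse(score > 0, "GDM", "control")
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney formulation: the probability a random positive scores
#' above a random negative, with half credit for ties.
#'
#' @param scores Numeric decision scores.
#' @param labels `"GDM"` / `"control"` (or logical, `TRUE` = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "GDM"
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("auc_score: need both classes")
  r <- rank(scores)                      # midranks: ties share credit
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the observed scores, from
#' "everything negative" to "everything positive".
#'
#' @inheritParams auc_score
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "GDM"
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !pos) / max(sum(!pos), 1),
      tpr = sum(pred & pos) / max(sum(pos), 1))
  }, c(fpr = 0, tpr = 0)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Evaluate the classifier on a labelled data set
#'
#' Confusion counts at the model's decision threshold (GDM positive), the
#' derived accuracy / sensitivity / specificity, the ROC curve from the
#' continuous decision scores, and the rank-based AUC.
#'
#' @param model A `gdm_svm`.
#' @param x Numeric matrix, samples in rows, containing the model's genes
#'   (a missing gene raises a feature-alignment error).
#' @param labels True `"GDM"` / `"control"` labels per row.
#' @return A list of class `eval_report`: `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `roc` (data frame), `auc`,
#'   `scores`, `predicted`.
#' @export
evaluate <- function(model, x, labels) {
  labels <- as.character(labels)
  score <- decision_scores(model, x)
  predicted <- ifelse(score > 0, "GDM", "control")
  pos <- labels == "GDM"
  tp <- sum(predicted == "GDM" & pos)
  fp <- sum(predicted == "GDM" & !pos)
  tn <- sum(predicted == "control" & !pos)
  fn <- sum(predicted == "control" & pos)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(labels),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    roc = roc_points(score, labels),
    auc = if (any(pos) && any(!pos)) auc_score(score, labels) else NA_real_,
    scores = score, predicted = predicted
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %s\n",
    x$accuracy, x$sensitivity, x$specificity,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Resampling stability on known-normal samples
#'
#' Repeatedly draws `floor(frac * n)` of the known-normal samples and
#' counts how many the model calls GDM; a stable model concentrates the
#' distribution at zero.
#'
#' @param model A `gdm_svm`.
#' @param x Numeric matrix of known-normal samples (rows), containing the
#'   model's genes.
#' @param frac Fraction drawn per replicate.
#' @param reps Number of replicates.
#' @param seed Seed.
#' @return A list with `counts` (misclassified count per replicate),
#'   `histogram` (table over counts) and `mode` (most frequent count).
#' @export
stability_resample <- function(model, x, frac = 0.5, reps = 1000, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("stability_resample: need at least 2 samples")
  n_draw <- max(1L, floor(frac * nrow(x)))
  score_all <- decision_scores(model, x)   # scores are per-sample: precompute
  counts <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(nrow(x), n_draw)
      sum(score_all[idx] > 0)
    }, integer(1))
  })
  hist <- table(counts)
  list(counts = counts, histogram = hist,
       mode = as.integer(names(hist)[which.max(hist)]))
}

#' Compare covariates between predicted groups
#'
#' Two-sample pooled t-test per covariate between the samples predicted
#' GDM and those predicted normal.
#'
#' @param predictions Character vector of `"GDM"` / `"control"`
#'   predictions.
#' @param covariates Data frame of numeric covariates (e.g. age, bmi), one
#'   row per sample in the same order.
#' @return Data frame with per-covariate group means, `t`, `df`, `p` and a
#'   `computable` flag (FALSE when a predicted group is empty or too
#'   small).
#' @export
compare_covariates <- function(predictions, covariates) {
  predictions <- as.character(predictions)
  if (nrow(covariates) != length(predictions)) {
    abort("compare_covariates: row count mismatch")
  }
  g1 <- predictions == "GDM"
  out <- lapply(names(covariates), function(v) {
    x1 <- covariates[[v]][g1]
    x2 <- covariates[[v]][!g1]
    if (length(x1) < 2 || length(x2) < 2) {
      return(data.frame(covariate = v, mean_pred_gdm = mean(x1),
                        mean_pred_normal = mean(x2), t = NA_real_,
                        df = NA_real_, p = NA_real_, computable = FALSE,
                        stringsAsFactors = FALSE))
    }
    tt <- t_test_summary(summary_stat(x1), summary_stat(x2))
    data.frame(covariate = v, mean_pred_gdm = mean(x1),
               mean_pred_normal = mean(x2), t = tt$t, df = tt$df, p = tt$p,
               computable = TRUE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
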