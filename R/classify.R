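# AD-vs-NC discrimination: degree-2 polynomial-kernel soft-margin SVM,
# stratified subject-level 6-fold cross-validation, confusion matrix, ROC
# and trapezoidal AUC. AD is the positive class throughout.

#' Classifier specification
#'
#' @param degree Polynomial kernel degree (default 2).
#' @param cost Soft-margin box constraint C (default 1).
#' @param gamma,coef0 Kernel scale and offset: `(gamma * <u, v> + coef0)^degree`.
#'   `gamma = NULL` (default) uses the SVM library convention
#'   `1 / n_features`, which keeps kernel values O(1) for standardized
#'   features of any dimension; `coef0` defaults to 1.
#' @param standardize Z-score each feature using training-fold statistics
#'   (default `TRUE`; constant features get unit divisor).
#' @param n_folds Number of CV folds (default 6).
#' @param seed Seed of the fold partition.
#' @return A list of class `meg_classifier_spec`.
#' @export
classifier_spec <- function(degree = 2, cost = 1, gamma = NULL, coef0 = 1,
                            standardize = TRUE, n_folds = 6, seed = 1) {
  stopifnot(degree >= 1, cost > 0, n_folds >= 2)
  structure(list(degree = degree, cost = cost, gamma = gamma, coef0 = coef0,
                 standardize = standardize, n_folds = n_folds, seed = seed),
            class = "meg_classifier_spec")
}

#' Fit a polynomial-kernel SVM
#'
#' Soft-margin SVM in the degree-2 polynomial kernel space (libsvm via
#' e1071). Standardization parameters are estimated on the training data
#' only and stored with the model. Decision scores are oriented so positive
#' favors AD.
#'
#' @param x `[subjects x features]` numeric matrix, no missing values.
#' @param y Labels (`"AD"`/`"NC"`), both classes present.
#' @param spec A [classifier_spec()].
#' @return A list of class `meg_svm` with `model`, `center`, `scale`,
#'   `spec`.
#' @export
fit_svm <- function(x, y, spec = classifier_spec()) {
  y <- factor(as.character(y), levels = c("NC", "AD"))
  if (length(unique(y)) < 2) {
    stop_megspect("training set must contain both classes",
                  "megspect_single_class")
  }
  stopifnot(is.matrix(x), all(is.finite(x)), nrow(x) == length(y))
  if (spec$standardize) {
    center <- colMeans(x)
    # population SD: invariant under duplicating the training set
    scl <- sqrt(colMeans(sweep(x, 2, center)^2))
    scl[scl == 0 | !is.finite(scl)] <- 1
    x <- sweep(sweep(x, 2, center), 2, scl, `/`)
  } else {
    center <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  gamma <- spec$gamma %||% (1 / ncol(x))
  model <- e1071::svm(x, y, type = "C-classification",
                      kernel = "polynomial", degree = spec$degree,
                      gamma = gamma, coef0 = spec$coef0,
                      cost = spec$cost, scale = FALSE, tolerance = 1e-8)
  structure(list(model = model, center = center, scale = scl, spec = spec,
                 levels = levels(y)),
            class = "meg_svm")
}

#' Decision scores and predicted labels
#'
#' @param object A `meg_svm`.
#' @param newdata `[subjects x features]` matrix.
#' @param ... Unused.
#' @return Data frame with `label` (factor NC/AD) and `score` (signed real;
#'   positive favors AD).
#' @export
predict.meg_svm <- function(object, newdata, ...) {
  x <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  pr <- stats::predict(object$model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # libsvm labels the decision column "A/B": positive score favors A.
  pos_first <- strsplit(colnames(dv)[1], "/")[[1]][1] == "AD"
  score <- if (pos_first) dv[, 1] else -dv[, 1]
  data.frame(label = factor(as.character(pr), levels = c("NC", "AD")),
             score = unname(score))
}

# Stratified fold assignment: within each class, balanced fold sizes,
# shuffled under the partition seed.
stratified_folds <- function(y, n_folds, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < n_folds) {
        stop_megspect(sprintf(
          "class %s has fewer subjects (%d) than folds (%d)",
          cl, length(idx), n_folds), "megspect_fold_infeasible")
      }
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  fold
}

#' ROC curve from decision scores
#'
#' Threshold sweep over the pooled scores (AD positive): one point per
#' distinct threshold plus the (0,0) and (1,1) endpoints; FPR and TPR are
#' non-decreasing along the curve.
#'
#' @param score Numeric decision scores, higher favors AD.
#' @param label `"AD"`/`"NC"` per score.
#' @return Data frame `fpr`, `tpr`, ordered from (0,0) to (1,1).
#' @export
roc_curve <- function(score, label) {
  pos <- label == "AD"
  stopifnot(any(pos), any(!pos))
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse ties: keep the last point of each tied score
  keep <- c(diff(score[ord]) != 0, TRUE)
  data.frame(fpr = c(0, fp[keep] / sum(!pos)),
             tpr = c(0, tp[keep] / sum(pos)))
}

#' Area under the ROC curve (trapezoid rule)
#'
#' @param roc A data frame from [roc_curve()], or `NULL` to compute from
#'   `score`/`label`.
#' @param score,label Alternative raw inputs.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc = NULL, score = NULL, label = NULL) {
  if (is.null(roc)) roc <- roc_curve(score, label)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

confusion_counts <- function(truth, pred) {
  tp <- sum(truth == "AD" & pred == "AD")
  fn <- sum(truth == "AD" & pred == "NC")
  tn <- sum(truth == "NC" & pred == "NC")
  fp <- sum(truth == "NC" & pred == "AD")
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Stratified k-fold cross-validation of the SVM
#'
#' Subject-level stratified partition (seeded); each subject is predicted
#' exactly once by a model never trained on it, with standardization
#' re-estimated inside every training fold. Pooled out-of-fold decision
#' scores define the ROC; AUC by the trapezoid rule.
#'
#' @param x `[subjects x features]` matrix (or a `meg_features` object).
#' @param y Labels (ignored for `meg_features`).
#' @param spec A [classifier_spec()].
#' @return A list of class `meg_cv_report`: `predictions` (subject, truth,
#'   fold, predicted label, score), `confusion` (TP/FP/TN/FN, AD positive),
#'   `accuracy`, `sensitivity`, `specificity`, `roc`, `auc`, `spec`.
#' @export
cross_validate <- function(x, y = NULL, spec = classifier_spec()) {
  if (inherits(x, "meg_features")) {
    y <- x$group
    sid <- x$subject_id
    x <- x$x
  } else {
    sid <- rownames(x) %||% sprintf("S%03d", seq_len(nrow(x)))
  }
  y <- factor(as.character(y), levels = c("NC", "AD"))
  fold <- stratified_folds(y, spec$n_folds, spec$seed)
  pred_label <- factor(rep(NA_character_, length(y)), levels = c("NC", "AD"))
  score <- numeric(length(y))
  for (k in seq_len(spec$n_folds)) {
    tr <- fold != k
    fit <- fit_svm(x[tr, , drop = FALSE], y[tr], spec)
    pr <- predict(fit, x[!tr, , drop = FALSE])
    pred_label[!tr] <- pr$label
    score[!tr] <- pr$score
  }
  cm <- confusion_counts(y, pred_label)
  n <- length(y)
  roc <- roc_curve(score, as.character(y))
  structure(list(
    predictions = data.frame(subject_id = sid, truth = y, fold = fold,
                             predicted = pred_label, score = score,
                             stringsAsFactors = FALSE),
    confusion = cm,
    accuracy = (cm$TP + cm$TN) / n,
    sensitivity = cm$TP / (cm$TP + cm$FN),
    specificity = cm$TN / (cm$TN + cm$FP),
    roc = roc, auc = roc_auc(roc), spec = spec),
    class = "meg_cv_report")
}

#' @export
print.meg_cv_report <- function(x, ...) {
  cm <- x$confusion
  cat(sprintf(
    "<meg_cv_report> %d-fold CV: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
    x$spec$n_folds, x$accuracy, x$sensitivity, x$specificity, x$auc))
  cat(sprintf("  confusion (AD positive): TP %d  FP %d  TN %d  FN %d\n",
              cm$TP, cm$FP, cm$TN, cm$FN))
  invisible(x)
}
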