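#' ROC curve and trapezoidal AUC from continuous scores
#'
#' Sweeps a threshold over the unique score values (ties grouped), recording
#' (FPR, TPR) from (0, 0) to (1, 1), and integrates by the trapezoid rule.
#' The resulting AUC satisfies the rank-statistic identity
#' `AUC = U / (n1 n2)` with U the Mann-Whitney statistic of the positive
#' scores, and is invariant under strictly monotone transforms of the
#' scores.
#'
#' @param scores Numeric scores; larger = more positive-looking.
#' @param truth Binary ground truth (0/1), same length.
#' @return List with `points` (data.frame `threshold, fpr, tpr`) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth))
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L))) stop("truth must be binary 0/1",
                                       call. = FALSE)
  n_pos <- sum(truth == 1L); n_neg <- sum(truth == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative observation",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(t)[grp_end]
  fp <- cumsum(1L - t)[grp_end]
  points <- data.frame(threshold = c(Inf, s[grp_end]),
                       fpr = c(0, fp / n_neg),
                       tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) *
               (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  list(points = points, auc = auc)
}

#' Classifier settings
#'
#' @param train_frac Fraction of ROIs in the stratified training split.
#' @param ntree Number of random-forest trees.
#' @param svm_cost Soft-margin cost of the radial-kernel SVM.
#' @param svm_gamma Radial kernel width; `NULL` = `1 / n_features`.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(train_frac = 0.8, ntree = 100L,
                              svm_cost = 1, svm_gamma = NULL) {
  stopifnot(train_frac > 0, train_frac < 1)
  structure(list(train_frac = train_frac, ntree = as.integer(ntree),
                 svm_cost = svm_cost, svm_gamma = svm_gamma),
            class = "classifier_config")
}

#' Train and evaluate the three reference classifiers
#'
#' Splits the ROI table into stratified train/test sets (default 80/20,
#' preserving the class balance), imputes undefined feature values by the
#' training-set median, standardizes features with training-set mean and SD
#' only, then fits binomial logistic regression, a radial-kernel SVM and a
#' random forest. Each model is scored on the held-out set: accuracy of the
#' hard class calls, and ROC/AUC from continuous scores (predicted
#' probability for LR and RF, decision value for the SVM).
#'
#' @param features Feature data.frame from [extract_features()] with a
#'   binary `group` column.
#' @param seed Integer seed controlling the split and the stochastic fits.
#' @param config A [classifier_config()].
#' @param models Subset of
#'   `c("logistic_regression", "svm", "random_forest")`.
#' @return A list of class `classifier_report_list`, one
#'   `classifier_report` per model (fields `model`, `accuracy`, `auc`,
#'   `roc`, `seed`, `n_train`, `n_test`).
#' @export
train_and_evaluate <- function(features, seed = 1L,
                               config = classifier_config(),
                               models = c("logistic_regression", "svm",
                                          "random_forest")) {
  models <- match.arg(models, several.ok = TRUE)
  feat_cols <- intersect(FEATURE_NAMES, names(features))
  if (length(feat_cols) == 0L) stop("no feature columns found",
                                    call. = FALSE)
  y <- as.integer(features$group)
  if (length(unique(y)) < 2L) stop("need both classes present",
                                   call. = FALSE)
  if (min(table(y)) < 20L) {
    stop("need at least 20 ROIs per class", call. = FALSE)
  }
  X <- as.matrix(features[, feat_cols])

  set.seed(seed)
  train_idx <- unlist(lapply(c(0L, 1L), function(g) {
    idx <- which(y == g)
    sample(idx, floor(config$train_frac * length(idx)))
  }))
  test_idx <- setdiff(seq_along(y), train_idx)

  # impute undefined values by training-set median, then standardize with
  # training-set statistics only (no test leakage)
  med <- apply(X[train_idx, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  for (j in seq_along(feat_cols)) X[is.na(X[, j]), j] <- med[j]
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sdv <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  ztr <- Z[train_idx, , drop = FALSE]; yte <- y[test_idx]
  zte <- Z[test_idx, , drop = FALSE]; ytr <- y[train_idx]

  fit_one <- function(model) {
    if (model == "logistic_regression") {
      df_tr <- data.frame(as.data.frame(ztr), y = ytr)
      fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                         data = df_tr))
      scores <- suppressWarnings(
        stats::predict(fit, newdata = as.data.frame(zte),
                       type = "response"))
      pred <- as.integer(scores > 0.5)
    } else if (model == "svm") {
      gamma <- config$svm_gamma %||% (1 / ncol(ztr))
      fit <- e1071::svm(x = ztr, y = factor(ytr, levels = c(0L, 1L)),
                        kernel = "radial", cost = config$svm_cost,
                        gamma = gamma, scale = FALSE)
      pr <- stats::predict(fit, zte, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      # decision values are signed toward the first label of the colname
      dv_name <- colnames(attr(pr, "decision.values"))[1]
      scores <- if (startsWith(dv_name, "1")) dv else -dv
      pred <- as.integer(as.character(pr))
    } else {
      fit <- randomForest::randomForest(
        x = ztr, y = factor(ytr, levels = c(0L, 1L)),
        ntree = config$ntree)
      scores <- stats::predict(fit, zte, type = "prob")[, "1"]
      pred <- as.integer(as.character(stats::predict(fit, zte)))
    }
    roc <- roc_auc(scores, yte)
    structure(list(model = model,
                   accuracy = mean(pred == yte),
                   auc = roc$auc, roc = roc$points, seed = seed,
                   n_train = length(train_idx), n_test = length(test_idx)),
              class = "classifier_report")
  }
  reports <- lapply(models, fit_one)
  names(reports) <- models
  structure(reports, class = "classifier_report_list")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%-20s accuracy %.3f  AUC %.3f  (train %d / test %d)\n",
              x$model, x$accuracy, x$auc, x$n_train, x$n_test))
  invisible(x)
}

#' @export
print.classifier_report_list <- function(x, ...) {
  cat("Held-out classifier performance\n")
  for (r in x) print(r)
  invisible(x)
}

#' @export
plot.classifier_report <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "False positive rate",
         ylab = "True positive rate", main = "ROC", ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  }
  graphics::lines(x$roc$fpr, x$roc$tpr, col = col)
  invisible(x)
}

#' @export
plot.classifier_report_list <- function(x, ...) {
  for (i in seq_along(x)) plot(x[[i]], add = i > 1, col = i, ...)
  graphics::legend("bottomright", legend = vapply(x, `[[`, "", "model"),
                   col = seq_along(x), lty = 1, bty = "n")
  invisible(x)
}

#' Evaluate a binary human rater against ground truth
#'
#' Builds the confusion table of a rater's 0/1 calls, and the single
#' operating point ROC: the curve runs (0,0) -> (FPR, TPR) -> (1,1), whose
#' trapezoidal area is `(sensitivity + specificity) / 2`.
#'
#' @param rating Rater's calls, 0/1.
#' @param truth Ground-truth labels, 0/1, same length.
#' @return A `rater_evaluation`: counts `tp, fp, tn, fn`, `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, and the two-segment ROC `points`.
#' @export
evaluate_rater <- function(rating, truth) {
  rating <- as.integer(rating); truth <- as.integer(truth)
  if (length(rating) != length(truth)) {
    stop("rating and truth must have equal length", call. = FALSE)
  }
  if (!all(rating %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L))) {
    stop("rating and truth must be binary 0/1", call. = FALSE)
  }
  rater_from_counts(tp = sum(rating == 1L & truth == 1L),
                    fp = sum(rating == 1L & truth == 0L),
                    tn = sum(rating == 0L & truth == 0L),
                    fn = sum(rating == 0L & truth == 1L))
}

#' Rater evaluation from a confusion table or printed rates
#'
#' `rater_from_counts()` builds the evaluation directly from the four
#' confusion counts. `rater_from_rates()` reconstructs the counts from a
#' reported overall accuracy and true-positive rate under a known class
#' design (`n_pos` positives, `n_neg` negatives):
#' `TP = round(tp_rate * n_pos)`, total correct
#' `= round(accuracy * (n_pos + n_neg))`, `TN = correct - TP`.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @param accuracy Overall fraction correct as reported.
#' @param tp_rate Fraction of positives called positive.
#' @param n_pos,n_neg Number of true positives/negatives presented.
#' @return A `rater_evaluation` (see [evaluate_rater()]).
#' @export
rater_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0,
            tp + fn > 0, tn + fp > 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = (tp + tn) / (tp + fp + tn + fn),
         sensitivity = sens, specificity = spec,
         auc = (sens + spec) / 2,
         points = data.frame(fpr = c(0, 1 - spec, 1),
                             tpr = c(0, sens, 1))),
    class = "rater_evaluation"
  )
}

#' @rdname rater_from_counts
#' @export
rater_from_rates <- function(accuracy, tp_rate, n_pos, n_neg) {
  tp <- as.integer(round(tp_rate * n_pos))
  correct <- as.integer(round(accuracy * (n_pos + n_neg)))
  tn <- correct - tp
  n_pos <- as.integer(n_pos); n_neg <- as.integer(n_neg)
  if (tn < 0 || tn > n_neg) {
    stop("reported accuracy and TP rate are inconsistent with the design",
         call. = FALSE)
  }
  rater_from_counts(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' @export
print.rater_evaluation <- function(x, ...) {
  cat("Binary rater evaluation\n",
      sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn),
      sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity),
      sprintf("  single-point AUC %.3f\n", x$auc), sep = "")
  invisible(x)
}

#' Read a rater ratings CSV (`roi_id,rating,truth`)
#'
#' @param path CSV path.
#' @return Data.frame with `roi_id`, `rating`, `truth`.
#' @export
read_ratings <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("roi_id", "rating", "truth")
  missing <- setdiff(required, names(r))
  if (length(missing)) {
    stop("ratings file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  r
}
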