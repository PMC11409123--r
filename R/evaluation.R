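#' Confusion counts of a binary classification
#'
#' @param truth,predictions Binary (0/1) vectors of equal positive length.
#' @return A list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`
#'   (their sum equals the vector length).
#' @export
confusion_counts <- function(truth, predictions) {
  if (length(truth) != length(predictions) || length(truth) < 1L) {
    fh_stop("truth and predictions must have equal length >= 1",
            "firehawkdr_input_error")
  }
  if (!all(truth %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    fh_stop("truth and predictions must be binary 0/1",
            "firehawkdr_input_error")
  }
  structure(list(tp = sum(truth == 1 & predictions == 1),
                 tn = sum(truth == 0 & predictions == 0),
                 fp = sum(truth == 0 & predictions == 1),
                 fn = sum(truth == 1 & predictions == 0)),
            class = "confusion_counts")
}

#' Percentage metrics from confusion counts
#'
#' Computes precision, specificity, sensitivity (recall), accuracy and F1 on
#' the 0-100 scale:
#' \deqn{Precision = 100\,TP/(TP+FP)}
#' \deqn{Specificity = 100\,TN/(TN+FP)}
#' \deqn{Sensitivity = 100\,TP/(TP+FN)}
#' \deqn{Accuracy = 100\,(TP+TN)/(TP+TN+FP+FN)}
#' \deqn{F1 = 2\,Precision \cdot Sensitivity/(Precision+Sensitivity)}
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' coerced to 0 or 100.
#'
#' @param counts A [confusion_counts()] or a list with fields tp/tn/fp/fn.
#' @return A list of class `metrics_report` with the five metrics (and
#'   `auc = NA`, fillable by [auc_score()]).
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  total <- tp + tn + fp + fn
  if (total == 0) {
    fh_stop("confusion counts sum to zero", "firehawkdr_input_error")
  }
  div <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  precision <- div(tp, tp + fp)
  specificity <- div(tn, tn + fp)
  sensitivity <- div(tp, tp + fn)
  accuracy <- 100 * (tp + tn) / total
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) {
    NA_real_
  } else {
    2 * precision * sensitivity / (precision + sensitivity)
  }
  structure(list(precision = precision, specificity = specificity,
                 sensitivity = sensitivity, accuracy = accuracy, f1 = f1,
                 auc = NA_real_),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat("<metrics_report>\n")
  cat("  precision:  ", fmt(x$precision), "%\n")
  cat("  specificity:", fmt(x$specificity), "%\n")
  cat("  sensitivity:", fmt(x$sensitivity), "%\n")
  cat("  accuracy:   ", fmt(x$accuracy), "%\n")
  cat("  F1:         ", fmt(x$f1), "%\n")
  cat("  AUC:        ", fmt(x$auc), "\n")
  invisible(x)
}

#' Rank-based AUC
#'
#' The probability that a uniformly drawn positive receives a higher score
#' than a uniformly drawn negative, ties counted one half (the rank-sum /
#' trapezoidal-equivalent estimator).
#'
#' @param truth Binary 0/1 vector; both classes must be present.
#' @param scores Numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auc_score <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), all(truth %in% c(0, 1)))
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)  # average ranks handle ties as one half
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold split
#'
#' Shuffles each class independently and deals it into `k` folds of
#' near-equal size, so per-class counts across folds differ by at most one.
#'
#' @param labels Binary 0/1 label vector.
#' @param k Number of folds, `>= 2`; every class must have at least `k`
#'   members.
#' @param seed Optional integer seed.
#' @return A list of `k` disjoint integer index vectors whose union is
#'   `seq_along(labels)`.
#' @export
stratified_kfold <- function(labels, k, seed = NULL) {
  stopifnot(all(labels %in% c(0, 1)))
  if (!is_count(k, 2L)) {
    fh_stop("k must be an integer >= 2", "firehawkdr_config_error")
  }
  if (any(table(labels) < k)) {
    fh_stop("every class needs at least k members", "firehawkdr_config_error")
  }
  with_seed(seed, {
    folds <- rep(list(integer(0)), k)
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      sizes <- rep(length(idx) %/% k, k)
      extra <- length(idx) %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      at <- cumsum(c(0L, sizes))
      for (f in seq_len(k)) {
        folds[[f]] <- c(folds[[f]], idx[(at[f] + 1L):at[f + 1L]])
      }
    }
    lapply(folds, sort)
  })
}

#' Average a list of metric reports
#'
#' Arithmetic mean per metric across folds; undefined (`NA`) entries are
#' excluded from the mean and counted in the `n_undefined` attribute.
#'
#' @param reports List of `metrics_report` objects.
#' @return A `metrics_report` of means.
#' @export
mean_metrics <- function(reports) {
  fields <- c("precision", "specificity", "sensitivity", "accuracy", "f1",
              "auc")
  out <- lapply(fields, function(f) {
    v <- vapply(reports, function(r) r[[f]], numeric(1))
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  names(out) <- fields
  undef <- sum(vapply(reports, function(r) {
    sum(vapply(fields, function(f) is.na(r[[f]]), logical(1)))
  }, numeric(1)))
  structure(c(out, list(n_undefined = undef)), class = "metrics_report")
}

#' Stratified k-fold cross-validation of the classifier pipeline
#'
#' For every fold the remaining folds form the training split; SMOTE
#' balancing (when enabled) and classifier training happen strictly inside
#' that split, so no test-fold sample ever leaks into neighbor search or
#' fitting. The held-out fold is scored with [classification_metrics()] and
#' [auc_score()].
#'
#' @param set A [labeled_vector_set()] of real samples.
#' @param k Number of folds.
#' @param spec A [classifier_spec()].
#' @param hyper A [hyperparameters()] used for every fold's model.
#' @param smote Logical: balance each training split by [smote_balance()]?
#' @param k_smote Neighborhood size for SMOTE.
#' @param seed Integer seed; folds, SMOTE and training use child seeds.
#' @return A list of class `cv_result`: `fold_reports` (per-fold
#'   `metrics_report`), `mean_report`, `folds`.
#' @export
cross_validate <- function(set, k, spec, hyper = hyperparameters(),
                           smote = TRUE, k_smote = 5L, seed = 1L) {
  stopifnot(inherits(set, "labeled_vector_set"))
  folds <- stratified_kfold(set$labels, k, seed = derive_seed(seed, "folds"))
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(set$labels), test_idx)
    stopifnot(length(intersect(train_idx, test_idx)) == 0L)  # leakage guard
    train <- labeled_vector_set(set$vectors[train_idx, , drop = FALSE],
                                set$labels[train_idx])
    if (smote) {
      train <- smote_balance(train, k = k_smote,
                             seed = derive_seed(seed, paste0("smote/", f)))
    }
    model <- train_classifier(spec, train$vectors, train$labels, hyper,
                              seed = derive_seed(seed, paste0("train/", f)))
    pred <- predict(model, set$vectors[test_idx, , drop = FALSE])
    rep_f <- classification_metrics(
      confusion_counts(set$labels[test_idx], pred$labels))
    rep_f$auc <- auc_score(set$labels[test_idx], pred$scores)
    reports[[f]] <- rep_f
  }
  structure(list(fold_reports = reports, mean_report = mean_metrics(reports),
                 folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", length(x$fold_reports), "folds; mean report:\n")
  print(x$mean_report)
  invisible(x)
}
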