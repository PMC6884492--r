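# Classifier validation and walking-bout aggregation.

#' ROC curve and AUC
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels; `positive` marks the positive class.
#' @param positive Positive class label (default `"walk"`).
#' @return Data frame with `threshold`, `fpr`, `tpr`, plus attribute
#'   `auc` (trapezoidal area, equals the Mann-Whitney statistic).
#' @export
roc_curve <- function(scores, labels, positive = "walk") {
  y <- labels == positive
  if (!any(y) || all(y)) stop("both classes required for a ROC curve", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  tp <- cumsum(ys)
  fp <- cumsum(!ys)
  last <- c(diff(ss) != 0, TRUE)  # collapse tied scores
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  thr <- c(Inf, ss[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Choose the posterior threshold nearest the ideal ROC corner
#'
#' Returns the threshold whose (fpr, tpr) point minimizes the Euclidean
#' distance to (0, 1); ties resolve to the higher threshold.
#'
#' @param roc Data frame with columns `threshold`, `fpr`, `tpr`.
#' @return Scalar threshold.
#' @export
select_probability_threshold <- function(roc) {
  stopifnot(nrow(roc) > 0)
  d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  best <- which(d == min(d))
  max(roc$threshold[best])
}

confusion_metrics <- function(truth_pos, pred_pos) {
  tp <- sum(truth_pos & pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Leave-one-subject-out cross-validation of the walking classifier
#'
#' For each fold all data of one subject are held out; Davies-Bouldin
#' feature selection and feature standardization are re-run on the
#' training subjects only, so no information from the held-out subject
#' leaks into the fold's model. Held-out predictions are pooled for the
#' final confusion matrix and ROC.
#'
#' @param data Data frame with a subject column, a label column and
#'   feature columns.
#' @param feature_cols Feature column names (default: all columns except
#'   subject and label).
#' @param subject_col,label_col Column names (defaults `"subject"`,
#'   `"label"`).
#' @param positive Positive class label (default `"walk"`).
#' @param dbi_threshold Davies-Bouldin selection threshold (default 2).
#'   Folds where no feature passes fall back to the single best feature.
#' @param C,gamma SVM hyperparameters passed to [train_classifier()].
#' @return List with pooled `metrics` (accuracy, sensitivity,
#'   specificity, auc), `roc`, per-subject confusion table, pooled
#'   `predictions`, and per-fold model summaries in `folds`.
#' @export
loso_cross_validate <- function(data, feature_cols = NULL,
                                subject_col = "subject", label_col = "label",
                                positive = "walk", dbi_threshold = 2,
                                C = 1, gamma = NULL) {
  data <- as.data.frame(data)
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(data), c(subject_col, label_col))
  }
  subjects <- unique(data[[subject_col]])
  if (length(subjects) < 2) stop("need at least two subjects for LOSO", call. = FALSE)
  preds <- vector("list", length(subjects))
  folds <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    s <- subjects[k]
    test_idx <- data[[subject_col]] == s
    train <- data[!test_idx, , drop = FALSE]
    binlab <- ifelse(train[[label_col]] == positive, positive, "other")
    feats <- tryCatch(
      select_features(train[, feature_cols, drop = FALSE], binlab,
                      threshold = dbi_threshold),
      error = function(e) {
        dbi <- vapply(train[, feature_cols, drop = FALSE],
                      davies_bouldin_index, numeric(1), labels = binlab)
        names(which.min(dbi))
      }
    )
    model <- train_classifier(train[, feature_cols, drop = FALSE], binlab,
                              feature_subset = as.character(feats),
                              positive = positive, C = C, gamma = gamma)
    p <- predict(model, data[test_idx, feature_cols, drop = FALSE])
    preds[[k]] <- data.frame(
      subject = s,
      truth = data[[label_col]][test_idx] == positive,
      score = p$score, prob = p$prob, pred = p$score > 0
    )
    folds[[k]] <- list(subject = s, selected_features = as.character(feats),
                       center = model$center, scale = model$scale,
                       sv_coef = model$sv_coef, b = model$b,
                       gamma = model$gamma)
  }
  pred <- do.call(rbind, preds)
  cm <- confusion_metrics(pred$truth, pred$pred)
  roc <- roc_curve(pred$prob, ifelse(pred$truth, positive, "other"),
                   positive = positive)
  per_subject <- do.call(rbind, lapply(split(pred, pred$subject), function(d) {
    m <- confusion_metrics(d$truth, d$pred)
    data.frame(subject = d$subject[1], tp = m$tp, tn = m$tn,
               fp = m$fp, fn = m$fn, accuracy = m$accuracy)
  }))
  rownames(per_subject) <- NULL
  list(
    metrics = list(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
                   specificity = cm$specificity, auc = attr(roc, "auc")),
    roc = roc, per_subject = per_subject, predictions = pred, folds = folds
  )
}

#' Aggregate classified windows into walking bouts
#'
#' A window is kept when labeled walking and its posterior meets the
#' probability threshold; maximal runs of at least `min_windows`
#' consecutive kept windows form bouts. Windows flagged as clipped poison
#' their bout.
#'
#' @param labels Logical (or `"walk"`-valued) per-window walking labels.
#' @param posteriors Per-window posterior probabilities.
#' @param windows List of windows from [partition_windows()] (used for
#'   start/end times); may be `NULL` for index-only bouts.
#' @param prob_threshold Posterior threshold (default 0.8).
#' @param min_windows Minimum consecutive windows per bout (default 2,
#'   i.e. 8 s).
#' @param clipped Optional logical vector marking windows with clipped
#'   samples; any clipped window drops its whole bout.
#' @return List with `bouts` (list of `walking_bout`: `window_indices`,
#'   `start`, `end`, `posteriors`) and `walking_time_s`
#'   (`window_s * number of kept windows in bouts`, clipped bouts
#'   excluded).
#' @export
build_walking_bouts <- function(labels, posteriors, windows = NULL,
                                prob_threshold = 0.8, min_windows = 2,
                                clipped = NULL, window_s = 4) {
  if (is.character(labels)) labels <- labels == "walk"
  stopifnot(length(labels) == length(posteriors))
  keep <- labels & posteriors >= prob_threshold
  if (is.null(clipped)) clipped <- rep(FALSE, length(labels))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bouts <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_windows) next
    idx <- starts[i]:ends[i]
    if (any(clipped[idx])) next
    b <- list(window_indices = idx,
              start = if (!is.null(windows)) windows[[idx[1]]]$start else (idx[1] - 1) * window_s,
              end = if (!is.null(windows)) windows[[idx[length(idx)]]]$end else idx[length(idx)] * window_s,
              posteriors = posteriors[idx])
    bouts[[length(bouts) + 1]] <- structure(b, class = "walking_bout")
  }
  walking_time_s <- window_s * sum(vapply(bouts, function(b) length(b$window_indices), integer(1)))
  list(bouts = bouts, walking_time_s = walking_time_s)
}
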