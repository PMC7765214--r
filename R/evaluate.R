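#' Stratified k-fold partition
#'
#' Splits row indices into `k` disjoint folds preserving the target's class
#' proportions within one record per class. Deterministic given the seed.
#'
#' @param data Data frame containing the target column.
#' @param target Target column name.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` integer vectors partitioning `seq_len(nrow(data))`.
#' @export
stratified_folds <- function(data, target, k = 10L, seed = 1L) {
  if (k < 2L) ssbn_stop("configuration", "k must be >= 2")
  labels <- data[[target]]
  if (is.null(labels)) ssbn_stop("configuration", "target column '%s' not found", target)
  counts <- table(labels)
  if (any(counts < k)) {
    ssbn_stop("stratification",
              "class '%s' has %d member(s), fewer than k = %d",
              names(counts)[which.min(counts)], min(counts), k)
  }
  folds <- vector("list", k)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      for (j in seq_len(k)) {
        folds[[j]] <- c(folds[[j]], idx[seq(j, length(idx), by = k)])
      }
    }
  })
  lapply(folds, sort)
}

#' Classify one record with a network
#'
#' Restricts the record to the network's non-target variables (dropping
#' missing entries), computes the target posterior, and predicts the
#' argmax state with ties broken toward the negative (majority) class. If
#' the observed record is impossible under the network the prior is used
#' instead and the fallback is flagged.
#'
#' @param net A [bayesian_network()] with a target.
#' @param record Named character vector (or one-row data frame) of observed
#'   states; `NA`s are ignored.
#' @param positive_state Target state treated as positive (default: the
#'   last declared state).
#' @return List: `prediction` (target state), `score` (posterior
#'   probability of the positive state), `fallback` (logical).
#' @export
classify <- function(net, record, positive_state = NULL) {
  target <- bn_target(net)
  if (is.null(target)) ssbn_stop("configuration", "network has no target variable")
  states <- bn_states(net, target)
  positive_state <- positive_state %||% states[length(states)]
  if (is.data.frame(record)) record <- unlist(lapply(record, as.character))
  record <- record[!is.na(record)]
  record <- record[intersect(names(record), setdiff(bn_vars(net), target))]
  fallback <- FALSE
  post <- tryCatch(
    posterior(net, target, record),
    ssbn_impossible_evidence = function(e) {
      fallback <<- TRUE
      posterior(net, target, NULL)
    }
  )
  p <- as.numeric(post)
  negative <- setdiff(states, positive_state)[1L]
  best <- states[p == max(p)]
  prediction <- if (negative %in% best) negative else best[1L]
  list(prediction = prediction, score = post[[positive_state]], fallback = fallback)
}

#' Classification metrics from pooled confusion counts
#'
#' Accuracy, precision, recall and F-measure (percent) from a 2x2 confusion
#' matrix. A degenerate classifier that never predicts the positive class
#' has no defined precision or F-measure; both are reported as `NA` with
#' `degenerate = TRUE`.
#'
#' @param tp,fp,fn,tn Confusion counts.
#' @return List: `accuracy`, `precision`, `recall`, `f_measure` (percent,
#'   `NA` when undefined) and `degenerate`.
#' @examples
#' confusion_metrics(4, 1, 2, 13)
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  acc <- 100 * (tp + tn) / n
  degenerate <- (tp + fp) == 0
  prec <- if (degenerate) NA_real_ else 100 * tp / (tp + fp)
  rec <- if ((tp + fn) == 0) NA_real_ else 100 * tp / (tp + fn)
  f <- if (degenerate || is.na(rec) || (prec + rec) == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  list(accuracy = acc, precision = prec, recall = rec, f_measure = f,
       degenerate = degenerate)
}

#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Area under the ROC curve computed from midranks of the positive-class
#' scores; invariant to any monotone transformation of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param is_positive Logical vector of true class memberships.
#' @return AUC in percent.
#' @export
rank_auc <- function(scores, is_positive) {
  npos <- sum(is_positive)
  nneg <- sum(!is_positive)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores)
  100 * (sum(r[is_positive]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Cross-validated evaluation of a Bayesian-family classifier
#'
#' Stratified k-fold cross-validation of a Naive Bayes, TAN or
#' Sons-and-Spouses classifier: for each fold, the network is learned on
#' the remaining folds and the held-out records are scored with
#' [classify()]. The confusion matrix is pooled across folds
#' (micro-average), which is stable when the positive class is rare; AUC
#' uses [rank_auc()] on the pooled scores.
#'
#' @inheritParams stratified_folds
#' @param method `"nb"`, `"tan"` or `"ss"`.
#' @param config A [learner_config()].
#' @param positive_state Target state treated as positive (default: the
#'   least frequent state, i.e. the rare outcome).
#' @return An object of class `cv_metrics`: `pooled` (accuracy, precision,
#'   recall, f_measure, auc in percent, `degenerate` flag), `folds` (per-
#'   fold data frame), `confusion` counts, and `fallback_count` (records
#'   scored from the prior because their profile was impossible under the
#'   fold's network).
#' @export
evaluate_cv <- function(data, target, method = c("ss", "tan", "nb"), k = 10L,
                        seed = 1L, config = learner_config(),
                        positive_state = NULL) {
  method <- match.arg(method)
  tcol <- data[[target]]
  if (is.null(tcol)) ssbn_stop("configuration", "target column '%s' not found", target)
  if (!is.factor(tcol)) tcol <- factor(tcol)
  positive_state <- positive_state %||% names(which.min(table(tcol)))
  folds <- stratified_folds(data, target, k, seed)
  scores <- numeric(nrow(data))
  preds <- character(nrow(data))
  fallback_count <- 0L
  fold_rows <- list()
  for (j in seq_along(folds)) {
    test_idx <- folds[[j]]
    net <- learn_network(data[-test_idx, , drop = FALSE], target, method, config)
    for (i in test_idx) {
      cl <- classify(net, data[i, , drop = FALSE], positive_state)
      scores[i] <- cl$score
      preds[i] <- cl$prediction
      if (cl$fallback) fallback_count <- fallback_count + 1L
    }
    truth_pos <- as.character(tcol[test_idx]) == positive_state
    pred_pos <- preds[test_idx] == positive_state
    cm <- confusion_metrics(sum(truth_pos & pred_pos), sum(!truth_pos & pred_pos),
                            sum(truth_pos & !pred_pos), sum(!truth_pos & !pred_pos))
    fold_rows[[j]] <- data.frame(fold = j, accuracy = cm$accuracy,
                                 precision = cm$precision, recall = cm$recall,
                                 f_measure = cm$f_measure,
                                 auc = rank_auc(scores[test_idx], truth_pos),
                                 degenerate = cm$degenerate)
  }
  truth_pos <- as.character(tcol) == positive_state
  pred_pos <- preds == positive_state
  tp <- sum(truth_pos & pred_pos); fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos); tn <- sum(!truth_pos & !pred_pos)
  pooled <- confusion_metrics(tp, fp, fn, tn)
  pooled$auc <- rank_auc(scores, truth_pos)
  structure(list(pooled = pooled,
                 folds = do.call(rbind, fold_rows),
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 fallback_count = fallback_count,
                 method = method, positive_state = positive_state),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("%s classifier, %d-fold CV (positive state: %s)\n",
              toupper(x$method), nrow(x$folds), x$positive_state))
  cat(sprintf("  accuracy %.2f | precision %s | recall %s | F %s | AUC %.2f\n",
              p$accuracy,
              if (is.na(p$precision)) "N/A" else sprintf("%.2f", p$precision),
              if (is.na(p$recall)) "N/A" else sprintf("%.2f", p$recall),
              if (is.na(p$f_measure)) "N/A" else sprintf("%.2f", p$f_measure),
              p$auc))
  if (p$degenerate) cat("  note: degenerate predictions (positive class never predicted)\n")
  invisible(x)
}
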