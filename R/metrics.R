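# Classification metrics: accuracy, Cohen's kappa, ROC-AUC (trapezoidal,
# tie-aware) and PR-AUC (step-wise average precision).

.roc_auc <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) return(NaN)
  r <- rank(y_prob, ties.method = "average")
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.pr_auc <- function(y_true, y_prob) {
  n1 <- sum(y_true == 1L)
  if (n1 == 0L || all(y_true == 1L)) return(NaN)
  ord <- order(y_prob, decreasing = TRUE)
  y <- y_true[ord]
  p <- y_prob[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # evaluate at distinct thresholds only (tie blocks collapse)
  last_of_block <- c(p[-1] != p[-length(p)], TRUE)
  tp <- tp[last_of_block]
  fp <- fp[last_of_block]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Binary classification metrics
#'
#' Accuracy and Cohen's kappa at a probability threshold, plus ROC-AUC
#' (rank/trapezoidal, equivalent over all thresholds) and PR-AUC computed as
#' step-wise average precision (not trapezoidal, which overestimates PR
#' curves). With a single observed class the AUCs are `NaN` with a warning.
#'
#' @param y_true 0/1 labels.
#' @param y_prob predicted probabilities.
#' @param threshold decision threshold for accuracy/kappa (default 0.5).
#' @return Named numeric vector `accuracy, kappa, roc_auc, pr_auc`.
#' @export
binary_metrics <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob))
    stop("y_true and y_prob lengths differ", call. = FALSE)
  y_true <- as.integer(y_true)
  pred <- as.integer(y_prob >= threshold)
  acc <- mean(pred == y_true)
  # kappa from marginal chance agreement
  p1t <- mean(y_true == 1L)
  p1p <- mean(pred == 1L)
  pe <- p1t * p1p + (1 - p1t) * (1 - p1p)
  kap <- if (pe < 1) (acc - pe) / (1 - pe) else NaN
  if (length(unique(y_true)) < 2L) {
    warning("single-class y_true: AUCs are NaN", call. = FALSE)
    return(c(accuracy = acc, kappa = kap, roc_auc = NaN, pr_auc = NaN))
  }
  c(accuracy = acc, kappa = kap, roc_auc = .roc_auc(y_true, y_prob),
    pr_auc = .pr_auc(y_true, y_prob))
}

#' Recall and precision at a threshold
#'
#' Per-fold diagnostic: recall = TP/(TP+FN), precision = TP/(TP+FP);
#' precision is `NaN` when nothing is predicted positive.
#'
#' @inheritParams binary_metrics
#' @return Named numeric vector `recall, precision`.
#' @export
recall_precision_at <- function(y_true, y_prob, threshold = 0.5) {
  y_true <- as.integer(y_true)
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  fn <- sum(pred == 0L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  c(recall = if (tp + fn > 0) tp / (tp + fn) else NaN,
    precision = if (tp + fp > 0) tp / (tp + fp) else NaN)
}

#' Evaluate LOOCV folds
#'
#' Per-participant accuracy, kappa, ROC-AUC and PR-AUC from [loocv()]
#' predictions, plus the arithmetic mean row.
#'
#' @param folds output of [loocv()].
#' @param threshold decision threshold (default 0.5).
#' @return A `data.table`, one row per participant plus a `Mean` row.
#' @export
evaluate_folds <- function(folds, threshold = 0.5) {
  rows <- lapply(folds, function(f) {
    m <- binary_metrics(f$predictions$y_true, f$predictions$y_prob,
                        threshold)
    data.table::data.table(participant = f$participant,
                           accuracy = m[["accuracy"]], kappa = m[["kappa"]],
                           roc_auc = m[["roc_auc"]], pr_auc = m[["pr_auc"]])
  })
  tab <- data.table::rbindlist(rows)
  mean_row <- data.table::data.table(
    participant = "Mean", accuracy = mean(tab$accuracy),
    kappa = mean(tab$kappa), roc_auc = mean(tab$roc_auc),
    pr_auc = mean(tab$pr_auc))
  data.table::rbindlist(list(tab, mean_row))
}
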