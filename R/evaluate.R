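#' Confusion counts
#'
#' @param labels binary ground-truth vector (0/1).
#' @param predictions binary predictions of equal length.
#' @return Named list with `TP`, `TN`, `FP`, `FN`; the four counts
#'   partition the sample.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop_validation("labels and predictions differ in length")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop_validation("labels and predictions must be binary")
  list(TP = sum(labels == 1 & predictions == 1),
       TN = sum(labels == 0 & predictions == 0),
       FP = sum(labels == 0 & predictions == 1),
       FN = sum(labels == 1 & predictions == 0))
}

#' Accuracy, sensitivity, specificity
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)` (true positive rate:
#' the fraction of seizure windows detected), `SPE = TN/(TN+FP)`. An empty
#' denominator raises an `ictalnet_undefined_metric` warning and yields
#' `NA`, never a silent zero.
#'
#' @param TP,TN,FP,FN confusion counts.
#' @return A fraction in `[0, 1]`, or `NA` with a warning.
#' @export
accuracy <- function(TP, TN, FP, FN) {
  n <- TP + TN + FP + FN
  if (n == 0) return(undefined_metric("accuracy"))
  (TP + TN) / n
}

#' @rdname accuracy
#' @export
sensitivity <- function(TP, FN) {
  if (TP + FN == 0) return(undefined_metric("sensitivity"))
  TP / (TP + FN)
}

#' @rdname accuracy
#' @export
specificity <- function(TN, FP) {
  if (TN + FP == 0) return(undefined_metric("specificity"))
  TN / (TN + FP)
}

#' ROC curve and trapezoid AUC
#'
#' Sweeps thresholds over the unique scores in descending order (tied
#' scores form a single threshold step), prepends (0,0) and appends (1,1),
#' and integrates by the trapezoid rule
#' `AUC = 1/2 * sum (x_{i+1} - x_i) (y_i + y_{i+1})` over the (FPR, TPR)
#' points. Equals the Mann-Whitney estimate: the probability that a random
#' positive outscores a random negative, counting ties as one half.
#'
#' @param labels binary vector with both classes present.
#' @param scores numeric scores (higher = more seizure-like).
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_and_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_validation("labels and scores differ in length")
  if (!all(labels %in% c(0, 1)))
    stop_validation("labels must be binary")
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    return(list(roc = NULL, auc = undefined_metric("AUC")))
  }
  ord <- order(scores, decreasing = TRUE)
  ls <- labels[ord]; ss <- scores[ord]
  # group tied scores into single steps
  grp <- cumsum(!duplicated(ss))
  tp <- cumsum(ls == 1); fp <- cumsum(ls == 0)
  last <- which(!duplicated(grp, fromLast = TRUE))
  roc <- data.frame(threshold = c(Inf, ss[last]),
                    fpr = c(0, fp[last] / N),
                    tpr = c(0, tp[last] / P))
  if (roc$fpr[nrow(roc)] != 1 || roc$tpr[nrow(roc)] != 1)
    roc <- rbind(roc, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  x <- roc$fpr; y <- roc$tpr
  auc <- 0.5 * sum(diff(x) * (head(y, -1) + y[-1]))
  list(roc = roc, auc = auc)
}

#' Evaluate a classifier on a labelled window set
#'
#' Computes probabilities, hard labels at `threshold`, confusion counts,
#' ACC/SEN/SPE, the ROC curve and its trapezoid AUC.
#'
#' @param model a trained `seizure_model` (or anything with a `predict`
#'   method returning probabilities).
#' @param test a `window_set` whose labels are hard 0/1.
#' @param threshold decision threshold.
#' @return An `eval_report`: list with `counts`, `acc`, `sen`, `spe`,
#'   `roc`, `auc`, `n`.
#' @export
evaluate_model <- function(model, test, threshold = 0.5) {
  stopifnot(inherits(test, "window_set"))
  p <- predict(model, test)
  y <- as.integer(test$labels >= 0.5)
  hard <- as.integer(p >= threshold)
  cc <- confusion_counts(y, hard)
  ra <- roc_and_auc(y, p)
  structure(list(counts = cc,
                 acc = accuracy(cc$TP, cc$TN, cc$FP, cc$FN),
                 sen = sensitivity(cc$TP, cc$FN),
                 spe = specificity(cc$TN, cc$FP),
                 roc = ra$roc, auc = ra$auc, n = length(y),
                 probs = p),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  ACC %.4f  SEN %.4f  SPE %.4f  AUC %.4f  (TP %d TN %d FP %d FN %d)\n",
    x$n, x$acc, x$sen, x$spe, x$auc,
    x$counts$TP, x$counts$TN, x$counts$FP, x$counts$FN))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Metrics and counts as JSON; ROC points as CSV next to it.
#'
#' @param report an `eval_report`.
#' @param path JSON output path; the ROC CSV replaces the extension.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(counts = report$counts,
         metrics = list(acc = report$acc, sen = report$sen,
                        spe = report$spe, auc = report$auc),
         n = report$n),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(report$roc)) {
    csv <- sub("\\.[^.]*$", ".roc.csv", path)
    write.csv(report$roc, csv, row.names = FALSE)
  }
  invisible(path)
}
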