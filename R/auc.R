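#' Univariate ROC analysis of one protein
#'
#' The AUC is the rank (Mann-Whitney) statistic: the probability that a
#' positive-class sample exceeds a negative-class sample, ties counted 1/2.
#' It is reported oriented as `max(A, 1 - A)` together with the direction
#' flag, and a p-value from the equivalent Mann-Whitney test of AUC = 0.5.
#'
#' @param values numeric vector (one protein across samples).
#' @param labels two-level factor; `positive` names the positive class.
#' @param positive positive-class label (default `"PPG"`).
#' @return list with `auc` (>= 0.5), `direction` (`"higher_in_PPG"` /
#'   `"higher_in_GPG"`, generically `higher_in_<class>`), `auc_raw`
#'   (positive-class orientation) and `p`.
#' @export
univariate_auc <- function(values, labels, positive = "PPG") {
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two classes")
  if (!positive %in% levels(labels)) stop("positive class not present in labels")
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(values)                       # midranks
  a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ht <- mwu_test(values[pos], values[!pos])
  negative <- setdiff(levels(labels), positive)
  list(auc = max(a, 1 - a),
       direction = paste0("higher_in_", if (a >= 0.5) positive else negative),
       auc_raw = a, p = ht$p)
}

#' Empirical ROC curve and AUC for classifier scores
#'
#' Standard empirical ROC over score thresholds; the trapezoid AUC equals
#' the rank AUC of [univariate_auc()].
#'
#' @param scores numeric classifier scores.
#' @param labels two-level factor.
#' @param positive positive-class label (default `"PPG"`).
#' @return list with `fpr`, `tpr`, `thresholds` (descending, starting at
#'   `Inf`) and `auc`.
#' @export
multivariate_roc <- function(scores, labels, positive = "PPG") {
  labels <- factor(labels)
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc)
}

# Stratified fold assignment: within each class, folds are as balanced as
# possible. Errors if any class is smaller than the fold count.
stratified_folds <- function(labels, k) {
  labels <- factor(labels)
  if (any(table(labels) < k)) {
    stop("stratification impossible: a class has fewer samples than folds")
  }
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}
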