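# Out-of-bag AUC of a fitted classification forest, from its OOB votes.
rf_oob_auc <- function(rf, labels, positive) {
  votes <- rf$votes[, positive]
  univariate_auc(votes, labels, positive = positive)$auc_raw
}

# One AUC-based backward-elimination pass: fit a forest, rank features,
# drop the least-important fraction, record OOB AUC at each set size.
# The optimal set is the smallest size attaining the maximal OOB AUC.
rf_backward <- function(x, labels, ntree, mtry, pdel, positive,
                        ranking = c("permutation", "gini")) {
  ranking <- match.arg(ranking)
  feats <- colnames(x)
  sizes <- aucs <- numeric(0)
  sets <- list()
  full_importance <- NULL
  repeat {
    rf <- randomForest::randomForest(
      x[, feats, drop = FALSE], labels,
      ntree = ntree, mtry = min(mtry, length(feats)),
      importance = (ranking == "permutation"))
    imp <- if (ranking == "permutation") {
      rf$importance[, "MeanDecreaseAccuracy"]
    } else {
      rf$importance[, "MeanDecreaseGini"]
    }
    if (is.null(full_importance)) full_importance <- imp
    sizes <- c(sizes, length(feats))
    aucs <- c(aucs, rf_oob_auc(rf, labels, positive))
    sets[[length(sets) + 1L]] <- feats
    if (length(feats) <= 2L) break
    ndrop <- max(1L, floor(pdel * length(feats)))
    # keep the most important; ties broken lexicographically for determinism
    keep <- feats[order(-imp, feats)][seq_len(length(feats) - ndrop)]
    feats <- keep
  }
  best <- which(aucs == max(aucs))
  opt <- best[which.min(sizes[best])]
  list(opt_features = sets[[opt]], opt_size = sizes[opt], opt_auc = aucs[opt],
       path = data.frame(size = sizes, oob_auc = aucs),
       full_importance = full_importance)
}

#' AUC-based random-forest backward-elimination feature selection
#'
#' Two-stage panel selection. Stage 1 (backward elimination): a random
#' forest of `ntree_rank` trees is fitted on all features; features are
#' ranked by permutation importance and the least-important
#' `n_eliminate_fraction` repeatedly dropped, recording the out-of-bag AUC
#' at each set size. The optimal set is the smallest size attaining the
#' maximal OOB AUC. Stage 2 (selection stability): the elimination is
#' repeated on the stage-1 optimal set inside `cv_repeats` rounds of
#' stratified `cv_folds`-fold cross-validation; each feature's selection
#' probability is the fraction of runs whose optimal subset contains it,
#' and its importance is its permutation importance min-max scaled to
#' \[0, 1\] within each run, averaged over runs.
#'
#' @param x numeric matrix, samples x features (e.g. log2 normalized
#'   imputed abundances), with column names.
#' @param labels two-level factor over rows of `x`.
#' @param ntree_rank trees per ranking forest (default 50000; scale down
#'   for small feature sets).
#' @param mtry_rank features sampled per tree split (default 8).
#' @param n_eliminate_fraction fraction of remaining features dropped per
#'   backward step (default 0.2).
#' @param cv_folds,cv_repeats stage-2 cross-validation design (defaults 3
#'   and 100). `cv_repeats = 0` skips stage 2 (importance then comes from
#'   the stage-1 ranking forest and `prob_select` is `NA`).
#' @param importance_threshold selection flag threshold (default 0.3).
#' @param positive positive-class label (default `"PPG"`).
#' @param ranking `"permutation"` (mean decrease in OOB accuracy, default)
#'   or `"gini"`.
#' @param seed optional integer seed; fixed seed makes the whole procedure
#'   deterministic.
#' @return a `ranked_feature_table` data frame over the stage-1 optimal
#'   set, sorted by importance: `protein_id`, `importance`, `prob_select`,
#'   `selected` (importance > threshold), `univariate_auc`. Attributes:
#'   `path` (set size vs OOB AUC), `opt_size`, `opt_oob_auc`, `threshold`.
#' @export
aucrf_select <- function(x, labels, ntree_rank = 50000, mtry_rank = 8,
                         n_eliminate_fraction = 0.2, cv_folds = 3,
                         cv_repeats = 100, importance_threshold = 0.3,
                         positive = "PPG", ranking = "permutation",
                         seed = NULL) {
  if (ncol(x) < 2) stop("need at least two features")
  if (is.null(colnames(x))) stop("x must have feature column names")
  labels <- factor(labels)
  if (nlevels(labels) != 2 || !positive %in% levels(labels)) {
    stop("labels must be two-level and contain the positive class")
  }
  if (!is.null(seed)) set.seed(seed)

  s1 <- rf_backward(x, labels, ntree = ntree_rank, mtry = mtry_rank,
                    pdel = n_eliminate_fraction, positive = positive,
                    ranking = ranking)
  opt <- sort(s1$opt_features)

  scale01 <- function(z) {
    rng <- range(z)
    if (rng[2] > rng[1]) (z - rng[1]) / (rng[2] - rng[1]) else rep(1, length(z))
  }

  if (cv_repeats > 0) {
    n_runs <- 0L
    sel_count <- stats::setNames(numeric(length(opt)), opt)
    imp_sum <- stats::setNames(numeric(length(opt)), opt)
    for (rep_i in seq_len(cv_repeats)) {
      fold <- stratified_folds(labels, cv_folds)
      for (f in seq_len(cv_folds)) {
        tr <- fold != f
        run <- rf_backward(x[tr, opt, drop = FALSE], droplevels(labels[tr]),
                           ntree = ntree_rank, mtry = mtry_rank,
                           pdel = n_eliminate_fraction, positive = positive,
                           ranking = ranking)
        sel_count[run$opt_features] <- sel_count[run$opt_features] + 1
        imp_sum <- imp_sum + scale01(run$full_importance[opt])
        n_runs <- n_runs + 1L
      }
    }
    importance <- imp_sum / n_runs
    prob_select <- sel_count / n_runs
  } else {
    importance <- scale01(s1$full_importance[opt])
    prob_select <- rep(NA_real_, length(opt))
  }

  uauc <- vapply(opt, function(f) {
    univariate_auc(x[, f], labels, positive = positive)$auc
  }, numeric(1))

  tab <- data.frame(protein_id = opt,
                    importance = unname(importance),
                    prob_select = unname(prob_select),
                    selected = unname(importance) > importance_threshold,
                    univariate_auc = unname(uauc),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$importance, tab$protein_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("ranked_feature_table", "data.frame")
  attr(tab, "path") <- s1$path
  attr(tab, "opt_size") <- s1$opt_size
  attr(tab, "opt_oob_auc") <- s1$opt_auc
  attr(tab, "threshold") <- importance_threshold
  tab
}

#' Filter a ranked feature table by importance
#'
#' Returns the features whose importance strictly exceeds the threshold,
#' ordered by decreasing importance.
#'
#' @param table a `ranked_feature_table` (or any data frame with
#'   `protein_id` and `importance` columns).
#' @param threshold importance cutoff (default 0.3).
#' @return character vector of feature ids.
#' @export
filter_by_importance <- function(table, threshold = 0.3) {
  stopifnot(nrow(table) > 0,
            all(c("protein_id", "importance") %in% names(table)))
  keep <- table[table$importance > threshold, , drop = FALSE]
  keep$protein_id[order(-keep$importance)]
}
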