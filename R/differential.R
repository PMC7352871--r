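#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test with midrank ties. The p-value is exact when the smaller
#' group has at most 8 observations and there are no ties, otherwise the
#' normal approximation with continuity and tie correction is used.
#'
#' @param a,b numeric vectors, both nonempty.
#' @return list with `U` (number of (a, b) pairs with a > b, ties counted
#'   1/2) and `p` (two-sided).
#' @export
mwu_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Volcano classification of differential abundance results
#'
#' A protein is `up_PPG` when its log2 fold change exceeds `fc_thresh` at
#' `p < p_thresh`, `down_PPG` when below `-fc_thresh` at `p < p_thresh`,
#' otherwise `ns`. Both inequalities are strict.
#'
#' @param table data frame with columns `log2fc` and `p`.
#' @param fc_thresh absolute log2 fold-change threshold (default 0.5).
#' @param p_thresh p-value threshold (default 0.05).
#' @return `table` with a `class` factor column added; counts per class in
#'   attribute `class_counts`.
#' @export
volcano_classify <- function(table, fc_thresh = 0.5, p_thresh = 0.05) {
  stopifnot(all(c("log2fc", "p") %in% names(table)))
  if (any(!is.finite(table$log2fc))) stop("fold changes must be finite")
  cls <- rep("ns", nrow(table))
  cls[table$log2fc > fc_thresh & table$p < p_thresh] <- "up_PPG"
  cls[table$log2fc < -fc_thresh & table$p < p_thresh] <- "down_PPG"
  table$class <- factor(cls, levels = c("up_PPG", "down_PPG", "ns"))
  attr(table, "class_counts") <- table(table$class)
  table
}

#' Per-protein differential abundance between prognosis groups
#'
#' Computes, for every protein, the log2 fold change (PPG mean minus GPG
#' mean of log2 values), the Mann-Whitney U statistic and two-sided
#' p-value, a Benjamini-Hochberg q-value (reported, not used for
#' classification), and the volcano class.
#'
#' @param x an imputed- or normalized-stage [abundance_matrix()] on the
#'   intensity scale (log2 is taken internally), or an already-log2 plain
#'   matrix with `log2_transform = FALSE`.
#' @param groups two-level factor over samples; the second level is the
#'   poor-prognosis (PPG) direction.
#' @param fc_thresh,p_thresh volcano thresholds, see [volcano_classify()].
#' @param log2_transform take log2 of the values first (default TRUE).
#' @return data frame: `protein_id`, `log2fc`, `U`, `p`, `q`, `class`.
#' @export
differential_table <- function(x, groups, fc_thresh = 0.5, p_thresh = 0.05,
                               log2_transform = TRUE) {
  v <- abundance_values(as_abundance(x))
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups")
  if (length(groups) != ncol(v)) stop("groups length must match sample count")
  y <- if (log2_transform) log2(v) else v
  ppg <- groups == levels(groups)[2]
  res <- t(apply(y, 1, function(row) {
    ht <- mwu_test(row[ppg], row[!ppg])
    c(log2fc = mean(row[ppg], na.rm = TRUE) - mean(row[!ppg], na.rm = TRUE),
      U = ht$U, p = ht$p)
  }))
  tab <- data.frame(protein_id = rownames(v), res, row.names = NULL,
                    stringsAsFactors = FALSE)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  volcano_classify(tab, fc_thresh = fc_thresh, p_thresh = p_thresh)
}

#' Permutation p-value for a Pearson correlation
#'
#' Computes Pearson's r on the given pairing and a permutation p-value
#' `(1 + #{|r*| >= |r|}) / (1 + n_perm)` obtained by permuting `y`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @return list with `r` and `p`.
#' @export
pearson_permutation <- function(x, y, n_perm = 999, seed = NULL) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- stats::cor(x, y)
  rstar <- replicate(n_perm, abs(stats::cor(x, sample(y))))
  list(r = r, p = (1 + sum(rstar >= abs(r))) / (1 + n_perm))
}
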