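#' Default gene mapping for the five-protein urinary panel
#'
#' Identity mapping from the panel gene symbols (ACP2, CTSA, GM2A, MUC1,
#' SPARCL1) to expression-matrix row identifiers; replace the values with
#' platform probe ids when applying the panel to array data.
#'
#' @return named list: panel gene -> character vector of row identifiers.
#' @export
default_panel_mapping <- function() {
  genes <- c("ACP2", "CTSA", "GM2A", "MUC1", "SPARCL1")
  stats::setNames(as.list(genes), genes)
}

#' Extract the panel feature matrix from an expression dataset
#'
#' Maps each panel gene to its probe row(s); multiple probes per gene are
#' collapsed (mean by default). Output rows follow the order of
#' `features`.
#'
#' @param expr numeric matrix, probes/genes x samples.
#' @param mapping named list or two-column data frame (`gene`, `probe`)
#'   mapping each panel gene to >= 1 row identifier of `expr`.
#' @param features panel genes to extract, in model feature order
#'   (default: all mapped genes, sorted).
#' @param collapse `"mean"` (default) or `"max"` across probes.
#' @return numeric matrix, panel genes x samples.
#' @export
map_panel_features <- function(expr, mapping, features = NULL,
                               collapse = c("mean", "max")) {
  collapse <- match.arg(collapse)
  if (is.data.frame(mapping)) {
    mapping <- split(as.character(mapping[[2]]), as.character(mapping[[1]]))
  }
  if (is.null(features)) features <- sort(names(mapping))
  unmapped <- setdiff(features, names(mapping))
  if (length(unmapped)) {
    stop("no mapping for panel gene(s): ", paste(unmapped, collapse = ", "))
  }
  rows <- lapply(features, function(g) {
    probes <- unlist(mapping[[g]])
    absent <- setdiff(probes, rownames(expr))
    if (length(absent) == length(probes)) {
      stop("no probe found in matrix for panel gene: ", g)
    }
    sub <- expr[intersect(probes, rownames(expr)), , drop = FALSE]
    if (collapse == "mean") colMeans(sub) else apply(sub, 2, max)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- features
  out
}

#' Apply a frozen panel model to an external expression matrix
#'
#' Scores external samples with a trained panel model without refitting.
#' Because the model was trained on urinary protein abundances and the
#' external data are typically transcript levels, the default bridging is
#' per-gene z-scoring within the external dataset (`dataset_zscore`), the
#' model's own center/scale being bypassed; `model_preprocessing` instead
#' applies the stored training parameters to values already on the
#' training scale.
#'
#' @param model a `panel_model`.
#' @param panel_matrix numeric matrix, panel genes x samples (all model
#'   features present as rows, no missing values).
#' @param standardization `"dataset_zscore"` (default) or
#'   `"model_preprocessing"`.
#' @return named numeric vector of scores in \[0, 1\].
#' @export
apply_panel_model <- function(model, panel_matrix,
                              standardization = c("dataset_zscore",
                                                  "model_preprocessing")) {
  standardization <- match.arg(standardization)
  stopifnot(inherits(model, "panel_model"))
  miss <- setdiff(model$feature_ids, rownames(panel_matrix))
  if (length(miss)) stop("panel matrix lacks gene(s): ", paste(miss, collapse = ", "))
  m <- panel_matrix[model$feature_ids, , drop = FALSE]
  if (anyNA(m)) stop("panel matrix must be complete")
  if (standardization == "dataset_zscore") {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      stop("zero variance under dataset z-scoring for gene(s): ",
           paste(rownames(m)[sds == 0], collapse = ", "))
    }
    z <- t(scale(t(m)))
    predict_scores(model, t(z), preprocess = FALSE)
  } else {
    predict_scores(model, t(m), preprocess = TRUE)
  }
}

#' Mann-Whitney comparisons of scores against a reference group
#'
#' Compares the reference disease group's scores with every other group;
#' p-values are reported raw and Benjamini-Hochberg adjusted. Singleton
#' groups are still tested (exact test) and flagged.
#'
#' @param scores numeric scores.
#' @param labels factor of disease-group labels (>= 2 levels).
#' @param reference reference group label.
#' @return data frame: `group`, `n`, `n_reference`, `U`, `p`, `p_adj`,
#'   `singleton`.
#' @export
groupwise_score_tests <- function(scores, labels, reference) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (!reference %in% levels(labels)) stop("reference group not present")
  ref <- scores[labels == reference]
  others <- setdiff(levels(labels), reference)
  rows <- lapply(others, function(g) {
    s <- scores[labels == g]
    ht <- mwu_test(ref, s)
    data.frame(group = g, n = length(s), n_reference = length(ref),
               U = ht$U, p = ht$p, singleton = length(s) == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[, c("group", "n", "n_reference", "U", "p", "p_adj", "singleton")]
}

#' Pearson correlation between two classifiers' scores
#'
#' @param scores_a,scores_b numeric vectors of equal length >= 3.
#' @return Pearson r.
#' @export
score_correlation <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) || length(scores_a) < 3) {
    stop("score vectors must have equal length >= 3")
  }
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    stop("undefined correlation: zero variance")
  }
  stats::cor(scores_a, scores_b)
}
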