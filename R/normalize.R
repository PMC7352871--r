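#' Correct raw LFQ intensities for spot-urine dilution
#'
#' Divides each sample's raw LFQ values by its urinary creatinine and/or
#' total protein concentration, offsetting the arbitrary dilution of random
#' spot urine collection. Missing entries stay missing.
#'
#' @param x raw-stage [abundance_matrix()].
#' @param meta per-sample metadata with `creatinine` (and `total_protein`
#'   when used), both strictly positive.
#' @param mode `"both"` (divide by creatinine x total protein, the default),
#'   `"creatinine"`, or `"protein"`.
#' @return corrected-stage [abundance_matrix()].
#' @export
correct_lfq <- function(x, meta, mode = c("both", "creatinine", "protein")) {
  mode <- match.arg(mode)
  x <- as_abundance(x)
  meta <- meta_for(x, meta)
  div <- switch(mode,
                creatinine = meta$creatinine,
                protein = meta$total_protein,
                both = meta$creatinine * meta$total_protein)
  if (is.null(div)) stop("metadata lacks the column(s) required for mode '", mode, "'")
  bad <- which(!is.finite(div) | div <= 0)
  if (length(bad)) {
    stop("data error: nonpositive divisor for sample(s): ",
         paste(meta$sample_id[bad], collapse = ", "))
  }
  abundance_matrix(sweep(abundance_values(x), 2, div, "/"), stage = "corrected")
}

#' NormFinder-type stability of candidate normalization proteins
#'
#' Model-based stability on log2-transformed corrected values: per-sample
#' averages over the candidate set are removed (absorbing global loading
#' differences), then for every candidate the intergroup variation (its
#' group-mean deviation from the candidate-set average, shrunken towards 0
#' by the empirical variance of those deviations across candidates) and its
#' intragroup variance are estimated. The stability value is
#' `mean over groups of |shrunken group deviation| + sqrt(within-group
#' variance / group size)`; lower is more stable.
#'
#' @param x corrected-stage [abundance_matrix()] of candidates only; no
#'   missing values allowed (filter first).
#' @param groups two-level factor over samples (column order).
#' @param log2_transform log2-transform values first (default TRUE; the
#'   additive-error stability model assumes log scale).
#' @return data frame sorted by stability then protein id: `protein_id`,
#'   `intergroup` (mean |shrunken deviation|), `intragroup_se`,
#'   `stability`, `rank`.
#' @export
normfinder_stability <- function(x, groups, log2_transform = TRUE) {
  v <- abundance_values(as_abundance(x, stage = "corrected"))
  if (anyNA(v)) stop("missing values among candidates; filter to complete proteins first")
  if (nrow(v) < 2) stop("need at least two candidate proteins")
  groups <- factor(groups)
  if (length(groups) != ncol(v)) stop("groups length must match sample count")
  if (nlevels(groups) < 2) stop("need at least two groups")
  y <- if (log2_transform) log2(v) else v
  I <- nrow(y)
  xr <- sweep(y, 2, colMeans(y))              # remove per-sample average
  m_all <- rowMeans(xr)
  inter <- se <- matrix(0, I, nlevels(groups))
  for (k in seq_len(nlevels(groups))) {
    idx <- which(groups == levels(groups)[k])
    ng <- length(idx)
    if (ng < 2) stop("each group needs >= 2 samples")
    m_g <- rowMeans(xr[, idx, drop = FALSE])
    v_g <- apply(xr[, idx, drop = FALSE], 1, stats::var)
    d <- m_g - m_all
    gamma2 <- max(sum(d^2) / (I - 1) - mean(v_g) / ng, 0)
    d_shrunk <- if (gamma2 > 0) d * gamma2 / (gamma2 + v_g / ng) else d * 0
    inter[, k] <- abs(d_shrunk)
    se[, k] <- sqrt(v_g / ng)
  }
  out <- data.frame(protein_id = rownames(y),
                    intergroup = rowMeans(inter),
                    intragroup_se = rowMeans(se),
                    stability = rowMeans(inter + se),
                    stringsAsFactors = FALSE)
  out <- out[order(out$stability, out$protein_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select endogenous normalization proteins
#'
#' Applies the three selection criteria in order: (1) quantified in all
#' samples; (2) corrected values do not differ between prognosis groups
#' (two-sided Mann-Whitney U, unadjusted p > `p_threshold`); (3) top-ranked
#' by NormFinder stability among the survivors.
#'
#' @param x corrected-stage [abundance_matrix()] (full matrix; candidates
#'   are its completely quantified proteins).
#' @param groups two-level factor over samples.
#' @param n_select number of normalization proteins to pick (default 6).
#' @param p_threshold Mann-Whitney exclusion threshold (default 0.05).
#' @return a `normalization_result` list: `norm_protein_ids`,
#'   `stability_table` (all criteria-1/2 survivors), `candidates`
#'   (complete proteins), `excluded_by_test`, plus `protein_medians` and
#'   `nsf_by_sample` once [compute_nsf()] has run.
#' @export
select_normalization_proteins <- function(x, groups, n_select = 6,
                                          p_threshold = 0.05) {
  x <- as_abundance(x, stage = "corrected")
  v <- abundance_values(x)
  groups <- factor(groups)
  candidates <- rownames(v)[stats::complete.cases(v)]
  if (length(candidates) == 0) stop("selection error: no completely quantified protein")
  ga <- groups == levels(groups)[1]
  pvals <- vapply(candidates, function(p) {
    mwu_test(v[p, ga], v[p, !ga])$p
  }, numeric(1))
  survivors <- candidates[pvals > p_threshold]
  if (length(survivors) < n_select) {
    stop(sprintf(paste0("selection error: only %d candidate(s) survive the ",
                        "completeness and group-difference criteria (need %d)"),
                 length(survivors), n_select))
  }
  sub <- abundance_matrix(v[survivors, , drop = FALSE], stage = x$stage)
  stab <- normfinder_stability(sub, groups)
  res <- list(norm_protein_ids = stab$protein_id[seq_len(n_select)],
              stability_table = stab,
              candidates = candidates,
              excluded_by_test = candidates[pvals <= p_threshold],
              mwu_p = pvals,
              protein_medians = NULL,
              nsf_by_sample = NULL)
  class(res) <- "normalization_result"
  res
}

#' @export
print.normalization_result <- function(x, ...) {
  cat("normalization_result\n")
  cat("  candidates (complete):", length(x$candidates), "\n")
  cat("  selected:", paste(x$norm_protein_ids, collapse = ", "), "\n")
  if (!is.null(x$nsf_by_sample)) {
    cat(sprintf("  NSF range: [%.3f, %.3f]\n",
                min(x$nsf_by_sample), max(x$nsf_by_sample)))
  }
  invisible(x)
}

#' Per-sample normalization scaling factors (NSF)
#'
#' Each selected normalization protein's corrected value is divided by its
#' median over all samples; the per-sample median of these ratios is that
#' sample's NSF.
#'
#' @param x corrected-stage [abundance_matrix()] containing the
#'   normalization proteins (complete in all samples).
#' @param result a `normalization_result` from
#'   [select_normalization_proteins()], or a character vector of
#'   normalization protein ids. If `result$protein_medians` is already
#'   filled those reference medians are reused (frozen-reference mode, for
#'   scaling new samples against a fixed cohort).
#' @return the `normalization_result` with `protein_medians` (per-protein
#'   cohort medians) and `nsf_by_sample` (named, strictly positive) filled.
#' @export
compute_nsf <- function(x, result) {
  x <- as_abundance(x, stage = "corrected")
  v <- abundance_values(x)
  if (is.character(result)) {
    result <- structure(list(norm_protein_ids = result),
                        class = "normalization_result")
  }
  ids <- result$norm_protein_ids
  miss <- setdiff(ids, rownames(v))
  if (length(miss)) stop("normalization proteins absent from matrix: ",
                         paste(miss, collapse = ", "))
  N <- v[ids, , drop = FALSE]
  if (anyNA(N)) stop("normalization proteins must be quantified in all samples")
  med <- if (!is.null(result$protein_medians)) {
    result$protein_medians[ids]
  } else {
    apply(N, 1, stats::median)
  }
  ratios <- sweep(N, 1, med, "/")
  nsf <- apply(ratios, 2, stats::median)
  if (any(!is.finite(nsf) | nsf <= 0)) {
    stop("undefined NSF (nonpositive ratio) for sample(s): ",
         paste(names(nsf)[!is.finite(nsf) | nsf <= 0], collapse = ", "))
  }
  result$protein_medians <- med
  result$nsf_by_sample <- nsf
  result
}

#' Apply normalization scaling factors
#'
#' Divides every protein's corrected value by its sample's NSF. The
#' normalization proteins themselves are excluded from the output by
#' default (they carry no information once used for scaling).
#'
#' @param x corrected-stage [abundance_matrix()].
#' @param result `normalization_result` with `nsf_by_sample` filled, or a
#'   named positive numeric vector of NSFs covering every sample.
#' @param drop_norm_proteins remove the normalization-protein rows
#'   (default TRUE).
#' @return normalized-stage [abundance_matrix()].
#' @export
apply_nsf <- function(x, result, drop_norm_proteins = TRUE) {
  x <- as_abundance(x, stage = "corrected")
  v <- abundance_values(x)
  if (is.numeric(result)) {
    nsf <- result
    norm_ids <- character(0)
  } else {
    nsf <- result$nsf_by_sample
    norm_ids <- result$norm_protein_ids
  }
  if (is.null(nsf)) stop("NSF not computed; run compute_nsf() first")
  miss <- setdiff(colnames(v), names(nsf))
  if (length(miss)) stop("NSF unavailable for sample(s): ",
                         paste(miss, collapse = ", "))
  out <- sweep(v, 2, nsf[colnames(v)], "/")
  if (drop_norm_proteins && length(norm_ids)) {
    out <- out[setdiff(rownames(out), norm_ids), , drop = FALSE]
  }
  abundance_matrix(out, stage = "normalized")
}

#' One-call correction and normalization
#'
#' Convenience wrapper: [correct_lfq()], [select_normalization_proteins()],
#' [compute_nsf()], [apply_nsf()].
#'
#' @inheritParams correct_lfq
#' @inheritParams select_normalization_proteins
#' @return list with `normalized` (normalized-stage matrix), `corrected`,
#'   and `result` (the filled `normalization_result`).
#' @export
normalize_abundance <- function(x, meta, mode = "both", n_select = 6,
                                p_threshold = 0.05) {
  meta <- meta_for(x, meta)
  corrected <- correct_lfq(x, meta, mode = mode)
  res <- select_normalization_proteins(corrected, meta$group,
                                       n_select = n_select,
                                       p_threshold = p_threshold)
  res <- compute_nsf(corrected, res)
  list(normalized = apply_nsf(corrected, res),
       corrected = corrected, result = res)
}
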