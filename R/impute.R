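#' Group-completeness filter
#'
#' Retains proteins whose missing fraction is strictly below
#' `max_missing_fraction` within every group (default scope), or over all
#' samples (`scope = "overall"`). The default 0.2 keeps proteins quantified
#' in more than 80% of each prognosis group.
#'
#' @param x an [abundance_matrix()].
#' @param groups factor over samples (column order); required for
#'   `scope = "per_group"`.
#' @param max_missing_fraction maximum tolerated missing fraction (default 0.2).
#' @param scope `"per_group"` (default) or `"overall"`.
#' @return the filtered [abundance_matrix()] (same stage), with attributes
#'   `n_retained` and `n_removed`.
#' @export
completeness_filter <- function(x, groups = NULL, max_missing_fraction = 0.2,
                                scope = c("per_group", "overall")) {
  scope <- match.arg(scope)
  if (max_missing_fraction < 0 || max_missing_fraction > 1) {
    stop("max_missing_fraction must be in [0, 1]")
  }
  x <- as_abundance(x)
  v <- abundance_values(x)
  if (scope == "per_group") {
    if (is.null(groups)) stop("groups required for per-group filtering")
    groups <- factor(groups)
    if (length(groups) != ncol(v)) stop("groups length must match sample count")
    frac <- sapply(levels(groups), function(g) {
      rowMeans(is.na(v[, groups == g, drop = FALSE]))
    })
    keep <- apply(frac < max_missing_fraction, 1, all)
  } else {
    keep <- rowMeans(is.na(v)) < max_missing_fraction
  }
  if (!any(keep)) {
    warning("completeness filter removed every protein")
    keep[] <- FALSE
  }
  out <- abundance_matrix(v[keep, , drop = FALSE], stage = x$stage)
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Local least squares (LLS) imputation
#'
#' For each protein with missing entries, the `k` completely quantified
#' proteins most correlated with it (absolute Pearson on log2 values over
#' its observed samples, requiring at least `min_overlap` overlapping
#' samples) are used as regressors in an ordinary least squares fit on the
#' observed samples; the fit predicts the missing entries. Observed values
#' are never altered. With `k = 0`, or when no eligible neighbour exists,
#' missing entries fall back to the protein's mean (computed on the log2
#' scale) with a warning.
#'
#' The neighbour regression is ridge-stabilized: the penalty is chosen per
#' protein by generalized cross-validation over a small grid including 0,
#' so exact linear dependence on neighbours is reproduced exactly (the
#' unpenalized least squares solution) while weakly informative neighbours
#' are shrunken instead of overfitted.
#'
#' @param x an [abundance_matrix()] (typically normalized stage).
#' @param k number of neighbour proteins (default 10; capped at the number
#'   of complete proteins and at observed-sample count minus 2).
#' @param log2_transform fit on the log2 scale and back-transform
#'   (default TRUE, matching intensity data).
#' @param min_overlap minimum jointly observed samples for a neighbour.
#' @return imputed-stage [abundance_matrix()] with zero missing entries and
#'   an `imputation_report` attribute (entries imputed per protein and the
#'   method used).
#' @export
lls_impute <- function(x, k = 10, log2_transform = TRUE, min_overlap = 6) {
  x <- as_abundance(x)
  v <- abundance_values(x)
  if (!anyNA(v)) {
    out <- abundance_matrix(v, stage = "imputed")
    attr(out, "imputation_report") <-
      data.frame(protein_id = character(0), n_imputed = integer(0),
                 method = character(0), stringsAsFactors = FALSE)
    return(out)
  }
  y <- if (log2_transform) log2(v) else v
  complete_ids <- rownames(y)[stats::complete.cases(y)]
  targets <- rownames(y)[!stats::complete.cases(y)]
  yc <- y[complete_ids, , drop = FALSE]
  report <- vector("list", length(targets))
  fallback_used <- FALSE

  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    row <- y[tg, ]
    obs <- which(!is.na(row))
    mis <- which(is.na(row))
    method <- "lls"
    pred <- NULL
    # at most half the observed samples as regressors
    kk <- min(k, length(complete_ids), (length(obs) - 1L) %/% 2L)
    if (kk >= 1 && length(obs) >= min_overlap) {
      sdv <- apply(yc[, obs, drop = FALSE], 1, stats::sd)
      usable <- which(sdv > 0)
      if (length(usable)) {
        r <- abs(stats::cor(row[obs], t(yc[usable, obs, drop = FALSE])))[1, ]
        nb <- usable[order(-r, complete_ids[usable])][seq_len(min(kk, length(usable)))]
        X <- t(yc[nb, obs, drop = FALSE])
        Xmis <- t(yc[nb, mis, drop = FALSE])
        pred <- ridge_gcv_predict(X, row[obs], Xmis)
      }
    }
    if (is.null(pred)) {
      method <- "mean"
      fallback_used <- TRUE
      pred <- rep(mean(row[obs]), length(mis))
    }
    y[tg, mis] <- pred
    report[[ti]] <- data.frame(protein_id = tg, n_imputed = length(mis),
                               method = method, stringsAsFactors = FALSE)
  }
  if (fallback_used) {
    warning("no eligible LLS neighbour for some protein(s); mean imputation used")
  }
  out_vals <- if (log2_transform) 2^y else y
  # observed entries must round-trip bit-exactly
  out_vals[!is.na(v)] <- v[!is.na(v)]
  out <- abundance_matrix(out_vals, stage = "imputed")
  attr(out, "imputation_report") <- do.call(rbind, report)
  out
}

# Ridge regression of y on standardized X with the penalty picked by
# generalized cross-validation over a grid spanning 0 (ordinary least
# squares) to Inf (the intercept-only / protein-mean model), so the
# per-protein fit can fall back to the mean when the neighbours carry no
# information. Intercept unpenalized. Returns predictions at Xnew.
ridge_gcv_predict <- function(X, y, Xnew,
                              lambda_grid = c(0, 0.01, 0.05, 0.1, 0.25,
                                              0.5, 1, 2, Inf)) {
  n <- nrow(X)
  xm <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs == 0] <- 1
  Xs <- scale(X, xm, xs)
  ym <- mean(y)
  yd <- y - ym
  sv <- svd(Xs)
  pos <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[pos]
  U <- sv$u[, pos, drop = FALSE]
  V <- sv$v[, pos, drop = FALSE]
  uy <- drop(crossprod(U, yd))
  best <- NULL
  for (lam in lambda_grid * n) {
    shrink <- if (is.finite(lam)) d^2 / (d^2 + lam) else rep(0, length(d))
    fitted <- drop(U %*% (shrink * uy))
    rss <- sum((yd - fitted)^2)
    df <- sum(shrink) + 1
    if (n - df < 2) next          # need residual df for GCV to be meaningful
    gcv <- n * rss / (n - df)^2
    if (is.null(best) || gcv < best$gcv - 1e-15) {
      best <- list(gcv = gcv, lam = lam, shrink = shrink)
    }
  }
  beta <- drop(V %*% ((best$shrink / d) * uy))
  drop(scale(Xnew, xm, xs) %*% beta) + ym
}
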