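#' Protein-by-sample abundance matrix
#'
#' Lightweight container for a label-free quantitation (LFQ) matrix with
#' proteins as rows and samples as columns, tagged with the processing stage
#' it has reached. Missing entries (proteins not quantified in a sample) are
#' `NA`.
#'
#' @param values numeric matrix, proteins x samples, with unique non-empty
#'   rownames (protein accessions) and colnames (sample ids). Values must be
#'   nonnegative or `NA`.
#' @param stage processing stage, one of `"raw"`, `"corrected"`,
#'   `"normalized"`, `"imputed"`.
#' @return an `abundance_matrix`: a list with elements `values` and `stage`.
#' @examples
#' m <- matrix(c(10, 20, NA, 40), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("S1", "S2")))
#' abundance_matrix(m, stage = "raw")
#' @export
abundance_matrix <- function(values,
                             stage = c("raw", "corrected", "normalized", "imputed")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix (proteins x samples)")
  }
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) || is.null(sid) || any(pid == "") || any(sid == "")) {
    stop("'values' must have non-empty rownames (proteins) and colnames (samples)")
  }
  if (anyDuplicated(pid)) {
    stop("duplicate protein ids: ", paste(unique(pid[duplicated(pid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (any(values < 0, na.rm = TRUE)) stop("abundances must be nonnegative")
  if (stage == "imputed" && anyNA(values)) {
    stop("stage 'imputed' must not contain missing values")
  }
  structure(list(values = values, stage = stage), class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("abundance_matrix: %d proteins x %d samples (stage: %s)\n",
              nrow(v), ncol(v), x$stage))
  cat(sprintf("  missing entries: %d (%.1f%%)\n",
              sum(is.na(v)), 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Extract the numeric matrix from an abundance_matrix
#'
#' @param x an `abundance_matrix` or a plain numeric matrix (returned as is).
#' @return numeric matrix, proteins x samples.
#' @export
abundance_values <- function(x) {
  if (inherits(x, "abundance_matrix")) x$values else x
}

#' Processing stage of an abundance matrix
#' @param x an `abundance_matrix`.
#' @export
abundance_stage <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  x$stage
}

# Coerce input to abundance_matrix; plain matrices get the given stage tag.
as_abundance <- function(x, stage = "raw") {
  if (inherits(x, "abundance_matrix")) x else abundance_matrix(x, stage = stage)
}

#' Validate per-sample metadata against an abundance matrix
#'
#' Checks that `meta` is a data frame with a `sample_id` column covering every
#' sample of `x`, and that `group` (if present) has exactly two levels.
#'
#' @param meta data frame of per-sample metadata.
#' @param x optional `abundance_matrix` whose samples must all be present.
#' @return `meta`, invisibly, with `group` coerced to factor.
#' @export
validate_sample_meta <- function(meta, x = NULL) {
  if (!is.data.frame(meta) || is.null(meta$sample_id)) {
    stop("metadata must be a data frame with a 'sample_id' column")
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!is.null(meta$group)) {
    meta$group <- factor(meta$group)
    if (nlevels(meta$group) != 2) {
      stop("'group' must take exactly two levels, got: ",
           paste(levels(meta$group), collapse = ", "))
    }
  }
  if (!is.null(x)) {
    sid <- colnames(abundance_values(x))
    miss <- setdiff(sid, meta$sample_id)
    if (length(miss)) {
      stop("samples missing from metadata: ", paste(miss, collapse = ", "))
    }
  }
  invisible(meta)
}

# Align metadata rows to matrix columns; errors on uncovered samples.
meta_for <- function(x, meta) {
  meta <- validate_sample_meta(meta, x)
  meta[match(colnames(abundance_values(x)), meta$sample_id), , drop = FALSE]
}
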