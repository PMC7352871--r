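#' Read a protein abundance matrix from TSV
#'
#' The expected layout is one header line, first column protein accession,
#' remaining columns one per sample. Empty cells, `NA`, `NaN` and (by
#' default) `0` are parsed as missing: an LFQ intensity of zero means the
#' protein was not quantified in that sample.
#'
#' @param path path to a tab-delimited text file.
#' @param stage stage tag to attach, see [abundance_matrix()].
#' @param zero_as_missing treat zeros as missing (default `TRUE`).
#' @return an [abundance_matrix()].
#' @export
read_abundance_matrix <- function(path, stage = "raw", zero_as_missing = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("", "NA", "NaN"),
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2) stop("format error: need a protein id column plus sample columns")
  pid <- df[[1]]
  if (anyDuplicated(pid)) {
    stop("format error: duplicate protein ids: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "))
  }
  cells <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("format error: non-numeric cell '%s' at protein %s, sample %s",
                 cells[bad[1, 1], bad[1, 2]], pid[bad[1, 1]],
                 colnames(cells)[bad[1, 2]]))
  }
  if (zero_as_missing) vals[!is.na(vals) & vals == 0] <- NA
  dimnames(vals) <- list(pid, colnames(cells))
  abundance_matrix(vals, stage = stage)
}

#' Write a protein abundance matrix to TSV
#'
#' Round-trips with [read_abundance_matrix()] up to float formatting
#' (values are written with full `digits = 17` precision).
#'
#' @param x an [abundance_matrix()] or numeric matrix.
#' @param path output path.
#' @param id_column header for the first column.
#' @export
write_abundance_matrix <- function(x, path, id_column = "protein_id") {
  v <- abundance_values(x)
  df <- data.frame(rownames(v), format(v, digits = 17, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[df == "NA"] <- NA
  names(df) <- c(id_column, colnames(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write per-sample metadata (CSV)
#'
#' @param path CSV path; must contain a `sample_id` column.
#' @return data frame with `group` (if present) as factor.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_meta(meta)
  if (!is.null(meta$group)) meta$group <- factor(meta$group)
  meta
}

#' @rdname read_sample_meta
#' @param meta data frame of per-sample metadata.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a GEO series-matrix text file
#'
#' Parses the standard series-matrix layout: metadata lines prefixed with
#' `!`, and a probe x sample expression table delimited by
#' `!series_matrix_table_begin` / `!series_matrix_table_end`. This replaces
#' on-line identifier extraction: probe-to-gene mapping is supplied
#' separately (see [map_panel_features()]).
#'
#' @param path path to an (uncompressed) series-matrix text file.
#' @return list with `matrix` (numeric, probes x samples), `samples`
#'   (data frame of `!Sample_*` annotation fields), `n_metadata_lines`,
#'   and `all_missing_probes` (probe ids with no finite value, retained in
#'   the matrix but flagged).
#' @export
read_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop("format error: missing !series_matrix_table_begin/end markers")
  }
  meta_lines <- grep("^!", lines[seq_len(beg - 1L)], value = TRUE)

  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)], header = TRUE,
                           sep = "\t", check.names = FALSE,
                           na.strings = c("", "NA", "null"),
                           stringsAsFactors = FALSE)
  probes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- probes
  # strip surrounding quotes GEO puts on sample ids
  colnames(mat) <- gsub('^"|"$', "", colnames(mat))

  samp <- grep("^!Sample_", meta_lines, value = TRUE)
  ann <- NULL
  if (length(samp)) {
    parts <- strsplit(samp, "\t", fixed = TRUE)
    nm <- make.unique(vapply(parts, function(p) sub("^!", "", p[[1]]), ""))
    vals <- lapply(parts, function(p) gsub('^"|"$', "", p[-1]))
    keep <- lengths(vals) == ncol(mat)
    if (any(keep)) {
      ann <- as.data.frame(stats::setNames(vals[keep], nm[keep]),
                           check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  all_missing <- probes[apply(mat, 1, function(r) all(!is.finite(r)))]
  list(matrix = mat, samples = ann, n_metadata_lines = length(meta_lines),
       all_missing_probes = all_missing)
}
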