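#' Construct an expression matrix
#'
#' The package's canonical container for expression data: a numeric matrix
#' with genes (probes) in rows and samples in columns, normalized and on a
#' log scale. Identifiers are opaque strings kept in the dimnames; they are
#' never parsed. All values must be finite: missing values are rejected
#' rather than imputed, because downstream SVM weights would silently
#' absorb any imputation artifact.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param probe_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `values`.
#' @return a matrix of class `expression_matrix`.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_data("expression values must be a numeric matrix")
  if (is.null(probe_ids) || is.null(sample_ids))
    abort_data("probe and sample identifiers are required")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values))
    abort_data("length(probe_ids) != nrow(values)")
  if (length(sample_ids) != ncol(values))
    abort_data("length(sample_ids) != ncol(values)")
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    abort_data("duplicate probe identifiers: ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    abort_data("duplicate sample identifiers: ", paste(dup, collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort_data("non-finite expression value at probe '", probe_ids[bad[1]],
               "', sample '", sample_ids[bad[2]], "'")
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples\n", nrow(x), ncol(x)))
  cat("probes:  ", paste(utils::head(rownames(x), 4), collapse = ", "),
      if (nrow(x) > 4) ", ..." else "", "\n", sep = "")
  cat("samples: ", paste(utils::head(colnames(x), 4), collapse = ", "),
      if (ncol(x) > 4) ", ..." else "", "\n", sep = "")
  invisible(x)
}

as_expression_matrix <- function(x) {
  if (inherits(x, "expression_matrix")) return(x)
  if (is.matrix(x)) return(expression_matrix(x))
  abort_data("cannot interpret object of class '", class(x)[1],
             "' as an expression matrix")
}

#' Read an expression matrix from tab-separated text
#'
#' Expects a header row and an identifier first column. By default genes
#' are in rows (the canonical orientation); `orientation =
#' "samples_in_rows"` transposes on read. Duplicated identifiers,
#' non-numeric cells and missing values are hard errors with locations —
#' nothing is imputed or dropped silently.
#'
#' @param path file path.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return an [expression_matrix].
#' @export
read_expression_tsv <- function(path,
                                orientation = c("genes_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort_data("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE,
                   quote = "\"", comment.char = "", na.strings = character(0))
  if (ncol(df) < 2) abort_data("expected an identifier column plus data columns: ", path)
  ids <- df[[1]]
  cells <- as.matrix(df[-1])
  trimmed <- trimws(cells)
  missing <- is.na(trimmed) | trimmed == "" | toupper(trimmed) %in% c("NA", "NAN")
  if (any(missing)) {
    at <- which(missing, arr.ind = TRUE)[1, ]
    abort_data("missing value at row '", ids[at[1]], "', column '",
               colnames(cells)[at[2]], "' (missing values are rejected, not imputed)")
  }
  vals <- suppressWarnings(array(as.numeric(trimmed), dim = dim(cells)))
  if (anyNA(vals)) {
    at <- which(is.na(vals), arr.ind = TRUE)[1, ]
    abort_data("non-numeric cell '", cells[at[1], at[2]], "' at row '",
               ids[at[1]], "', column '", colnames(cells)[at[2]], "'")
  }
  rownames(vals) <- ids
  colnames(vals) <- colnames(cells)
  if (orientation == "samples_in_rows") vals <- t(vals)
  expression_matrix(vals)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are printed with 17 significant digits so that a write/read
#' round-trip reproduces the matrix exactly.
#'
#' @param x an [expression_matrix].
#' @param path output file path.
#' @param id_column header of the identifier column.
#' @export
write_expression_tsv <- function(x, path, id_column = "probe_id") {
  x <- as_expression_matrix(x)
  chr <- formatC(unclass(x), digits = 17, format = "g")
  out <- cbind(rownames(x), chr)
  colnames(out) <- c(id_column, colnames(x))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO Series Matrix file
#'
#' Parses the standard text dialect: `!`-prefixed metadata lines and one
#' expression table delimited by `!series_matrix_table_begin` /
#' `!series_matrix_table_end`. Per-sample metadata lines (`!Sample_*`) are
#' captured verbatim as free text; class labels are *not* inferred — they
#' must come from a separate sample table (see [read_sample_table]).
#'
#' @param path file path.
#' @return a list with elements `matrix` (an [expression_matrix]) and
#'   `samples` (data frame of sample accessions and free-text metadata).
#' @export
read_geo_series_matrix <- function(path) {
  if (!file.exists(path)) abort_data("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1)
    abort_data("no !series_matrix_table_begin marker in ", path)
  if (length(end) != 1 || end <= begin + 1)
    abort_data("no !series_matrix_table_end marker (or empty table) in ", path)

  unquote <- function(x) gsub('^"|"$', "", x)
  table_lines <- lines[(begin + 1):(end - 1)]
  parts <- strsplit(table_lines, "\t", fixed = TRUE)
  width <- lengths(parts)
  if (length(unique(width)) != 1)
    abort_data("ragged series-matrix table: rows have ", min(width), "..",
               max(width), " fields")
  header <- unquote(parts[[1]])
  sample_ids <- header[-1]
  body <- parts[-1]
  ids <- unquote(vapply(body, `[`, "", 1))
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(body, `[`, -1))),
           nrow = length(body), byrow = TRUE))
  if (anyNA(vals)) abort_data("non-numeric or missing value in series-matrix table")
  rownames(vals) <- ids
  colnames(vals) <- sample_ids

  meta_lines <- grep("^!Sample_", lines[seq_len(begin - 1)], value = TRUE)
  samples <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (ln in meta_lines) {
    fields <- unquote(strsplit(ln, "\t", fixed = TRUE)[[1]])
    key <- sub("^!Sample_", "", fields[1])
    vals_meta <- rep_len(fields[-1], length(sample_ids))
    if (key %in% names(samples)) {
      samples[[key]] <- paste(samples[[key]], vals_meta, sep = "; ")
    } else {
      samples[[key]] <- vals_meta
    }
  }
  list(matrix = expression_matrix(vals), samples = samples)
}

#' Align an expression matrix with a sample table
#'
#' Reorders the matrix columns to the sample-table order and returns the
#' aligned class labels. Samples present in the matrix but absent from the
#' table are dropped with a notice; a table sample missing from the matrix
#' is an error. Expression values themselves are never modified.
#'
#' @param x an [expression_matrix].
#' @param samples a [sample_table].
#' @return list with `matrix` (columns in table order) and `labels`
#'   (integer 0/1 vector aligned to the columns).
#' @export
align_samples <- function(x, samples) {
  x <- as_expression_matrix(x)
  samples <- as_sample_table(samples)
  missing <- setdiff(samples$sample_id, colnames(x))
  if (length(missing))
    abort_data("samples absent from the expression matrix: ",
               paste(missing, collapse = ", "))
  dropped <- setdiff(colnames(x), samples$sample_id)
  if (length(dropped))
    message("align_samples: dropping ", length(dropped),
            " matrix column(s) not in the sample table: ",
            paste(dropped, collapse = ", "))
  out <- expression_matrix(unclass(x)[, samples$sample_id, drop = FALSE])
  list(matrix = out, labels = as.integer(samples$class_label))
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column to share the same value distribution: the target is
#' the row-wise mean of the per-column sorted values; each column's values
#' are replaced by the target value at their rank, and ties within a column
#' receive the mean of the target values over the tied span. This is the
#' quantile step of RMA only; background correction and probe summarization
#' are upstream concerns.
#'
#' @param x an [expression_matrix] with at least two samples.
#' @return a quantile-normalized [expression_matrix].
#' @export
quantile_normalize <- function(x) {
  x <- as_expression_matrix(x)
  if (ncol(x) < 2)
    abort_data("quantile normalization needs >= 2 samples (nothing to normalize against)")
  v <- unclass(x)
  target <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) {
    o <- order(col)
    grp <- cumsum(c(TRUE, diff(col[o]) != 0))
    res <- numeric(length(col))
    res[o] <- stats::ave(target, grp, FUN = mean)
    res
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out)
}
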