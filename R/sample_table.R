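#' Construct a sample metadata table
#'
#' Per-sample metadata with a binary class label: 1 for the condition coded
#' as the positive class (e.g. well watered), 0 for the other (drought).
#' `group` and `condition` are free text (genotype/line and stress
#' condition in the motivating design); `replicate` is a positive integer.
#'
#' @param df data frame with columns `sample_id` and `class_label`;
#'   `group`, `condition` and `replicate` are optional and default to
#'   placeholders.
#' @return data frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  if (!is.data.frame(df)) abort_data("sample table must be a data frame")
  need <- c("sample_id", "class_label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_data("sample table lacks column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup))
    abort_data("duplicate sample id(s): ", paste(dup, collapse = ", "))
  lab_num <- suppressWarnings(as.numeric(as.character(df$class_label)))
  bad <- is.na(lab_num) | !(lab_num %in% c(0, 1))
  if (any(bad)) {
    i <- which(bad)[1]
    abort_data("class label must be 0 or 1; sample '", df$sample_id[i],
               "' has label '", df$class_label[i], "'")
  }
  df$class_label <- as.integer(lab_num)
  if (is.null(df$group)) df$group <- NA_character_
  if (is.null(df$condition)) df$condition <- NA_character_
  if (is.null(df$replicate)) df$replicate <- 1L
  rep_num <- suppressWarnings(as.integer(df$replicate))
  if (anyNA(rep_num) || any(rep_num < 1))
    abort_data("replicate must be a positive integer")
  df$replicate <- rep_num
  out <- df[, c("sample_id", "group", "condition", "replicate", "class_label")]
  class(out) <- c("sample_table", "data.frame")
  out
}

as_sample_table <- function(x) {
  if (inherits(x, "sample_table")) return(x)
  if (is.data.frame(x)) return(sample_table(x))
  abort_data("cannot interpret object of class '", class(x)[1],
             "' as a sample table")
}

#' Read a sample metadata table from tab-separated text
#'
#' Expects a header with at least `sample_id` and `class_label` columns;
#' labels must parse as 0/1.
#'
#' @param path file path.
#' @return a [sample_table].
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort_data("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sample_table(df)
}

#' Write a sample table as tab-separated text
#' @param x a [sample_table].
#' @param path output file path.
#' @export
write_sample_table <- function(x, path) {
  x <- as_sample_table(x)
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Both classes must be present (and optionally >= min_per_class each)
# before a table is used for training.
check_two_classes <- function(labels, min_per_class = 1) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 < min_per_class || n0 < min_per_class)
    abort_data("need at least ", min_per_class, " sample(s) per class; got ",
               n1, " of class 1 and ", n0, " of class 0")
  invisible(TRUE)
}
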