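#' Construct a ranked gene list
#'
#' One SVM-RFE output: a total ordering of the input genes. Genes are
#' eliminated one (or a chunk) at a time; the gene eliminated last is the
#' best (rank 1). Each entry records the elimination step (1 = first
#' eliminated) and the squared-weight criterion the gene had when removed.
#'
#' @param probe_id character vector of gene identifiers (a permutation of
#'   the input gene set).
#' @param elimination_step integer vector, values exactly `1..G`.
#' @param criterion nonnegative numeric vector, the per-gene `w_i^2` at
#'   elimination.
#' @return data frame of class `ranked_list`, ordered best-first, with
#'   columns `rank`, `probe_id`, `elimination_step`, `criterion`.
#' @export
ranked_list <- function(probe_id, elimination_step, criterion) {
  probe_id <- as.character(probe_id)
  G <- length(probe_id)
  if (length(elimination_step) != G || length(criterion) != G)
    abort_data("ranked list fields must have equal length")
  if (anyDuplicated(probe_id))
    abort_data("ranked list contains duplicate probes: ",
               paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  step <- as.integer(round(elimination_step))
  if (!setequal(step, seq_len(G)))
    abort_data("elimination steps must be exactly 1..", G, " with no gaps")
  if (any(!is.finite(criterion)) || any(criterion < 0))
    abort_data("criterion values must be finite and nonnegative")
  o <- order(step, decreasing = TRUE) # last eliminated first
  out <- data.frame(rank = seq_len(G),
                    probe_id = probe_id[o],
                    elimination_step = step[o],
                    criterion = as.numeric(criterion)[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' @export
print.ranked_list <- function(x, n = 10, ...) {
  cat(sprintf("ranked_list: %d genes (rank 1 = last eliminated)\n", nrow(x)))
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("...", nrow(x) - n, "more\n")
  invisible(x)
}

#' Write / read a ranked list as tab-separated text
#' @param x a [ranked_list].
#' @param path file path.
#' @rdname ranked_list_io
#' @export
write_ranked_list <- function(x, path) {
  stopifnot(inherits(x, "ranked_list"))
  df <- as.data.frame(x)
  df$criterion <- formatC(df$criterion, digits = 17, format = "g")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ranked_list_io
#' @export
read_ranked_list <- function(path) {
  if (!file.exists(path)) abort_data("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("probe_id", "elimination_step", "criterion")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_data("ranked list file lacks column(s): ", paste(miss, collapse = ", "))
  ranked_list(df$probe_id, df$elimination_step, as.numeric(df$criterion))
}

# rank of each gene in `probes` within list x; absent genes get Inf
rank_in_list <- function(x, probes) {
  r <- setNames(x$rank, x$probe_id)[probes]
  r[is.na(r)] <- Inf
  unname(r)
}
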