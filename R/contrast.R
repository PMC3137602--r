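# Contrastive filtering: genes that rank highly for BOTH phenotype groups
# (e.g. drought-resistant and drought-susceptible genotypes) are "tuning
# genes" — generic stress responders rather than trait-specific candidates
# — and are removed from the target list.

top_prefix <- function(x, K, what) {
  probes <- if (inherits(x, "ranked_list")) x$probe_id
  else if (inherits(x, "aggregate_ranking")) x$probe_id
  else as.character(x)
  dup <- unique(probes[duplicated(probes)])
  if (length(dup))
    abort_data(what, " contains duplicate probes: ", paste(dup, collapse = ", "))
  if (K > length(probes))
    abort_config("K (", K, ") exceeds the length of ", what, " (", length(probes), ")")
  probes[seq_len(K)]
}

#' Find tuning genes shared by two top-K lists
#'
#' Intersects the top-`K` prefixes of two ranked gene lists (matching on
#' probe id, which is unambiguous) and removes the shared genes from list
#' A, preserving A's order and re-ranking the survivors `1..m`.
#'
#' @param list_a,list_b ordered probe-id character vectors, or
#'   [ranked_list] / [aggregate_ranking] objects (their order is used).
#'   `list_a` is the target (e.g. resistant) list that gets cleaned.
#' @param K prefix depth (study values: 10 and 100).
#' @return object of class `tuning_gene_report`: `list_a_top`,
#'   `list_b_top`, `tuning_genes` (data frame with each gene's rank in both
#'   lists), `cleaned` (data frame `rank`, `probe_id`).
#' @export
find_tuning_genes <- function(list_a, list_b, K) {
  if (!is.numeric(K) || length(K) != 1 || K < 1)
    abort_config("K must be a positive integer")
  a <- top_prefix(list_a, K, "list_a")
  b <- top_prefix(list_b, K, "list_b")
  shared <- a[a %in% b]
  tuning <- data.frame(probe_id = shared,
                       rank_a = match(shared, a),
                       rank_b = match(shared, b),
                       stringsAsFactors = FALSE)
  kept <- setdiff(a, shared)
  cleaned <- data.frame(rank = seq_along(kept), probe_id = kept,
                        stringsAsFactors = FALSE)
  structure(list(list_a_top = a, list_b_top = b,
                 tuning_genes = tuning, cleaned = cleaned, K = as.integer(K)),
            class = "tuning_gene_report")
}

#' @export
print.tuning_gene_report <- function(x, ...) {
  cat(sprintf("tuning_gene_report: top-%d vs top-%d, %d shared gene(s)\n",
              x$K, x$K, nrow(x$tuning_genes)))
  if (nrow(x$tuning_genes)) print(x$tuning_genes, row.names = FALSE)
  cat("cleaned list (", nrow(x$cleaned), " genes): ",
      paste(x$cleaned$probe_id, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Size of the overlap of two top-K lists
#'
#' @inheritParams find_tuning_genes
#' @return integer, `|top-K(a) intersect top-K(b)|`. Symmetric in its list
#'   arguments and nondecreasing in `K`.
#' @export
overlap_count <- function(list_a, list_b, K) {
  nrow(find_tuning_genes(list_a, list_b, K)$tuning_genes)
}

#' Write a tuning-gene report as tab-separated text
#'
#' Two files: `<path>` gets the tuning genes with their ranks in both
#' lists, `<cleaned_path>` the cleaned re-ranked list.
#'
#' @param x a `tuning_gene_report`.
#' @param path,cleaned_path output paths.
#' @export
write_tuning_report <- function(x, path, cleaned_path = NULL) {
  stopifnot(inherits(x, "tuning_gene_report"))
  write.table(x$tuning_genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cleaned_path))
    write.table(x$cleaned, cleaned_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
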