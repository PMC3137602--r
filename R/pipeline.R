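#' Assemble and validate a pipeline configuration
#'
#' All fields are validated up front, before any computation, and the full
#' configuration is serialized into the output directory as a manifest so
#' any run can be reproduced exactly from the manifest alone.
#'
#' @param matrix path to an expression TSV, or an [expression_matrix].
#' @param samples path to a sample-table TSV, or a [sample_table].
#' @param out output directory.
#' @param alpha t-test prefilter threshold (study value 0.001).
#' @param variant `"pooled"` or `"welch"` t-test.
#' @param C SVM cost.
#' @param standardize z-score genes per training fold.
#' @param n_folds,repetitions resampling design (study: 6 and 100).
#' @param N aggregation top-list depth (study: 10).
#' @param mode `"per_repetition"` or `"pooled"`.
#' @param seed master seed; every stochastic stage derives from it.
#' @param stratified stratify folds by class.
#' @param write_lists also write every ranked list under `out/lists/`.
#' @param geo_series_matrix optional: read the expression matrix from a
#'   GEO Series Matrix file instead of `matrix`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(matrix = NULL, samples = NULL, out = "rfet_out",
                       alpha = 0.001, variant = "pooled", C = 1,
                       standardize = TRUE, n_folds = 6L, repetitions = 100L,
                       N = 10L, mode = "per_repetition", seed = 17L,
                       stratified = FALSE, write_lists = FALSE,
                       geo_series_matrix = NULL) {
  if (is.null(matrix) && is.null(geo_series_matrix))
    abort_config("either 'matrix' or 'geo_series_matrix' is required")
  if (is.null(samples)) abort_config("'samples' is required")
  if (!variant %in% c("pooled", "welch"))
    abort_config("variant must be 'pooled' or 'welch'")
  if (!mode %in% c("per_repetition", "pooled"))
    abort_config("mode must be 'per_repetition' or 'pooled'")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1)
    abort_config("alpha must be in (0, 1]")
  if (!is.numeric(C) || C <= 0) abort_config("C must be positive")
  if (n_folds < 2) abort_config("n_folds must be >= 2")
  if (repetitions < 1) abort_config("repetitions must be >= 1")
  if (N < 1) abort_config("N must be >= 1")
  structure(list(matrix = matrix, samples = samples, out = out,
                 alpha = alpha, variant = variant, C = C,
                 standardize = isTRUE(standardize),
                 n_folds = as.integer(n_folds),
                 repetitions = as.integer(repetitions), N = as.integer(N),
                 mode = mode, seed = as.integer(seed),
                 stratified = isTRUE(stratified),
                 write_lists = isTRUE(write_lists),
                 geo_series_matrix = geo_series_matrix),
            class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config]; unknown keys are an error.
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file.
#' @return a [run_config].
#' @export
read_run_config <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE))
    abort_config("the 'yaml' package is required to read YAML configs")
  if (!file.exists(path)) abort_config("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort_config("config must be a YAML mapping")
  over <- list(...)
  cfg[names(over)] <- over
  unknown <- setdiff(names(cfg), names(formals(run_config)))
  if (length(unknown))
    abort_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, cfg)
}

load_inputs <- function(config) {
  mat <- if (!is.null(config$geo_series_matrix)) {
    read_geo_series_matrix(config$geo_series_matrix)$matrix
  } else if (is.character(config$matrix)) {
    read_expression_tsv(config$matrix)
  } else as_expression_matrix(config$matrix)
  st <- if (is.character(config$samples)) read_sample_table(config$samples)
        else as_sample_table(config$samples)
  align_samples(mat, st)
}

#' Run the full gene-selection pipeline
#'
#' Executes filter, ensemble and aggregation and writes every artifact
#' into the output directory: `filtered.tsv` (per-gene t, p and pass
#' flag), `final_ranking.tsv`, `occurrence.tsv` (top-10/top-30 stability
#' counts for the final top-N genes), `accuracy.tsv` (held-out fold
#' accuracies), optionally `lists/list_###.tsv`, and `manifest.json`
#' (config + seed + package version).
#'
#' @param config a [run_config].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `final`, `lists`, `accuracy`, `filtered`,
#'   `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) abort_config("config must come from run_config()")
  say <- function(...) if (!quiet) message("[rfet] ", ...)

  inp <- load_inputs(config)
  check_two_classes(inp$labels, min_per_class = 2)
  say("loaded ", nrow(inp$matrix), " genes x ", ncol(inp$matrix), " samples")

  tt <- ttest_per_gene(inp$matrix, inp$labels, variant = config$variant)
  keep <- filter_by_pvalue(tt, config$alpha)
  say("prefilter: ", length(keep), " genes with p < ", config$alpha)
  if (length(keep) < 2)
    abort_compute("no genes passed filter (", length(keep), " gene(s) with p < ",
                  config$alpha, "); raise alpha")

  sub <- expression_matrix(unclass(inp$matrix)[keep, , drop = FALSE])
  plan <- make_cv_plan(ncol(sub), config$n_folds, config$repetitions,
                       seed = config$seed, stratified = config$stratified,
                       labels = if (config$stratified) inp$labels else NULL)
  ens <- run_ensemble(sub, inp$labels, plan, C = config$C,
                      standardize = config$standardize, mode = config$mode)
  say(length(ens$lists), " ranked lists; mean held-out accuracy ",
      sprintf("%.3f", mean(ens$accuracy$accuracy)))

  N_used <- min(config$N, length(keep))
  if (N_used < config$N)
    say("N reduced to ", N_used, " (only ", length(keep), " genes survive the filter)")
  final <- aggregate_rankings(ens$lists, N = N_used)

  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out, f)
  filt_df <- data.frame(tt, pass = tt$p_value < config$alpha)
  write.table(filt_df, p("filtered.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_aggregate_ranking(final, p("final_ranking.tsv"))
  write.table(ens$accuracy, p("accuracy.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  top_genes <- final$probe_id[seq_len(min(N_used, nrow(final)))]
  occ <- data.frame(probe_id = top_genes,
                    top10 = top_n_occurrence(ens$lists, top_genes, min(10L, length(keep))),
                    top30 = top_n_occurrence(ens$lists, top_genes, min(30L, length(keep))),
                    row.names = NULL)
  write.table(occ, p("occurrence.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  if (config$write_lists) {
    dir.create(p("lists"), showWarnings = FALSE)
    for (i in seq_along(ens$lists))
      write_ranked_list(ens$lists[[i]], p(sprintf("lists/list_%03d.tsv", i)))
  }

  manifest <- config
  manifest$matrix <- if (is.character(config$matrix)) config$matrix else "<in-memory>"
  manifest$samples <- if (is.character(config$samples)) config$samples else "<in-memory>"
  manifest <- c(unclass(manifest),
                list(package_version = as.character(packageVersion("rfet")),
                     n_genes_input = nrow(inp$matrix),
                     n_genes_filtered = length(keep), N_used = N_used))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  say("artifacts written to ", config$out)
  invisible(list(final = final, lists = ens$lists, accuracy = ens$accuracy,
                 filtered = filt_df,
                 paths = list(out = config$out,
                              final_ranking = p("final_ranking.tsv"),
                              filtered = p("filtered.tsv"),
                              occurrence = p("occurrence.tsv"),
                              manifest = p("manifest.json"))))
}

#' Contrast two completed runs (or ranking files) for tuning genes
#'
#' Takes the final rankings of a target-group run and a contrast-group run
#' (paths to `final_ranking.tsv`, to plain ranked-list TSVs, or in-memory
#' objects), intersects their top-K, and writes the tuning-gene report and
#' the cleaned list. Mismatched gene universes produce a warning listing
#' the set differences; the intersection proceeds on probe ids.
#'
#' @param ranking_a,ranking_b rankings (target first).
#' @param K prefix depth.
#' @param out output directory.
#' @return (invisibly) the `tuning_gene_report`.
#' @export
run_contrast_pipeline <- function(ranking_a, ranking_b, K = 10L,
                                  out = "rfet_contrast") {
  load_ranking <- function(r) {
    if (is.character(r) && length(r) == 1 && file.exists(r)) {
      df <- read.delim(r, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
      if (!"probe_id" %in% names(df))
        abort_data("ranking file lacks a probe_id column: ", r)
      df$probe_id
    } else if (inherits(r, c("ranked_list", "aggregate_ranking"))) {
      r$probe_id
    } else as.character(r)
  }
  a <- load_ranking(ranking_a); b <- load_ranking(ranking_b)
  only_a <- setdiff(a, b); only_b <- setdiff(b, a)
  if (length(only_a) || length(only_b))
    warning("gene universes differ: ", length(only_a), " only in A, ",
            length(only_b), " only in B; intersecting on probe ids",
            call. = FALSE)
  rep <- find_tuning_genes(a, b, K)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_tuning_report(rep, file.path(out, "tuning_genes.tsv"),
                      file.path(out, "cleaned_list.tsv"))
  invisible(rep)
}
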