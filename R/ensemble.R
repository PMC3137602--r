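#' Build a repeated n-fold resampling plan
#'
#' Each repetition randomly partitions the samples into `n_folds` subsets
#' of near-equal size (sizes differ by at most one). Each subset is held
#' out once per repetition, so every sample has an equal chance to train;
#' `n_folds == n_samples` is leave-one-out. Splits are fully determined by
#' `seed`; the caller's RNG state is untouched.
#'
#' @param n_samples number of samples.
#' @param n_folds subsets per repetition, `2 <= n_folds <= n_samples`
#'   (typical choices: 12, 6, 4, 3).
#' @param repetitions number of independent repartitions (the study's `p`;
#'   its value was 100).
#' @param seed integer seed.
#' @param stratified balance classes across folds (needs `labels`); off by
#'   default — the procedure as described splits purely at random.
#' @param labels 0/1 labels, required when `stratified = TRUE`.
#' @return object of class `cv_plan`; `splits[[r]][[f]]` holds the
#'   held-out sample indices of fold `f` in repetition `r`.
#' @export
make_cv_plan <- function(n_samples, n_folds, repetitions = 1L, seed = 1L,
                         stratified = FALSE, labels = NULL) {
  if (n_folds < 2 || n_folds > n_samples)
    abort_config("n_folds must be in [2, n_samples]; got ", n_folds,
                 " for ", n_samples, " samples")
  if (repetitions < 1) abort_config("repetitions must be >= 1")
  if (stratified && is.null(labels))
    abort_config("stratified splitting needs labels")
  one_split <- function() {
    if (stratified) {
      fold_of <- integer(n_samples)
      nxt <- 0L
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- ((nxt + seq_along(idx) - 1L) %% n_folds) + 1L
        nxt <- nxt + length(idx)
      }
      lapply(seq_len(n_folds), function(f) sort(which(fold_of == f)))
    } else {
      perm <- sample(n_samples)
      sizes <- rep(n_samples %/% n_folds, n_folds)
      extra <- n_samples %% n_folds
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      ends <- cumsum(sizes)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      lapply(seq_len(n_folds), function(f) sort(perm[starts[f]:ends[f]]))
    }
  }
  splits <- with_seed(seed, lapply(seq_len(repetitions), function(r) one_split()))
  structure(list(n_samples = n_samples, n_folds = n_folds,
                 repetitions = as.integer(repetitions), seed = as.integer(seed),
                 stratified = stratified, splits = splits),
            class = "cv_plan")
}

# Merge the n fold-level lists of one repetition into a single ranked list:
# order by mean rank across folds, ties by mean criterion (higher first),
# then probe id. The merged criterion is the mean elimination criterion.
merge_ranked_lists <- function(lists) {
  probes <- lists[[1]]$probe_id
  G <- length(probes)
  ranks <- sapply(lists, rank_in_list, probes = probes)
  crits <- sapply(lists, function(l) setNames(l$criterion, l$probe_id)[probes])
  mean_rank <- rowMeans(ranks)
  mean_crit <- rowMeans(crits)
  o <- order(mean_rank, -mean_crit, probes)
  ranked_list(probes[o], seq(G, 1), mean_crit[o])
}

#' Run SVM-RFE over every training set of a resampling plan
#'
#' For each (repetition, fold), the training set is all samples minus the
#' held-out subset; SVM-RFE produces one fold-level ranked list. In
#' `"per_repetition"` mode (default) the `n_folds` fold lists of each
#' repetition are merged by mean rank into one list, yielding exactly
#' `repetitions` lists; `"pooled"` keeps every fold-level list
#' (`repetitions * n_folds` of them). Each fold's full-feature SVM also
#' classifies its held-out samples; the accuracies are logged for reporting
#' and never influence the ranking.
#'
#' @param x an [expression_matrix] (genes in rows).
#' @param labels 0/1 vector aligned to columns.
#' @param plan a [make_cv_plan] object for `ncol(x)` samples.
#' @param C,standardize,chunk,tol passed to [svm_rfe_rank].
#' @param mode `"per_repetition"` or `"pooled"`.
#' @return list with `lists` (the ranked lists), `accuracy` (data frame:
#'   repetition, fold, n_heldout, n_correct, accuracy) and `mode`.
#' @export
run_ensemble <- function(x, labels, plan, C = 1, standardize = TRUE,
                         chunk = 1L, tol = 1e-6,
                         mode = c("per_repetition", "pooled")) {
  mode <- match.arg(mode)
  x <- as_expression_matrix(x)
  if (!inherits(plan, "cv_plan")) abort_config("plan must come from make_cv_plan()")
  if (plan$n_samples != ncol(x))
    abort_config("plan was built for ", plan$n_samples, " samples but the matrix has ",
                 ncol(x))
  y <- encode_labels(labels)
  v <- unclass(x)
  n <- ncol(v)

  lists <- list()
  acc <- vector("list", plan$repetitions * plan$n_folds)
  ai <- 0L
  for (r in seq_len(plan$repetitions)) {
    fold_lists <- vector("list", plan$n_folds)
    for (f in seq_len(plan$n_folds)) {
      held <- plan$splits[[r]][[f]]
      train <- setdiff(seq_len(n), held)
      ytr <- y[train]
      if (length(unique(ytr)) < 2)
        abort_data("repetition ", r, ", fold ", f, ": training set is single-class; ",
                   "regenerate the plan with stratified = TRUE and a new seed")
      vtr <- v[, train, drop = FALSE]
      if (standardize) {
        st <- standardize_genes(vtr)
        vtr <- st$values
        vte <- (v[, held, drop = FALSE] - st$center) / st$scale
        vte[st$flat, ] <- 0
      } else {
        vte <- v[, held, drop = FALSE]
      }
      fold_lists[[f]] <- svm_rfe_rank(expression_matrix(vtr), ytr, C = C,
                                      standardize = FALSE, chunk = chunk, tol = tol)
      fit <- train_linear_svm(t(vtr), ytr, C = C, tol = tol)
      pred <- predict(fit, t(vte))
      ai <- ai + 1L
      acc[[ai]] <- data.frame(repetition = r, fold = f,
                              n_heldout = length(held),
                              n_correct = sum(pred == y[held]),
                              accuracy = mean(pred == y[held]))
    }
    if (mode == "per_repetition") {
      lists[[r]] <- merge_ranked_lists(fold_lists)
    } else {
      lists <- c(lists, fold_lists)
    }
  }
  list(lists = lists, accuracy = do.call(rbind, acc[seq_len(ai)]), mode = mode)
}

#' Aggregate many ranked lists into one final gene ranking
#'
#' The re-ranking measure combines, for each gene `j` over the `p` supplied
#' lists: its occurrence `O_j` (number of lists where it ranks within the
#' top `N`), its per-list elimination weights `w_jk`, and its per-list
#' ranks `r_jk`. The composite score is an occurrence-gated weight sum with
#' a linear rank discount:
#'
#'   `score_j = sum over lists k with r_jk <= N of  w_jk * (N - r_jk + 1) / N`
#'
#' Genes are sorted by score (descending), ties by `O_j` then probe id.
#' Genes never inside any top-`N` score 0 and are ordered after all scored
#' genes by their mean rank across lists. The result is a strict total
#' order regardless of input list order.
#'
#' @param lists list of [ranked_list] objects over the same gene universe.
#' @param N top-list depth (study value: 10).
#' @param p number of lists; must equal `length(lists)` (study value: 100).
#' @return data frame of class `aggregate_ranking` with columns
#'   `final_rank`, `probe_id`, `occurrence`, `weight_sum`, `score`,
#'   `mean_rank`.
#' @export
aggregate_rankings <- function(lists, N = 10L, p = length(lists)) {
  if (!length(lists)) abort_config("no ranked lists supplied")
  if (p != length(lists))
    abort_config("p (", p, ") must equal the number of lists (", length(lists), ")")
  if (N < 1) abort_config("N must be >= 1")
  G <- nrow(lists[[1]])
  if (N > G) abort_config("N (", N, ") exceeds list length (", G, ")")
  probes <- sort(unique(unlist(lapply(lists, `[[`, "probe_id"))))

  ranks <- sapply(lists, rank_in_list, probes = probes)
  crits <- sapply(lists, function(l) {
    cr <- setNames(l$criterion, l$probe_id)[probes]
    cr[is.na(cr)] <- 0
    unname(cr)
  })
  if (is.null(dim(ranks))) { ranks <- matrix(ranks, ncol = 1); crits <- matrix(crits, ncol = 1) }

  in_top <- is.finite(ranks) & ranks <= N
  occurrence <- rowSums(in_top)
  weight_sum <- rowSums(crits * in_top)
  score <- rowSums(crits * in_top * (N - ifelse(in_top, ranks, 0) + 1) / N)
  finite_ranks <- ranks; finite_ranks[!is.finite(ranks)] <- G + 1
  mean_rank <- rowMeans(finite_ranks)

  scored <- occurrence > 0
  o1 <- which(scored)[order(-score[scored], -occurrence[scored], probes[scored])]
  o2 <- which(!scored)[order(mean_rank[!scored], probes[!scored])]
  o <- c(o1, o2)
  out <- data.frame(final_rank = seq_along(o), probe_id = probes[o],
                    occurrence = as.integer(occurrence[o]),
                    weight_sum = weight_sum[o], score = score[o],
                    mean_rank = mean_rank[o], stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("aggregate_ranking", "data.frame")
  out
}

#' Count how often genes enter the top-N across lists
#'
#' The stability signal: for each queried gene, the number of lists in
#' which its rank is `<= N`. Genes absent from a list are treated as rank
#' infinity there. Typical depths are 10 and 30.
#'
#' @param lists list of [ranked_list] objects.
#' @param gene character vector of probe ids (one or many).
#' @param N top-list depth.
#' @return named integer vector of counts.
#' @export
top_n_occurrence <- function(lists, gene, N) {
  if (!length(lists)) abort_config("no ranked lists supplied")
  gene <- as.character(gene)
  ranks <- sapply(lists, rank_in_list, probes = gene)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = length(lists))
  setNames(as.integer(rowSums(is.finite(ranks) & ranks <= N)), gene)
}

#' Write an aggregate ranking as tab-separated text
#' @param x an `aggregate_ranking`.
#' @param path file path.
#' @export
write_aggregate_ranking <- function(x, path) {
  stopifnot(inherits(x, "aggregate_ranking"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
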