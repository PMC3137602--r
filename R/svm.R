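#' Train a linear soft-margin SVM
#'
#' Solves the standard SVM dual (sequential minimal optimization with
#' maximal-violating-pair selection, compiled) for a linear kernel. The
#' weight vector is recovered as `w = sum_k alpha_k y_k x_k`. The solver is
#' deterministic given `(X, y, C)`; the stopping tolerance on the KKT
#' violation gap is pinned (default `1e-6`) so results are reproducible
#' across platforms.
#'
#' @param X numeric matrix, samples in rows, genes (features) in columns.
#' @param y labels, either `-1/+1` or `0/1` (0 is mapped to -1; in the
#'   motivating design 1 = well watered, 0 = drought).
#' @param C soft-margin cost parameter, positive.
#' @param tol solver tolerance.
#' @param max_iter SMO iteration cap.
#' @return object of class `linear_svm`: `weights`, `bias`,
#'   `support_coefficients` (`alpha_k * y_k`), `alpha`, `cost_parameter`.
#' @export
train_linear_svm <- function(X, y, C = 1, tol = 1e-6, max_iter = 100000L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort_data("non-finite values in training matrix")
  y <- encode_labels(y)
  if (length(y) != nrow(X)) abort_data("length(y) != nrow(X)")
  if (length(unique(y)) < 2)
    abort_data("training labels contain a single class")
  if (!is.numeric(C) || length(C) != 1 || is.na(C) || C <= 0)
    abort_config("C must be a single positive number")
  fit <- .smo_train(X, y, C, tol, as.integer(max_iter))
  structure(list(weights = setNames(as.numeric(fit$weights), colnames(X)),
                 bias = as.numeric(fit$bias),
                 alpha = as.numeric(fit$alpha),
                 support_coefficients = as.numeric(fit$alpha) * y,
                 cost_parameter = C,
                 tol = tol),
            class = "linear_svm")
}

# map 0/1 or -1/+1 labels to -1/+1
encode_labels <- function(y) {
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1)))
    abort_data("labels must be 0/1 or -1/+1")
  y
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  score <- drop(newdata %*% object$weights) + object$bias
  ifelse(score >= 0, 1, -1)
}

#' Squared-weight elimination criterion
#'
#' The per-gene ranking criterion `c_i = w_i^2`: a second-order estimate of
#' the change in the SVM objective if gene `i` were removed. The gene with
#' the smallest criterion contributes least to the decision boundary and is
#' eliminated first.
#'
#' @param model a `linear_svm` fit, or a numeric weight vector.
#' @return nonnegative numeric vector.
#' @export
ranking_criterion <- function(model) {
  w <- if (inherits(model, "linear_svm")) model$weights else as.numeric(model)
  w^2
}

# z-score each gene (row) across samples; zero-variance genes become all 0
# with a warning rather than NaN.
standardize_genes <- function(v) {
  ctr <- rowMeans(v)
  scl <- apply(v, 1, sd)
  flat <- scl == 0 | !is.finite(scl)
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) standardized to 0", call. = FALSE)
    scl[flat] <- 1
  }
  out <- (v - ctr) / scl
  out[flat, ] <- 0
  list(values = out, center = ctr, scale = scl, flat = flat)
}

#' Rank genes by recursive feature elimination with a linear SVM
#'
#' Trains a linear SVM on the surviving genes, removes the gene with the
#' smallest squared weight, and repeats until no genes remain (sequential
#' backward selection). The returned list orders genes from last eliminated
#' (rank 1, most discriminative) to first eliminated.
#'
#' Ties on the criterion eliminate the gene occurring *later* in the
#' current gene order — a fixed, documented rule so runs are deterministic.
#' With `standardize = TRUE` (default) each gene is z-scored across the
#' training samples first, making the elimination order invariant to
#' per-gene rescaling; zero-variance genes are set to 0 with a warning.
#'
#' @param x an [expression_matrix] (genes in rows) or plain matrix with
#'   probe ids as rownames.
#' @param labels 0/1 (or -1/+1) vector aligned to columns.
#' @param C soft-margin cost (default 1, the common solver default).
#' @param standardize z-score genes on the training samples first.
#' @param chunk genes removed per iteration; 1 (the default) is the
#'   faithful one-at-a-time procedure, larger values are a documented
#'   speedup for very wide matrices.
#' @param tol,max_iter SMO solver controls.
#' @return a [ranked_list].
#' @export
svm_rfe_rank <- function(x, labels, C = 1, standardize = TRUE, chunk = 1L,
                         tol = 1e-6, max_iter = 100000L) {
  x <- as_expression_matrix(x)
  if (nrow(x) < 2) abort_data("RFE needs at least 2 genes")
  y <- encode_labels(labels)
  if (length(y) != ncol(x)) abort_data("length(labels) != number of samples")
  if (length(unique(y)) < 2) abort_data("labels contain a single class")
  if (!is.numeric(C) || length(C) != 1 || C <= 0)
    abort_config("C must be a single positive number")

  v <- unclass(x)
  if (standardize) v <- standardize_genes(v)$values
  res <- .rfe_rank(t(v), y, C, tol, as.integer(max_iter), as.integer(chunk))
  ranked_list(rownames(v), res$elimination_step, res$criterion)
}
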