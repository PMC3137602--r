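#' Per-gene two-sample t-test
#'
#' Screens every gene for a class-mean difference before the (expensive)
#' RFE stage. The default is the classical pooled-variance two-sample t;
#' Welch's unequal-variance variant is available. P-values are two-sided:
#' no directional hypothesis is imposed.
#'
#' Degenerate genes — zero variance in both groups with equal means — get
#' `t = 0, p = 1` and are flagged; zero pooled variance with unequal means
#' gets `p = 0` with a warning (an infinite-evidence artifact of constant
#' groups, not a meaningful statistic).
#'
#' @param x an [expression_matrix] (genes in rows).
#' @param labels binary 0/1 vector aligned to the columns of `x`; each
#'   class needs at least two samples.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return data frame of class `gene_test_result` with columns `probe_id`,
#'   `t_statistic`, `df`, `p_value`, `mean_class1`, `mean_class0`,
#'   `degenerate`, one row per gene in input order.
#' @export
ttest_per_gene <- function(x, labels, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  x <- as_expression_matrix(x)
  labels <- as.integer(labels)
  if (length(labels) != ncol(x))
    abort_data("length(labels) != number of samples")
  if (!all(labels %in% c(0L, 1L)))
    abort_data("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2 || n0 < 2)
    abort_data("each class needs >= 2 samples for a variance estimate; got ",
               n1, " and ", n0)

  v <- unclass(x)
  x1 <- v[, labels == 1L, drop = FALSE]
  x0 <- v[, labels == 0L, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  s1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  s0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  diff <- m1 - m0

  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1 + (n0 - 1) * s0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, nrow(v))
  } else {
    se <- sqrt(s1 / n1 + s0 / n0)
    df <- (s1 / n1 + s0 / n0)^2 /
      ((s1 / n1)^2 / (n1 - 1) + (s0 / n0)^2 / (n0 - 1))
  }

  zero_se <- se == 0
  degenerate <- zero_se & diff == 0
  infinite <- zero_se & diff != 0
  tt <- ifelse(zero_se, 0, diff / ifelse(zero_se, 1, se))
  df[zero_se] <- n1 + n0 - 2
  p <- 2 * pt(-abs(tt), df)
  tt[degenerate] <- 0; p[degenerate] <- 1
  tt[infinite] <- sign(diff[infinite]) * Inf
  p[infinite] <- 0
  if (any(infinite))
    warning(sum(infinite), " gene(s) constant within both groups with ",
            "unequal means: p set to 0", call. = FALSE)

  out <- data.frame(probe_id = rownames(v), t_statistic = tt, df = df,
                    p_value = p, mean_class1 = m1, mean_class0 = m0,
                    degenerate = degenerate, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("gene_test_result", "data.frame")
  out
}

#' Filter genes by t-test p-value
#'
#' Keeps genes with `p_value < alpha` (strict). No multiple-testing
#' correction is applied: the procedure this package implements uses a raw
#' p-value cutoff as a complexity-reduction step, not an inference.
#'
#' @param results output of [ttest_per_gene].
#' @param alpha threshold in `(0, 1]`; the motivating study used `0.001`.
#' @return character vector of passing probe ids, in input order.
#' @export
filter_by_pvalue <- function(results, alpha) {
  if (!is.data.frame(results) || !nrow(results))
    abort_data("empty t-test results")
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    abort_config("alpha must be a single value in (0, 1]")
  results$probe_id[results$p_value < alpha]
}
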