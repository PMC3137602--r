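mk <- function(values_by_gene, samples = NULL) {
  m <- do.call(rbind, values_by_gene)
  rownames(m) <- names(values_by_gene)
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  expression_matrix(m)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pooled t matches the closed form on the worked example", {
  # class 1: (1,2,3), class 0: (4,5,6): t = -3 / sqrt(2/3), df = 4
  m <- mk(list(g1 = c(1, 2, 3, 4, 5, 6)))
  res <- ttest_per_gene(m, c(1, 1, 1, 0, 0, 0), variant = "pooled")
  expect_equal(res$t_statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(-3 / sqrt(2 / 3)), 4), tolerance = 1e-12)
})

test_that("degenerate genes are handled as contracted", {
  m <- mk(list(sym = c(1, 3, 2, 2, 3, 1),   # equal means, nonzero variance
               flat = rep(5, 6),            # constant everywhere
               split = c(1, 1, 1, 2, 2, 2)))# zero variance, unequal means
  expect_warning(res <- ttest_per_gene(m, c(1, 1, 1, 0, 0, 0)), "p set to 0")
  expect_equal(res$t_statistic[1], 0)
  expect_equal(res$p_value[1], 1)
  expect_false(res$degenerate[1])
  expect_equal(res$t_statistic[2], 0)
  expect_equal(res$p_value[2], 1)
  expect_true(res$degenerate[2])
  expect_equal(res$p_value[3], 0)
  expect_true(is.infinite(res$t_statistic[3]) && res$t_statistic[3] < 0)
})

test_that("class-size preconditions are enforced", {
  m <- toy_matrix(3, 3)
  expect_error(ttest_per_gene(m, c(1, 0, 0)), ">= 2 samples",
               class = "rfet_data_error")
})

test_that("pooled p-values match the textbook oracle to 1e-12", {
  set.seed(21)
  for (rep in 1:5) {
    m <- expression_matrix(matrix(rnorm(200), 20, 10,
                                  dimnames = list(sprintf("g%d", 1:20),
                                                  sprintf("s%d", 1:10))))
    lab <- sample(rep(c(1, 0), 5))
    res <- ttest_per_gene(m, lab, variant = "pooled")
    for (i in 1:20) {
      o <- oracle_pooled_t(unclass(m)[i, lab == 1], unclass(m)[i, lab == 0])
      expect_equal(res$t_statistic[i], o$t, tolerance = 1e-12)
      expect_equal(res$p_value[i], o$p, tolerance = 1e-12)
    }
  }
})

test_that("welch variant agrees with stats::t.test", {
  set.seed(22)
  m <- expression_matrix(matrix(rnorm(50), 5, 10,
                                dimnames = list(sprintf("g%d", 1:5),
                                                sprintf("s%d", 1:10))))
  lab <- rep(c(1, 0), each = 5)
  res <- ttest_per_gene(m, lab, variant = "welch")
  for (i in 1:5) {
    ref <- t.test(unclass(m)[i, lab == 1], unclass(m)[i, lab == 0])
    expect_equal(res$t_statistic[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-12)
    expect_equal(res$df[i], unname(ref$parameter), tolerance = 1e-12)
  }
})

test_that("label swap negates t and preserves p", {
  set.seed(23)
  m <- expression_matrix(matrix(rnorm(120), 12, 10,
                                dimnames = list(sprintf("g%d", 1:12),
                                                sprintf("s%d", 1:10))))
  lab <- rep(c(1, 0), each = 5)
  a <- ttest_per_gene(m, lab)
  b <- ttest_per_gene(m, 1 - lab)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("filter_by_pvalue is strict and monotone in alpha", {
  res <- data.frame(probe_id = c("a", "b", "c"),
                    p_value = c(0.0005, 0.01, 0.5))
  expect_identical(filter_by_pvalue(res, 0.001), "a")
  # boundary is exclusive
  res2 <- data.frame(probe_id = "x", p_value = 0.001)
  expect_identical(filter_by_pvalue(res2, 0.001), character(0))
  expect_error(filter_by_pvalue(res, 0), class = "rfet_config_error")
  expect_error(filter_by_pvalue(res, 1.5), class = "rfet_config_error")

  # alpha = 1 keeps everything non-degenerate (p < 1)
  m <- toy_matrix(6, 8, seed = 4)
  lab <- rep(c(1, 0), each = 4)
  tt <- ttest_per_gene(m, lab)
  expect_identical(filter_by_pvalue(tt, 1), tt$probe_id[tt$p_value < 1])

  # nesting over a grid of alphas
  set.seed(24)
  m2 <- expression_matrix(matrix(rnorm(300), 30, 10,
                                 dimnames = list(sprintf("g%d", 1:30),
                                                 sprintf("s%d", 1:10))))
  tt2 <- ttest_per_gene(m2, rep(c(1, 0), each = 5))
  alphas <- c(0.001, 0.01, 0.05, 0.2, 1)
  sets <- lapply(alphas, function(a) filter_by_pvalue(tt2, a))
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})
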