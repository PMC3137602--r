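test_that("maximum-margin toy has the symmetric solution", {
  fit <- train_linear_svm(matrix(c(-1, 1), 2, 1), c(-1, 1), C = 100)
  expect_equal(unname(fit$weights), 1, tolerance = 1e-9)
  expect_equal(fit$bias, 0, tolerance = 1e-9)
})

test_that("duplicated feature columns share their weight", {
  set.seed(31)
  base <- c(rnorm(4, 2), rnorm(4, -2))
  X <- cbind(base, base, rnorm(8))
  fit <- train_linear_svm(X, c(rep(1, 4), rep(-1, 4)), C = 1)
  expect_lt(abs(fit$weights[1] - fit$weights[2]), 1e-6)
})

test_that("weights match the dual-QP oracle and the dual expansion", {
  skip_if_not_installed("quadprog")
  set.seed(32)
  for (i in 1:20) {
    X <- matrix(rnorm(18), 6, 3)
    y <- c(1, 1, 1, -1, -1, -1)
    for (C in c(0.5, 1, 10)) {
      fit <- train_linear_svm(X, y, C = C)
      expect_equal(unname(fit$weights), qp_svm_weights(X, y, C),
                   tolerance = 1e-5)
      # w must equal sum_k alpha_k y_k x_k
      expect_equal(unname(fit$weights),
                   drop(t(X) %*% fit$support_coefficients), tolerance = 1e-6)
      expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= C + 1e-12))
    }
  }
})

test_that("training rejects degenerate inputs", {
  X <- matrix(rnorm(8), 4, 2)
  expect_error(train_linear_svm(X, c(1, 1, 1, 1)), "single class",
               class = "rfet_data_error")
  X[1, 1] <- NA
  expect_error(train_linear_svm(X, c(1, 1, -1, -1)), "non-finite",
               class = "rfet_data_error")
  expect_error(train_linear_svm(matrix(rnorm(8), 4, 2), c(1, 1, -1, -1), C = -1),
               class = "rfet_config_error")
})

test_that("ranking criterion is the squared weight", {
  expect_equal(ranking_criterion(c(3, -2, 0)), c(9, 4, 0))
  expect_equal(ranking_criterion(rep(0, 4)), rep(0, 4))
  set.seed(33)
  w <- rnorm(10)
  expect_identical(which.min(ranking_criterion(w)), which.min(abs(w)))
})

test_that("RFE forces the obvious elimination order on a constructed case", {
  set.seed(34)
  lab <- rep(c(1, 0), each = 4)
  m <- rbind(signal = ifelse(lab == 1, 1, -1) + rnorm(8, sd = 0.01),
             noise = rnorm(8),
             flat = rep(3, 8))
  colnames(m) <- sprintf("s%d", 1:8)
  expect_warning(rl <- svm_rfe_rank(expression_matrix(m), lab), "zero-variance")
  expect_identical(rl$probe_id, c("signal", "noise", "flat"))
  expect_identical(rl$elimination_step, c(3L, 2L, 1L))
})

test_that("RFE elimination order matches the from-scratch QP oracle", {
  skip_if_not_installed("quadprog")
  set.seed(35)
  lab <- rep(c(1, 0), each = 4)
  for (i in 1:10) {
    v <- matrix(rnorm(32), 4, 8)
    v[1, lab == 1] <- v[1, lab == 1] + 2  # one real signal gene
    rownames(v) <- sprintf("g%d", 1:4)
    colnames(v) <- sprintf("s%d", 1:8)
    vs <- rfet:::standardize_genes(v)$values
    mine <- svm_rfe_rank(expression_matrix(vs), lab, standardize = FALSE)
    expect_identical(mine$probe_id, oracle_rfe(vs, lab))
  }
})

test_that("RFE output is a permutation, deterministic, and scale-robust", {
  set.seed(36)
  lab <- rep(c(1, 0), each = 5)
  for (i in 1:5) {
    v <- matrix(rnorm(15 * 10), 15, 10,
                dimnames = list(sprintf("g%02d", 1:15), sprintf("s%d", 1:10)))
    m <- expression_matrix(v)
    rl <- svm_rfe_rank(m, lab)
    expect_setequal(rl$probe_id, rownames(v))
    expect_setequal(rl$elimination_step, 1:15)
    # determinism
    expect_identical(as.data.frame(svm_rfe_rank(m, lab))$probe_id, rl$probe_id)
    # scaling one gene's row leaves the standardized order unchanged
    v2 <- v; v2[7, ] <- v2[7, ] * 1000
    expect_identical(svm_rfe_rank(expression_matrix(v2), lab)$probe_id,
                     rl$probe_id)
  }
})

test_that("chunked elimination still yields a valid full ranking", {
  set.seed(37)
  lab <- rep(c(1, 0), each = 5)
  m <- expression_matrix(matrix(rnorm(200), 20, 10,
                                dimnames = list(sprintf("g%02d", 1:20),
                                                sprintf("s%d", 1:10))))
  rl <- svm_rfe_rank(m, lab, chunk = 4)
  expect_setequal(rl$probe_id, rownames(m))
  expect_setequal(rl$elimination_step, 1:20)
})

test_that("predict.linear_svm separates what it trained on", {
  set.seed(38)
  X <- rbind(matrix(rnorm(20, 3), 10, 2), matrix(rnorm(20, -3), 10, 2))
  y <- c(rep(1, 10), rep(0, 10))
  fit <- train_linear_svm(X, y, C = 1)
  expect_equal(predict(fit, X), ifelse(y == 1, 1, -1))
})
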