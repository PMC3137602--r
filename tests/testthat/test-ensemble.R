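test_that("cv plans partition samples into near-equal disjoint folds", {
  plan <- make_cv_plan(12, 6, repetitions = 1, seed = 5)
  folds <- plan$splits[[1]]
  expect_length(folds, 6)
  expect_true(all(lengths(folds) == 2))
  expect_identical(sort(unlist(folds)), 1:12)

  # uneven division: sizes differ by at most one
  plan2 <- make_cv_plan(10, 4, repetitions = 3, seed = 5)
  for (r in 1:3) {
    sz <- lengths(plan2$splits[[r]])
    expect_lte(max(sz) - min(sz), 1)
    expect_identical(sort(unlist(plan2$splits[[r]])), 1:10)
  }

  # leave-one-out boundary
  loo <- make_cv_plan(7, 7, seed = 1)
  expect_true(all(lengths(loo$splits[[1]]) == 1))

  expect_error(make_cv_plan(5, 6), class = "rfet_config_error")
})

test_that("cv plans are seed-reproducible and leave the RNG alone", {
  a <- make_cv_plan(12, 6, 10, seed = 42)
  b <- make_cv_plan(12, 6, 10, seed = 42)
  expect_identical(a$splits, b$splits)
  expect_false(identical(a$splits,
                         make_cv_plan(12, 6, 10, seed = 43)$splits))
  set.seed(99); before <- rnorm(1)
  make_cv_plan(12, 6, 10, seed = 1)
  set.seed(99)
  expect_identical(before, rnorm(1))
})

test_that("stratified plans keep both classes in every training set", {
  lab <- rep(c(1, 0), each = 6)
  plan <- make_cv_plan(12, 6, 20, seed = 3, stratified = TRUE, labels = lab)
  for (r in 1:20) for (f in 1:6) {
    train <- setdiff(1:12, plan$splits[[r]][[f]])
    expect_gte(length(unique(lab[train])), 2)
  }
})

test_that("ensemble produces the contracted number of lists", {
  sim <- simulate_expression(synthetic_spec(n_genes = 12, n_per_class = 5,
                                            n_informative = 1, seed = 8))
  lab <- sim$samples$class_label
  plan <- make_cv_plan(10, 3, repetitions = 2, seed = 7)
  per_rep <- run_ensemble(sim$matrix, lab, plan, mode = "per_repetition")
  expect_length(per_rep$lists, 2)
  pooled <- run_ensemble(sim$matrix, lab, plan, mode = "pooled")
  expect_length(pooled$lists, 6)
  # every list is a full permutation
  for (l in pooled$lists) expect_setequal(l$probe_id, rownames(sim$matrix))
  # accuracy log covers every fold
  expect_identical(nrow(per_rep$accuracy), 6L)
  expect_true(all(per_rep$accuracy$accuracy >= 0 & per_rep$accuracy$accuracy <= 1))
})

test_that("single-class training folds are rejected with advice", {
  m <- toy_matrix(5, 6, seed = 12)
  lab <- c(1, 1, 1, 1, 1, 0)
  plan <- make_cv_plan(6, 2, seed = 1) # one fold must contain the lone 0
  expect_error(run_ensemble(m, lab, plan), "stratified",
               class = "rfet_data_error")
})

test_that("a perfectly separating gene tops the merged repetition list", {
  lab <- rep(c(1, 0), each = 4)
  set.seed(13)
  v <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:8)))
  v[3, ] <- ifelse(lab == 1, 2, -2) + rnorm(8, sd = 0.05)
  plan <- make_cv_plan(8, 8, repetitions = 1, seed = 2) # LOOCV
  ens <- run_ensemble(expression_matrix(v), lab, plan)
  expect_length(ens$lists, 1)
  expect_identical(ens$lists[[1]]$probe_id[1], "g3")
})

test_that("aggregation reproduces hand-computed scores exactly", {
  # three 5-gene lists, N = 2; discount is 1 at rank 1, 0.5 at rank 2
  L1 <- make_list(c("a", "b", "c", "d", "e"), c(4, 3, 2, 1, 0.5))
  L2 <- make_list(c("b", "a", "d", "c", "e"), c(5, 2, 2, 1, 0.25))
  L3 <- make_list(c("a", "c", "b", "e", "d"), c(6, 1, 3, 0.5, 0.1))
  agg <- aggregate_rankings(list(L1, L2, L3), N = 2)
  expect_identical(agg$probe_id, c("a", "b", "c", "d", "e"))
  # a: 4*1 + 2*0.5 + 6*1 ; b: 3*0.5 + 5*1 ; c: 1*0.5
  expect_equal(agg$score, c(11, 6.5, 0.5, 0, 0))
  expect_identical(agg$occurrence, c(3L, 2L, 1L, 0L, 0L))
  expect_equal(agg$weight_sum, c(12, 8, 1, 0, 0))
  # unscored genes ordered by mean rank: d = (4+3+5)/3 < e = (5+5+4)/3
  expect_equal(agg$mean_rank[4:5], c(4, 14 / 3))
  expect_identical(agg$final_rank, 1:5)
})

test_that("aggregation is invariant to list order and monotone in N", {
  set.seed(14)
  lists <- replicate(6, {
    probes <- sample(sprintf("g%02d", 1:15))
    make_list(probes, sort(rexp(15), decreasing = TRUE))
  }, simplify = FALSE)
  a <- aggregate_rankings(lists, N = 5)
  b <- aggregate_rankings(rev(lists), N = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$score >= 0))
  # per-gene score is nondecreasing in N
  a10 <- aggregate_rankings(lists, N = 10)
  merged <- merge(as.data.frame(a), as.data.frame(a10), by = "probe_id")
  expect_true(all(merged$score.y >= merged$score.x - 1e-12))
  expect_error(aggregate_rankings(lists, N = 16), class = "rfet_config_error")
})

test_that("single-list aggregation preserves the input order", {
  L <- make_list(sprintf("g%d", 1:6), c(9, 7, 5, 3, 2, 1))
  agg <- aggregate_rankings(list(L), N = 6)
  expect_identical(agg$probe_id, L$probe_id)
  # dominant gene: rank 1 everywhere with the largest weights
  expect_identical(agg$final_rank[agg$probe_id == "g1"], 1L)
})

test_that("top_n_occurrence counts and bounds behave", {
  L1 <- make_list(c("a", "b", "c"), c(3, 2, 1))
  L2 <- make_list(c("b", "a", "c"), c(3, 2, 1))
  lists <- list(L1, L2)
  expect_identical(unname(top_n_occurrence(lists, "a", 1)), 1L)
  expect_identical(unname(top_n_occurrence(lists, "a", 2)), 2L)
  expect_identical(unname(top_n_occurrence(lists, "zz", 3)), 0L)
  occ <- top_n_occurrence(lists, c("a", "b", "c"), 2)
  expect_identical(occ, c(a = 2L, b = 2L, c = 0L))
})
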