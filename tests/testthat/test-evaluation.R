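test_that("stratified splits follow the per-class rounding rule", {
  y8 <- rep(c(1, -1), each = 4)
  sp <- make_splits(y8, 5, 0.75, 1)
  for (s in sp) {
    expect_equal(sum(y8[s$train_idx] > 0), 3)
    expect_equal(sum(y8[s$train_idx] < 0), 3)
    expect_length(intersect(s$train_idx, s$test_idx), 0)
    expect_setequal(c(s$train_idx, s$test_idx), 1:8)
  }
  # 11 vs 32 at 75%: round-half-up gives 8 and 24 train subjects
  y43 <- c(rep(1, 11), rep(-1, 32))
  sp43 <- make_splits(y43, 3, 0.75, 2)
  expect_equal(sum(y43[sp43[[1]]$train_idx] > 0), 8)
  expect_equal(sum(y43[sp43[[1]]$train_idx] < 0), 24)
})

test_that("splits are reproducible from the master seed", {
  y <- rep(c(1, -1), c(6, 9))
  expect_identical(make_splits(y, 10, 0.75, 99), make_splits(y, 10, 0.75, 99))
  expect_false(identical(make_splits(y, 10, 0.75, 99),
                         make_splits(y, 10, 0.75, 100)))
})

test_that("splitting guards degenerate class sizes", {
  expect_error(make_splits(c(1, -1, -1, -1), 5, 0.75), "at least 2")
  expect_error(make_splits(rep(c(1, -1), each = 2), 5, 0.9),
               "empty train or test")
})

test_that("ROC AUC matches hand-computed and degenerate cases", {
  expect_equal(roc_auc(c(2, 1), c(1, -1)), 1.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, -1, 1, -1)), 0.75)
  expect_equal(roc_auc(rep(1, 6), rep(c(1, -1), 3)), 0.5)
  expect_error(roc_auc(1:3, rep(1, 3)), "both classes")
})

test_that("ROC AUC equals the brute-force pair count", {
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    npos <- sample(seq_len(n - 1), 1)
    y <- sample(c(rep(1, npos), rep(-1, n - npos)))
    scores <- round(rnorm(n), 1)  # ties likely
    expect_equal(roc_auc(scores, y), brute_auc(scores, y))
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    npos <- sample(2:(n - 2), 1)
    y <- sample(c(rep(1, npos), rep(-1, n - npos)))
    scores <- rnorm(n)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(y, levels = c(-1, 1)), predictor = scores,
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, y), ref)
  }
})

test_that("median AUC is invariant to monotone transforms of scores", {
  set.seed(3)
  scores <- rnorm(20)
  y <- rep(c(1, -1), 10)
  a1 <- roc_auc(scores, y)
  expect_equal(roc_auc(exp(scores), y), a1)
  expect_equal(roc_auc(100 + 3 * scores, y), a1)
})

test_that("PR-AUC endpoints and null behavior are correct", {
  expect_equal(pr_auc(c(3, 2, 1, 0), c(1, 1, -1, -1)), 1.0)
  expect_equal(pr_auc(c(5, 1, 2, 3), c(1, -1, -1, -1)), 1.0)
  expect_error(pr_auc(1:3, rep(-1, 3)), "at least one positive")
  set.seed(10)
  n <- 4000
  y <- c(rep(1, 1000), rep(-1, 3000))
  p_null <- pr_auc(rnorm(n), y)
  expect_gt(p_null, 0.20)
  expect_lt(p_null, 0.30)
  # trapezoidal variant agrees closely away from degenerate starts
  expect_equal(pr_auc(rnorm(n), y, method = "trapezoid"), 0.25,
               tolerance = 0.05)
})

test_that("permutation p-value respects floor, ceiling and determinism", {
  labels <- rep(c(1, -1), 8)
  per_split <- lapply(1:5, function(i)
    list(scores = rnorm(8), test_idx = seq(i, i + 7)))
  p_floor <- permutation_pvalue(2, per_split, labels, 999, seed = 1)
  expect_equal(p_floor, 1 / 1000)
  p_ceil <- permutation_pvalue(-1, per_split, labels, 99, seed = 1)
  expect_equal(p_ceil, 1.0)
  expect_identical(permutation_pvalue(0.6, per_split, labels, 199, seed = 7),
                   permutation_pvalue(0.6, per_split, labels, 199, seed = 7))
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(2024)
  B <- 99L
  n <- 16
  pvals <- vapply(1:300, function(r) {
    labels <- sample(rep(c(1, -1), n / 2))
    per_split <- lapply(1:8, function(i) {
      idx <- sample.int(n, 10)
      list(scores = rnorm(10), test_idx = idx)
    })
    obs <- median(vapply(per_split, function(s)
      roc_auc(s$scores, labels[s$test_idx]), 0.0))
    permutation_pvalue(obs, per_split, labels, B, seed = 5000 + r)
  }, 0.0)
  expect_lte(mean(pvals <= 0.05), 0.09)
  expect_lte(mean(pvals <= 0.2), 0.27)
  # empirical CDF never exceeds uniform by more than sampling noise
  grid <- seq(0.05, 0.95, by = 0.05)
  ecdf_vals <- vapply(grid, function(g) mean(pvals <= g), 0.0)
  expect_true(all(ecdf_vals <= grid + 0.07))
})

test_that("run_experiment shares splits, aggregates exactly, and is deterministic", {
  ds <- tiny_dataset(n_pos = 8, n_neg = 10, dims = c(a = 5L, b = 6L),
                     effect = 1.5, seed = 88)
  e1 <- run_experiment(ds, models = c("unimodal", "early_fusion", "mkl"),
                       n_splits = 12, n_permutations = 49, master_seed = 6)
  e2 <- run_experiment(ds, models = c("unimodal", "early_fusion", "mkl"),
                       n_splits = 12, n_permutations = 49, master_seed = 6)
  expect_identical(results_table(e1), results_table(e2))
  for (r in e1$results) {
    expect_equal(r$median_auc, median(r$per_split_auc))
    expect_true(all(r$per_split_auc >= 0 & r$per_split_auc <= 1))
    expect_gte(r$perm_pvalue, 1 / 50)
  }
  # one shared split plan across model families (paired design)
  expect_length(e1$archive$splits, 12)
  expect_named(e1$archive$per_model,
               c("unimodal_a", "unimodal_b", "early_fusion", "mkl"))
})

test_that("modality exclusion shapes the multimodal models only", {
  ds <- tiny_dataset(dims = c(a = 4L, b = 5L, c = 6L))
  e <- run_experiment(ds, models = c("unimodal", "mkl"),
                      multimodal_modalities = c("a", "b"),
                      n_splits = 5, n_permutations = 9, master_seed = 2)
  expect_named(e$archive$per_model$mkl$weights, c("a", "b"))
  expect_true("unimodal_c" %in% names(e$results))
})

test_that("every model stays near chance on label-free data", {
  ds <- generate_cohort(synthetic_spec(10, 14, c(a = 6L, b = 8L),
                                       effect_size = 0, seed = 5))
  e <- run_experiment(ds, models = c("unimodal", "early_fusion", "mkl"),
                      n_splits = 30, n_permutations = 19, master_seed = 9)
  for (r in e$results) {
    expect_gte(r$median_auc, 0.25)
    expect_lte(r$median_auc, 0.75)
  }
})
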