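test_that("solve_komd handles forced and symmetric solutions exactly", {
  # one subject per class: the only feasible point
  K <- random_psd(2, 1)
  expect_equal(unname(solve_komd(K, c(1, -1), 0.3)), c(1, 1))
  # identity kernel, pure ridge: uniform within class
  g <- solve_komd(diag(4), c(1, 1, -1, -1), lambda_reg = 1)
  expect_equal(unname(g), rep(0.5, 4), tolerance = 1e-8)
  # gamma lives on the bi-simplex
  y <- c(1, 1, 1, -1, -1)
  g2 <- solve_komd(random_psd(5, 3), y, 0.4)
  expect_true(all(g2 >= -1e-12))
  expect_equal(sum(g2[y > 0]), 1, tolerance = 1e-8)
  expect_equal(sum(g2[y < 0]), 1, tolerance = 1e-8)
})

test_that("solve_komd rejects invalid problems", {
  expect_error(solve_komd(diag(3), c(1, 1, 1), 0.5), "both classes")
  expect_error(solve_komd(diag(3), c(1, -1, 1), 1.5), "lambda_reg")
  indef <- matrix(c(1, 2, 2, 1), 2)
  expect_error(solve_komd(indef, c(1, -1), 0.5), "positive semidefinite")
})

test_that("solve_komd beats a fine bi-simplex grid on random problems", {
  sizes <- list(c(2, 2), c(2, 3), c(3, 2), c(3, 3))
  for (s in 1:4) {
    np_nn <- sizes[[s]]
    y <- c(rep(1, np_nn[1]), rep(-1, np_nn[2]))
    K <- random_psd(sum(np_nn), 100 + s)
    for (lambda in c(0, 0.5, 1)) {
      g <- solve_komd(K, y, lambda)
      f_sol <- komd_objective(K, y, lambda, g)
      f_grid <- grid_min_objective(K, y, lambda, step = 0.02)
      expect_lte(f_sol, f_grid + 1e-9)
    }
  }
})

test_that("solve_komd matches an interior-point QP solver", {
  skip_if_not_installed("kernlab")
  y <- c(1, 1, 1, 1, -1, -1, -1)
  K <- random_psd(7, 11)
  for (lambda in c(0.2, 0.8)) {
    g <- solve_komd(K, y, lambda)
    Q <- (1 - lambda) * (K * tcrossprod(y)) + diag(lambda, 7)
    A <- rbind(as.numeric(y > 0), as.numeric(y < 0))
    ip <- kernlab::ipop(c = rep(0, 7), H = 2 * Q, A = A, b = c(1, 1),
                        l = rep(0, 7), u = rep(10, 7), r = c(0, 0),
                        sigf = 9)
    f_mine <- komd_objective(K, y, lambda, g)
    f_ipop <- komd_objective(K, y, lambda, kernlab::primal(ip))
    expect_lte(f_mine, f_ipop + 1e-6)
    expect_equal(f_mine, f_ipop, tolerance = 1e-4)
  }
})

test_that("solve_komd solution beats random bi-simplex points", {
  set.seed(5)
  y <- c(rep(1, 4), rep(-1, 6))
  K <- random_psd(10, 21)
  g <- solve_komd(K, y, 0.3)
  f_sol <- komd_objective(K, y, 0.3, g)
  for (b in 1:2000) {
    cand <- numeric(10)
    rp <- rexp(4); rn <- rexp(6)
    cand[y > 0] <- rp / sum(rp)
    cand[y < 0] <- rn / sum(rn)
    expect_lte(f_sol, komd_objective(K, y, 0.3, cand) + 1e-10)
  }
})

test_that("easymkl weights are a probability vector with exact symmetries", {
  ds <- tiny_dataset()
  y <- ds$labels[1:10]
  ks1 <- build_kernel_set(ds, 1:10, include_modalities = "a")
  m1 <- easymkl_fit(ks1, y)
  expect_equal(unname(m1$eta), 1.0)

  ks <- build_kernel_set(ds, 1:10)
  m <- easymkl_fit(ks, y)
  expect_true(all(m$eta >= 0))
  expect_equal(sum(m$eta), 1, tolerance = 1e-10)
  expect_equal(sum(m$gamma[y > 0]), 1, tolerance = 1e-8)
  expect_equal(sum(m$gamma[y < 0]), 1, tolerance = 1e-8)

  # two byte-identical kernels split the weight evenly
  ks2 <- ks
  ks2$modalities <- list(a = ks$modalities$a, b = ks$modalities$a)
  ks2$modalities$b$train$modality <- "b"
  m2 <- easymkl_fit(ks2, y)
  expect_equal(unname(m2$eta), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("a kernel with no class information gets vanishing weight", {
  # label-aligned kernel vs epsilon-diagonal stand-in for an all-zero kernel
  y <- c(1, 1, -1, -1)
  x <- matrix(c(1, 1, -1, -1), 4, 1)
  k_sig <- normalize_kernel(linear_kernel(x, modality = "sig")$train)$train
  k_nil <- gram_matrix(diag(1e-12, 4), k_sig$row_subjects, k_sig$col_subjects,
                       modality = "nil")
  ks <- structure(list(modalities = list(sig = list(train = k_sig, test = NULL),
                                         nil = list(train = k_nil, test = NULL)),
                       train_subjects = k_sig$row_subjects,
                       test_subjects = NULL, normalization = "trace",
                       standardize = FALSE, features = NULL),
                  class = "kernel_set")
  m <- easymkl_fit(ks, y)
  expect_equal(unname(m$eta), c(1, 0), tolerance = 1e-6)
})

test_that("eta is invariant to modality ordering", {
  ds <- tiny_dataset(dims = c(a = 4L, b = 6L, c = 5L))
  y <- ds$labels[1:10]
  ks <- build_kernel_set(ds, 1:10)
  ks_rev <- ks
  ks_rev$modalities <- rev(ks$modalities)
  e1 <- easymkl_fit(ks, y)$eta
  e2 <- easymkl_fit(ks_rev, y)$eta
  expect_equal(e1[names(e2)], e2, tolerance = 1e-7)
})

test_that("eta is invariant to a common rescaling of the features", {
  ds <- tiny_dataset(dims = c(a = 4L, b = 6L))
  ds2 <- ds
  ds2$modalities <- lapply(ds$modalities, function(m) 3.7 * m)
  y <- ds$labels[1:10]
  e1 <- easymkl_fit(build_kernel_set(ds, 1:10), y)$eta
  e2 <- easymkl_fit(build_kernel_set(ds2, 1:10), y)$eta
  expect_equal(e1, e2, tolerance = 1e-8)
})

test_that("decision scores follow the composite-kernel expansion", {
  # all-zero test blocks: every score equals the bias
  ds <- tiny_dataset()
  y <- ds$labels[1:10]
  ks <- build_kernel_set(ds, 1:10, 11:14)
  m <- easymkl_fit(ks, y)
  ks0 <- ks
  for (nm in names(ks0$modalities))
    ks0$modalities[[nm]]$test$values[] <- 0
  expect_equal(unname(mkl_decision_scores(m, ks0)), rep(m$bias, 4))

  # hand evaluation with one train subject per class
  yy <- c(1, -1)
  kt <- gram_matrix(diag(2), c("p", "n"), c("p", "n"))
  kx <- gram_matrix(matrix(c(1, 0), 1), "z", c("p", "n"))
  ks1 <- structure(list(modalities = list(m = list(train = kt, test = kx)),
                        train_subjects = c("p", "n"), test_subjects = "z",
                        normalization = "trace", standardize = FALSE,
                        features = NULL), class = "kernel_set")
  m1 <- easymkl_fit(ks1, yy)   # gamma forced to [1, 1]
  expect_equal(unname(m1$gamma), c(1, 1))
  expect_equal(unname(mkl_decision_scores(m1, ks1)), 1 + m1$bias)
})

test_that("decision scoring validates modality and column order", {
  ds <- tiny_dataset()
  y <- ds$labels[1:10]
  ks <- build_kernel_set(ds, 1:10, 11:14)
  m <- easymkl_fit(ks, y)
  ks_missing <- ks
  ks_missing$modalities$a <- NULL
  expect_error(mkl_decision_scores(m, ks_missing), "lacks modalities")
  ks_scrambled <- ks
  ks_scrambled$modalities$a$test$col_subjects <-
    rev(ks_scrambled$modalities$a$test$col_subjects)
  expect_error(mkl_decision_scores(m, ks_scrambled), "column order")
})

test_that("primal weights reproduce kernel scores (dual equivalence)", {
  # direct evaluation on a two-subject problem with identity kernel
  x <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE,
              dimnames = list(c("p", "n"), c("f1", "f2")))
  ks <- linear_kernel(x)
  kset <- structure(list(modalities = list(m = list(train = ks$train, test = NULL)),
                         train_subjects = c("p", "n"), test_subjects = NULL,
                         normalization = "trace", standardize = FALSE,
                         features = NULL), class = "kernel_set")
  m <- easymkl_fit(kset, c(1, -1))
  w <- extract_primal_weights(m, list(m = x))
  expect_equal(unname(w$m), c(1, -1))

  # random multimodal fits: kernel score == primal score + bias
  for (s in 1:5) {
    ds <- tiny_dataset(seed = 200 + s, dims = c(a = 6L, b = 9L))
    y <- ds$labels[1:10]
    ks <- build_kernel_set(ds, 1:10, 11:14, keep_features = TRUE)
    fit <- easymkl_fit(ks, y)
    w <- extract_primal_weights(fit, lapply(ks$features, `[[`, "train"))
    kernel_scores <- mkl_decision_scores(fit, ks)
    primal_scores <- fit$bias +
      drop(ks$features$a$test %*% w$a) + drop(ks$features$b$test %*% w$b)
    expect_equal(unname(kernel_scores), unname(primal_scores),
                 tolerance = 1e-8)
  }
})

test_that("a zero-weight modality yields a zero primal weight vector", {
  y <- c(1, 1, -1, -1)
  x_sig <- matrix(c(1, 1, -1, -1), 4, 1, dimnames = list(letters[1:4], "s1"))
  x_nil <- matrix(0, 4, 2, dimnames = list(letters[1:4], c("n1", "n2")))
  k_sig <- normalize_kernel(linear_kernel(x_sig, modality = "sig")$train)$train
  k_nil <- gram_matrix(diag(1e-12, 4), letters[1:4], letters[1:4], "nil")
  ks <- structure(list(modalities = list(sig = list(train = k_sig, test = NULL),
                                         nil = list(train = k_nil, test = NULL)),
                       train_subjects = letters[1:4], test_subjects = NULL,
                       normalization = "trace", standardize = FALSE,
                       features = NULL), class = "kernel_set")
  m <- easymkl_fit(ks, y)
  w <- extract_primal_weights(m, list(sig = x_sig, nil = x_nil))
  expect_lt(max(abs(w$nil)), 1e-6)
})

test_that("single-kernel MKL ranks like plain KOMD on that kernel", {
  ds <- tiny_dataset(dims = c(a = 8L))
  y <- ds$labels[1:10]
  ks <- build_kernel_set(ds, 1:10, 11:14)
  m <- easymkl_fit(ks, y)
  sc_mkl <- mkl_decision_scores(m, ks)
  g <- solve_komd(ks$modalities$a$train$values, y)
  sc_komd <- drop(ks$modalities$a$test$values %*% (g * y))
  expect_equal(order(sc_mkl), order(sc_komd))
})

test_that("the SVM final-classifier variant is fit on the same composite kernel", {
  skip_if_not_installed("kernlab")
  ds <- tiny_dataset(n_pos = 8, n_neg = 10, effect = 2, seed = 61)
  y <- ds$labels[1:13]
  ks <- build_kernel_set(ds, 1:13, 14:18)
  mk <- easymkl_fit(ks, y)
  ms <- easymkl_fit(ks, y, final_classifier = "svm")
  expect_equal(mk$eta, ms$eta)  # eta depends only on step 1-2
  # both variants separate this easy cohort the same way
  expect_gt(cor(mkl_decision_scores(mk, ks), mkl_decision_scores(ms, ks),
                method = "spearman"), 0.7)
})

test_that("model serialization round-trips scores exactly", {
  ds <- tiny_dataset()
  y <- ds$labels[1:10]
  ks <- build_kernel_set(ds, 1:10, 11:14)
  m <- easymkl_fit(ks, y)
  path <- withr::local_tempfile(fileext = ".json")
  write_mkl_model(m, path)
  m2 <- read_mkl_model(path)
  expect_equal(mkl_decision_scores(m2, ks), mkl_decision_scores(m, ks))
  expect_equal(m2$eta, m$eta)
})
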