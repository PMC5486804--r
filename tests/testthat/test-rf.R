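test_that("Gini impurity takes its closed-form values and bounds", {
  expect_identical(gini_impurity(c(10, 0, 0)), 0)
  expect_equal(gini_impurity(rep(7, 5)), 0.8)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "positive total")
  expect_error(gini_impurity(c(-1, 2)), "nonnegative")
  set.seed(3)
  for (i in 1:20) {
    K <- sample(2:6, 1)
    h <- rpois(K, 5) + 1
    g <- gini_impurity(h)
    expect_gte(g, 0); expect_lte(g, 1 - 1 / K)
  }
})

test_that("candidate sampling yields the configured number of node tests", {
  set.seed(8)
  eval_data <- matrix(runif(50 * 400), 50, 400)
  cand <- sample_candidate_splits(400, eval_data, 100, 20)
  expect_identical(nrow(cand), 2000L)          # 100 x 20 tests per node
  expect_true(all(cand$p1 != cand$p2))
  expect_identical(nrow(sample_candidate_splits(400, eval_data, 1, 1)), 1L)
  # the conventional sqrt(p) budget this replaces would be only 20 tests
  expect_identical(floor(sqrt(400)), 20)
  # thresholds stay within the observed difference range of their pair
  for (j in unique(cand$p1)[1:5]) {
    rows <- cand$p1 == j
    p2 <- cand$p2[rows][1]
    d <- eval_data[, j] - eval_data[, p2]
    expect_true(all(cand$theta[rows & cand$p2 == p2] >= min(d) &
                      cand$theta[rows & cand$p2 == p2] <= max(d)))
  }
})

test_that("the chosen split maximizes subsample impurity decrease", {
  # two classes perfectly separated by pixel 1 against constant pixel 2
  set.seed(5)
  n <- 120
  X <- matrix(runif(n * 10), n, 10)
  y <- rep(1:2, each = n / 2)
  X[, 1] <- ifelse(y == 1, runif(n, 0, 0.3), runif(n, 0.7, 1))
  X[, 2] <- 0.5
  hyper <- rf_hyper(n_split_functions = 60, n_thresholds = 10,
                    n_eval_samples = 200, min_node_size = 5, max_depth = 4)
  sp <- best_split(X, y, K = 2, hyper, detail = TRUE)
  expect_false(is.null(sp))
  # subsample = full node here, so re-score every candidate independently
  for (i in seq_len(nrow(sp$candidates))) {
    d <- X[, sp$candidates$p1[i]] - X[, sp$candidates$p2[i]]
    expect_lte(gini_decrease_ref(y, d <= sp$candidates$theta[i], 2),
               sp$decrease + 1e-12)
  }
  # weighted child impurity never exceeds the parent's for the chosen split
  expect_gte(sp$decrease, 0)
  # a perfect separator exists among 600 candidates with high probability;
  # the chosen split should achieve pure children
  gl <- gini_impurity(tabulate(y[sp$left], 2))
  gr <- gini_impurity(tabulate(y[!sp$left], 2))
  expect_equal(gl + gr, 0)
  expect_identical(length(sp$eval_idx), as.integer(min(200, n)))
})

test_that("tree growth stops at depth, node-size and purity limits", {
  set.seed(6)
  X <- matrix(runif(99 * 16), 99, 16)
  y <- sample(1:3, 99, replace = TRUE)
  # immediate stop at depth 0
  t0 <- grow_tree(X, y, 3, rf_hyper(max_depth = 0, min_node_size = 5))
  expect_true(t0$leaf)
  expect_equal(sum(t0$prob), 1)
  expect_equal(t0$prob, tabulate(y, 3) / 99)
  # 99 samples < default min_node_size of 100
  t1 <- grow_tree(X, y, 3, rf_hyper(max_depth = 8, min_node_size = 100))
  expect_true(t1$leaf)
})

test_that("every training sample reaches exactly one leaf", {
  set.seed(9)
  n <- 300L
  X <- matrix(runif(n * 25), n, 25)
  y <- 1L + (X[, 3] > 0.5) + (X[, 17] > 0.6)
  tree <- grow_tree(X, y, 3, rf_hyper(max_depth = 5, min_node_size = 10,
                                      n_split_functions = 40))
  count_arrivals <- function(node, idx) {
    if (node$leaf) return(length(idx))
    d <- X[idx, node$p1] - X[idx, node$p2]
    count_arrivals(node$left, idx[d <= node$theta]) +
      count_arrivals(node$right, idx[d > node$theta])
  }
  expect_identical(count_arrivals(tree, seq_len(n)), n)
})

test_that("forests are deterministic, unbagged and tree-order invariant", {
  set.seed(10)
  n <- 150
  X <- matrix(runif(n * 16), n, 16)
  y <- 1L + (X[, 5] > 0.5)
  hyper <- rf_hyper(forest_size = 5, max_depth = 3, min_node_size = 10,
                    n_split_functions = 30, n_thresholds = 5)
  f1 <- train_forest(X, y, K = 2, hyper = hyper, seed = 4)
  f2 <- train_forest(X, y, K = 2, hyper = hyper, seed = 4)
  expect_identical(f1, f2)

  # single-tree forest prediction equals that tree's leaf histogram
  fs <- train_forest(X, y, K = 2, hyper = rf_hyper(1, 3, 30, 5, 200, 10),
                     seed = 7)
  v <- runif(16)
  expect_identical(predict_forest(fs, v)$prob, route_ref(fs$trees[[1]], v))

  # averaging is invariant to tree order
  fperm <- f1; fperm$trees <- rev(fperm$trees)
  for (i in 1:5) {
    v <- runif(16)
    expect_equal(predict_forest(f1, v)$prob, predict_forest(fperm, v)$prob)
  }
})

test_that("forest output is a distribution matching a brute-force tree walk", {
  set.seed(12)
  n <- 200
  X <- matrix(runif(n * 20), n, 20)
  y <- 1L + (X[, 2] > 0.4) + (X[, 11] > 0.7)
  f <- train_forest(X, y, K = 3,
                    hyper = rf_hyper(6, 4, 40, 8, 100, 15), seed = 2)
  for (i in 1:20) {
    v <- runif(20)
    p <- predict_forest(f, v)
    ref <- rowMeans(vapply(f$trees, route_ref, numeric(3), v = v))
    expect_equal(p$prob, ref)
    expect_equal(sum(p$prob), 1)
    expect_identical(p$class, which.max(ref))
  }
  # all trees agreeing on a pure leaf gives a one-hot distribution
  pure <- f
  pure$trees <- list(list(leaf = TRUE, prob = c(0, 1, 0), n = 1),
                     list(leaf = TRUE, prob = c(0, 1, 0), n = 1))
  expect_identical(predict_forest(pure, v)$prob, c(0, 1, 0))
  expect_error(predict_forest(structure(list(trees = list()),
                                        class = "rf_forest"), v), "untrained")
})

test_that("rotation augmentation replicates patches on the angle grid", {
  p <- smooth_patch(6)
  expect_length(augment_rotations(p, 0L), 360L)
  a5 <- augment_rotations(p, 5L)
  expect_length(a5, 72L)
  expect_length(augment_rotations(p, 10L), 36L)
  expect_identical(a5[[1]]$pixels, p$pixels)  # angle 0 copy is the original
  expect_identical(a5[[2]]$pixels, rotate_patch(p, 5)$pixels)
  expect_length(augment_rotations(list(p, p), 10L), 72L)
})

test_that("deeper trees never fit the training set worse", {
  ds <- tiny_dataset(counts = c(8L, 8L, 8L), delta = 1.2, seed = 21)
  X <- t(vapply(ds$patches, function(p) as.numeric(p$pixels), numeric(400)))
  y <- ds$manifest$label
  acc <- vapply(c(0L, 2L, 6L), function(d) {
    f <- train_forest(X, y, K = 3,
                      hyper = rf_hyper(4, d, 60, 10, 200, 4), seed = 31)
    mean(predict_forest(f, X)$class == y)
  }, 0)
  expect_true(all(diff(acc) >= 0))
})
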