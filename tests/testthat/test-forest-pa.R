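test_that("weight ranges follow the level schedule", {
  expect_equal(weight_range(1), c(0, exp(-1)))
  expect_equal(weight_range(2, rho = 0.01), c(exp(-1) + 0.01, exp(-1 / 2)))
  expect_error(weight_range(20, rho = 0.01), "too large")
  expect_error(weight_range(0), "at least 1")
  expect_error(weight_range(2, rho = 0), "positive")
  # upper bounds increase strictly toward 1 with depth
  ub <- exp(-1 / (1:50))
  expect_true(all(diff(ub) > 0))
  expect_lt(max(ub), 1)
})

test_that("merit damps gain multiplicatively", {
  expect_equal(merit(0.4, 0.5), 0.2)
  expect_equal(merit(0.7, 1), 0.7)
  expect_equal(merit(0, 0.3), 0)
  expect_error(merit(-0.1, 0.5), "nonnegative")
  expect_error(merit(0.1, 0), "weight")
})

test_that("perfectly separable 1-D data yields a depth-1 tree", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  tree <- build_pa_tree(x, y)
  expect_false(tree$is_leaf[1])
  expect_equal(tree$threshold[1], 6.5)
  expect_true(all(tree$is_leaf[-1]))
  expect_equal(tree$tested_levels, c(`1` = 1L))
  pred <- predict_tree(tree, x)
  expect_equal(as.integer(pred[, 2] >= 0.5), y)
})

test_that("equal weights reproduce the naive unweighted CART", {
  set.seed(61)
  for (rep in 1:4) {
    n <- 40L
    x <- matrix(rnorm(n * 3), n, 3)
    y <- as.integer(x[, 1] + 0.4 * rnorm(n) > 0)
    if (length(unique(y)) < 2) next
    tree <- build_pa_tree(x, y, weights = rep(1, 3))
    expect_same_tree(tree, oracle_cart(x, y))
  }
})

test_that("a harsh penalty can dethrone the informative attribute", {
  set.seed(62)
  n <- 60L
  informative <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  noise <- rnorm(n)
  x <- cbind(informative, noise)
  y <- rep(c(0L, 1L), each = n / 2)
  fair <- build_pa_tree(x, y, weights = c(1, 1))
  expect_equal(fair$feature[1], 1L)
  biased <- build_pa_tree(x, y, weights = c(1e-6, 1))
  expect_equal(biased$feature[1], 2L)
})

test_that("weight updates penalize tested attributes and heal the rest", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  x <- cbind(x, 0)  # second attribute constant: never tested
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  tree <- build_pa_tree(x, y)
  state <- list(weight = c(1, 0.9), increment = c(0, 0.2))
  set.seed(63)
  new <- update_weights(state, tree, rho = 0.01, n_trees = 10L)
  wr <- weight_range(1)
  expect_gte(new$weight[1], wr[1])
  expect_lte(new$weight[1], wr[2])
  expect_equal(new$increment[1], (1 - new$weight[1]) / 10)
  expect_equal(new$weight[2], 1)  # 0.9 + 0.2 capped at 1

  # degenerate single-leaf tree: nothing tested, only recovery applies
  leafy <- build_pa_tree(matrix(0, 4, 2), rep(1L, 4), n_classes = 2L)
  st2 <- update_weights(list(weight = c(0.5, 0.5),
                             increment = c(0.1, 0.3)), leafy)
  expect_equal(st2$weight, c(0.6, 0.8))
})

test_that("with penalties off the forest is exactly bagged CART", {
  set.seed(64)
  n <- 50L
  x <- matrix(rnorm(n * 3), n, 3)
  y <- as.integer(x[, 1] - x[, 2] > 0)
  n_trees <- 5L
  forest <- train_forest(x, y, n_trees = n_trees, seed = 9,
                         penalize = FALSE)
  # oracle: same bootstrap stream, naive recursive CART on each resample
  set.seed(9)
  for (i in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    expect_same_tree(forest$trees[[i]],
                     oracle_cart(x[boot, , drop = FALSE], y[boot]))
  }
})

test_that("penalization produces root diversity across trees", {
  set.seed(65)
  n <- 80L
  x <- matrix(rnorm(n * 5), n, 5)
  y <- as.integer(x[, 1] + 0.8 * x[, 2] + 0.3 * rnorm(n) > 0)
  forest <- train_forest(x, y, n_trees = 20L, seed = 10)
  roots <- vapply(forest$trees, function(tr) tr$feature[1], 0L)
  expect_gte(length(unique(roots)), 2L)
})

test_that("forests are deterministic, accurate on blobs, and normalized", {
  bl <- make_blobs(40, d = 4, seed = 66)
  f1 <- train_forest(bl$x, bl$y, n_trees = 25L, seed = 11)
  f2 <- train_forest(bl$x, bl$y, n_trees = 25L, seed = 11)
  p1 <- predict_forest(f1, bl$x)
  expect_identical(p1, predict_forest(f2, bl$x))
  expect_equal(unname(rowSums(p1)), rep(1, nrow(bl$x)))

  # out-of-bag style check on fresh draws from the same blobs
  fresh <- make_blobs(40, d = 4, seed = 67)
  acc <- mean((predict_forest(f1, fresh$x)[, 2] >= 0.5) == (fresh$y == 1))
  expect_gt(acc, 0.9)

  expect_error(train_forest(bl$x, rep(1L, nrow(bl$x))), "single class")
  expect_error(predict_forest(structure(list(), class = "list"), bl$x),
               "pa_forest")
  expect_error(predict_forest(f1, bl$x[, 1:2]), "features")
})

test_that("single-tree edge cases behave", {
  # one tree, no update has happened: equals one bagged CART
  set.seed(68)
  x <- matrix(rnorm(30), 15, 2)
  y <- as.integer(x[, 1] > 0)
  f <- train_forest(x, y, n_trees = 1L, seed = 12)
  set.seed(12)
  boot <- sample.int(15, 15, replace = TRUE)
  expect_same_tree(f$trees[[1]], oracle_cart(x[boot, , drop = FALSE],
                                             y[boot]))
  # pure-leaf predictions are 0/1
  p <- predict_forest(f, x)
  expect_true(all(p %in% c(0, 1) | (p >= 0 & p <= 1)))
  expect_error(build_pa_tree(x[0, , drop = FALSE], integer(0)), "empty")
})

test_that("serialized forests reload bit-equal in behaviour", {
  bl <- make_blobs(25, d = 3, seed = 69)
  f <- train_forest(bl$x, bl$y, n_trees = 8L, seed = 13)
  path <- withr::local_tempfile()
  write_forest(f, path)
  back <- read_forest(path)
  expect_equal(predict_forest(back, bl$x), predict_forest(f, bl$x))
  expect_equal(back$n_trees, f$n_trees)
  expect_equal(vapply(back$trees, function(t) length(t$feature), 0L),
               vapply(f$trees, function(t) length(t$feature), 0L))
})
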