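test_that("sample graphs are symmetric, self-looped and renormalized", {
  # three identical descriptors, k = 2: complete graph, all entries 1/3
  g <- build_sample_graph(matrix(1, 3, 4), k = 2)
  expect_equal(g$a_hat, matrix(1 / 3, 3, 3))

  # saturated k wires everything regardless of features
  set.seed(51)
  x <- matrix(rnorm(20), 5, 4)
  gs <- build_sample_graph(x, k = 4)
  expect_true(all(gs$a_hat > 0))

  # orthogonal one-hot features still keep the self-loop
  gd <- build_sample_graph(diag(4), k = 1)
  expect_true(all(diag(gd$a_hat) > 0))

  expect_error(build_sample_graph(x, k = 0), "positive")
  expect_error(build_sample_graph(x, k = 5), "smaller")

  # spectral normalization: symmetric, nonnegative
  expect_equal(gs$a_hat, t(gs$a_hat))
  expect_true(all(gs$a_hat >= 0))
})

test_that("the exact layer is the plain normalized propagation", {
  h <- matrix(c(1, 3), 2, 1)
  a <- matrix(0.5, 2, 2)
  w <- matrix(1, 1, 1)
  expect_equal(full_layer(h, a, w), matrix(2, 2, 1))
  expect_equal(full_layer(h, diag(2), diag(1)), h)
  # rectification kills all-negative pre-activations
  expect_equal(full_layer(h, a, -w, act = circlink:::relu),
               matrix(0, 2, 1))
  expect_error(full_layer(h, matrix(1, 3, 3), w), "conform")
})

test_that("exhaustive uniform sampling reproduces the exact layer", {
  set.seed(52)
  for (rep in 1:5) {
    n <- 10L
    a <- matrix(runif(n * n), n, n); a <- (a + t(a)) / 2
    h <- matrix(rnorm(n * 3), n, 3)
    w <- matrix(rnorm(6), 3, 2)
    q <- importance_distribution(a, "uniform")
    expect_equal(sampled_layer(h, a, w, q, t = n, exhaustive = TRUE),
                 full_layer(h, a, w), tolerance = 1e-10)
  }
})

test_that("sampled layers are seed-deterministic and near-unbiased", {
  a <- matrix(0.5, 2, 2)
  h <- matrix(c(1, 3), 2, 1)
  w <- matrix(1, 1, 1)
  q <- importance_distribution(a, "uniform")
  s1 <- sampled_layer(h, a, w, q, t = 50, seed = 7)
  expect_identical(s1, sampled_layer(h, a, w, q, t = 50, seed = 7))

  # CLT check: mean estimate within 3 standard errors of the exact value
  t_draw <- 1000L
  est <- sampled_layer(h, a, w, q, t = t_draw, seed = 8)
  # per-draw atoms are a_hat[v,u] h[u] / q(u): values {1, 3} equally likely
  se <- stats::sd(c(1, 3)) / sqrt(t_draw)
  expect_true(all(abs(est - 2) < 3 * se + 1e-9))
})

test_that("importance-sampled pre-activations are unbiased on a fixed graph", {
  set.seed(53)
  n <- 5L
  a <- matrix(runif(n * n, 0, 1), n, n); a <- (a + t(a)) / 2
  h <- matrix(rnorm(n * 2), n, 2)
  w <- diag(2)
  exact <- full_layer(h, a, w)
  q <- importance_distribution(a, "importance")
  draws <- 10000L
  acc <- matrix(0, n, 2)
  for (i in seq_len(draws)) {
    acc <- acc + sampled_layer(h, a, w, q, t = 3L)
  }
  est <- acc / draws
  # Monte-Carlo error bound: generous 3-sigma envelope on each entry
  expect_lt(max(abs(est - exact)), 0.12)
})

test_that("the column-norm proposal cuts variance on a hub graph", {
  # one high-degree hub: node 1 connected to everyone, spokes only to hub
  n <- 12L
  a <- matrix(0, n, n)
  a[1, ] <- a[, 1] <- 1
  diag(a) <- 1
  dinv <- 1 / sqrt(rowSums(a))
  a_hat <- a * tcrossprod(dinv)
  set.seed(54)
  h <- matrix(rnorm(n), n, 1)
  w <- matrix(1, 1, 1)
  qs <- lapply(c("uniform", "importance"), importance_distribution,
               a_hat = a_hat)
  var_of <- function(q) {
    ests <- replicate(600, sampled_layer(h, a_hat, w, q, t = 4L)[, 1])
    mean(apply(ests, 1, stats::var))
  }
  expect_lt(var_of(qs[[2]]), var_of(qs[[1]]))
})

test_that("zero-mass nodes with nonzero kernel columns raise a warning", {
  a <- matrix(0.5, 3, 3)
  h <- matrix(1, 3, 1)
  w <- matrix(1, 1, 1)
  q <- list(q = c(0.5, 0.5, 0), mode = "manual")
  expect_warning(sampled_layer(h, a, w, q, t = 5, seed = 1), "zero mass")
})

test_that("sampled batch loss matches closed forms and the exact loss", {
  set.seed(55)
  bl <- make_blobs(20, d = 3, seed = 55)
  g <- build_sample_graph(bl$x, k = 4)
  g$labels <- bl$y
  g$train_mask <- rep(TRUE, g$n)
  cfg <- gcn_config(hidden_dim = 8, epochs = 0, seed = 2)
  weights <- circlink:::init_gcn(ncol(bl$x), cfg)
  q <- importance_distribution(g$a_hat)
  exact <- batch_loss(weights, g, batch = 1:10, t = c(16L, 16L), q = q,
                      exhaustive = TRUE)
  expect_gt(exact, 0)
  # with zeroed weights the softmax is uniform: loss is exactly log 2
  zw <- lapply(weights, function(w) w * 0)
  expect_equal(batch_loss(zw, g, batch = 1:10, t = c(16L, 16L), q = q,
                          exhaustive = TRUE), log(2))
  expect_error(batch_loss(weights, g, batch = integer(0), t = c(4L, 4L),
                          q = q), "empty")
})

test_that("training is deterministic, label-blind off-mask, and learns blobs", {
  bl <- make_blobs(30, d = 4, seed = 56)
  g <- build_sample_graph(bl$x, k = 5)
  g$labels <- bl$y
  g$train_mask <- rep(c(TRUE, FALSE), length.out = g$n)
  cfg <- gcn_config(hidden_dim = 16, sample_sizes = c(24L, 24L),
                    batch_size = 16L, epochs = 60L, seed = 4)
  m1 <- train_fastgcn(g, cfg)
  m2 <- train_fastgcn(g, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_lt(utils::tail(m1$loss_trace, 1), log(2))

  # flipping labels outside the train mask never changes the weights
  g3 <- g
  g3$labels[!g3$train_mask] <- 1L - g3$labels[!g3$train_mask]
  m3 <- train_fastgcn(g3, cfg)
  expect_identical(m1$weights, m3$weights)

  # zero epochs: initialization untouched
  m0 <- train_fastgcn(g, gcn_config(hidden_dim = 16, epochs = 0, seed = 4))
  expect_identical(m0$weights, circlink:::init_gcn(4L, m0$config))

  g_bad <- g
  g_bad$labels[g_bad$train_mask] <- 1L
  expect_error(train_fastgcn(g_bad, cfg), "single class")
})

test_that("extracted features are penultimate activations for every node", {
  bl <- make_blobs(15, d = 4, seed = 57)
  g <- build_sample_graph(bl$x, k = 4)
  g$labels <- bl$y
  g$train_mask <- rep(TRUE, g$n)
  cfg <- gcn_config(hidden_dim = 6, sample_sizes = c(16L, 16L),
                    batch_size = 30L, epochs = 10L, seed = 5)
  m <- train_fastgcn(g, cfg)
  emb <- extract_features(m, g)
  expect_equal(dim(emb), c(g$n, 6L))
  expect_true(all(emb >= 0))  # ReLU output
  expect_equal(emb, circlink:::relu(g$a_hat %*% g$features %*% m$weights$w0))

  # identical descriptors with identical neighbourhoods embed identically
  # (saturated k so the neighbourhoods cannot differ by tie-breaking)
  x <- rbind(bl$x[1, ], bl$x[1, ], bl$x[3:10, ])
  gg <- build_sample_graph(x, k = nrow(x) - 1L)
  expect_equal(gg$a_hat[1, ], gg$a_hat[2, ], ignore_attr = TRUE)
  emb2 <- circlink:::relu(gg$a_hat %*% gg$features %*% m$weights$w0)
  expect_equal(emb2[1, ], emb2[2, ])

  p <- predict_gcn(m, g)
  expect_equal(unname(rowSums(p)), rep(1, g$n))
})
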