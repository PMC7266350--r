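#' Build the normalized graph over pair samples
#'
#' Graph convolution needs a graph over the training examples. Each pair
#' sample is a node carrying its fusion descriptor; nodes are wired by
#' k-nearest-neighbour search under cosine similarity, symmetrized by union
#' (an edge exists if either endpoint selects the other). Self-loops are
#' added and the adjacency is renormalized as
#' `D^{-1/2} (A + I) D^{-1/2}`, the standard propagation kernel.
#'
#' @param features numeric matrix, one descriptor per node.
#' @param k neighbours per node (0 < k < n).
#' @return a `sample_graph`: list with `n`, `a_hat` (dense normalized
#'   kernel), `features`, and empty `labels`/`train_mask` slots filled in by
#'   the training harness.
#' @export
build_sample_graph <- function(features, k = 10L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (k <= 0L) stop("k must be positive")
  if (k >= n) stop("k must be smaller than the number of nodes (", n, ")")
  norms <- sqrt(rowSums(features^2))
  safe <- ifelse(norms > 0, norms, 1)
  unit <- features / safe
  cs <- tcrossprod(unit)
  diag(cs) <- -Inf  # never select self as a neighbour
  adj <- matrix(FALSE, n, n)
  for (v in seq_len(n)) {
    nb <- order(cs[v, ], decreasing = TRUE)[seq_len(k)]
    adj[v, nb] <- TRUE
  }
  adj <- adj | t(adj)         # union symmetrization
  a <- matrix(0, n, n)
  a[adj] <- 1
  diag(a) <- 1                # self-loops
  dinv <- 1 / sqrt(rowSums(a))
  a_hat <- a * tcrossprod(dinv)
  structure(list(n = n, a_hat = a_hat, features = features,
                 labels = NULL, train_mask = NULL),
            class = "sample_graph")
}

#' @export
print.sample_graph <- function(x, ...) {
  cat("sample graph: ", x$n, " nodes, ",
      (sum(x$a_hat > 0) - x$n) / 2, " undirected edges, ",
      ncol(x$features), " features per node\n", sep = "")
  invisible(x)
}

#' Node sampling distribution for layer-wise Monte Carlo
#'
#' Either uniform over nodes, or the importance proposal proportional to the
#' squared column norms of the propagation kernel, which concentrates samples
#' on well-connected nodes and reduces estimator variance.
#'
#' @param a_hat normalized adjacency.
#' @param mode `"importance"` (default) or `"uniform"`.
#' @return list with `q` (probability vector summing to 1) and `mode`.
#' @export
importance_distribution <- function(a_hat, mode = c("importance", "uniform")) {
  mode <- match.arg(mode)
  n <- ncol(a_hat)
  q <- if (mode == "uniform") rep(1 / n, n) else {
    w <- colSums(a_hat^2)
    w / sum(w)
  }
  list(q = q, mode = mode)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Exact graph convolution layer
#'
#' Deterministic propagation `sigma(A_hat %*% h %*% W)` over the full graph,
#' i.e. the integral transform between consecutive embedding layers
#' evaluated exactly on the finite node set.
#'
#' @param h node embeddings (n x d_in).
#' @param a_hat normalized adjacency.
#' @param w weight matrix (d_in x d_out).
#' @param act activation function (default identity).
#' @return n x d_out embedding matrix.
#' @export
full_layer <- function(h, a_hat, w, act = identity) {
  if (ncol(a_hat) != nrow(h)) stop("a_hat and h shapes do not conform")
  if (ncol(h) != nrow(w)) stop("h and w shapes do not conform")
  act(a_hat %*% h %*% w)
}

#' Monte-Carlo estimate of a graph convolution layer
#'
#' Draws `t` node indices i.i.d. from the proposal `q` and estimates the
#' propagation by importance weighting:
#' `sigma( (1/t) * sum_j A_hat(v, u_j) h(u_j) W / q(u_j) )`.
#' The pre-activation is an unbiased estimator of the exact layer's
#' pre-activation. With `exhaustive = TRUE` every node is used exactly once
#' under the uniform measure, which reproduces [full_layer()] exactly.
#'
#' @param h node embeddings over the full node set.
#' @param a_hat normalized adjacency.
#' @param w weight matrix.
#' @param q sampling distribution from [importance_distribution()].
#' @param t sample size (>= 1).
#' @param seed optional RNG seed for the draw.
#' @param act activation (default identity).
#' @param rows optional subset of output rows to evaluate (default all).
#' @param exhaustive use all nodes once instead of sampling.
#' @return length(rows) x d_out embedding matrix.
#' @export
sampled_layer <- function(h, a_hat, w, q, t, seed = NULL, act = identity,
                          rows = NULL, exhaustive = FALSE) {
  if (t < 1L) stop("sample size t must be at least 1")
  n <- ncol(a_hat)
  if (is.null(rows)) rows <- seq_len(nrow(a_hat))
  if (exhaustive) {
    idx <- seq_len(n)
    qv <- rep(1 / n, n)
    t <- n
  } else {
    if (!is.null(seed)) set.seed(seed)
    zero_mass <- q$q == 0 & colSums(abs(a_hat)) > 0
    if (any(zero_mass)) {
      warning("sampling distribution places zero mass on ",
              sum(zero_mass), " node(s) with nonzero kernel column; ",
              "the estimator is biased")
    }
    idx <- sample.int(n, t, replace = TRUE, prob = q$q)
    qv <- q$q[idx]
  }
  scale <- 1 / (t * qv)
  pre <- a_hat[rows, idx, drop = FALSE] %*%
    (h[idx, , drop = FALSE] * scale) %*% w
  act(pre)
}

#' Configuration for the sampled graph convolutional network
#'
#' @param hidden_dim width of the hidden embedding layer.
#' @param n_classes output classes (softmax).
#' @param sample_sizes Monte-Carlo sample sizes per layer, innermost first.
#' @param batch_size minibatch size over training nodes.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for initialization, batching and layer sampling.
#' @param sampling `"importance"` or `"uniform"` proposal.
#' @return a `gcn_config` list.
#' @export
gcn_config <- function(hidden_dim = 64L, n_classes = 2L,
                       sample_sizes = c(256L, 256L), batch_size = 256L,
                       epochs = 200L, learning_rate = 0.01, seed = 1L,
                       sampling = c("importance", "uniform")) {
  stopifnot(hidden_dim >= 1L, all(sample_sizes >= 1L), batch_size >= 1L,
            epochs >= 0L, learning_rate > 0)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 n_classes = as.integer(n_classes),
                 sample_sizes = as.integer(sample_sizes),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 seed = as.integer(seed),
                 sampling = match.arg(sampling)),
            class = "gcn_config")
}

glorot <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

init_gcn <- function(d_in, config) {
  set.seed(config$seed)
  list(w0 = glorot(d_in, config$hidden_dim),
       w1 = glorot(config$hidden_dim, config$n_classes))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

cross_entropy <- function(p, y) {
  # y: integer class labels in 0..K-1
  eps <- 1e-12
  -mean(log(pmax(p[cbind(seq_along(y), y + 1L)], eps)))
}

# One sampled forward pass over a batch of output nodes. Returns the pieces
# needed for backpropagation.
gcn_sampled_forward <- function(weights, graph, batch, q, t) {
  n <- graph$n
  s0 <- sample.int(n, t[1L], replace = TRUE, prob = q$q)
  s1 <- sample.int(n, t[2L], replace = TRUE, prob = q$q)
  a0 <- graph$a_hat[s1, s0, drop = FALSE] *
    rep(1 / (t[1L] * q$q[s0]), each = length(s1))
  a1 <- graph$a_hat[batch, s1, drop = FALSE] *
    rep(1 / (t[2L] * q$q[s1]), each = length(batch))
  ax0 <- a0 %*% graph$features[s0, , drop = FALSE]
  pre1 <- ax0 %*% weights$w0
  h1 <- relu(pre1)
  ah1 <- a1 %*% h1
  logits <- ah1 %*% weights$w1
  list(a1 = a1, ax0 = ax0, pre1 = pre1, h1 = h1, ah1 = ah1,
       p = softmax_rows(logits))
}

#' Sampled minibatch loss
#'
#' Cross-entropy of the softmax outputs over a batch of training nodes, with
#' the lower layers estimated by importance-sampled propagation. With
#' exhaustive uniform sampling this reduces to the exact full-propagation
#' loss.
#'
#' @param weights list with `w0`, `w1` (as built by the trainer).
#' @param graph a `sample_graph` carrying `labels`.
#' @param batch node indices (must be labelled).
#' @param t integer vector of per-layer sample sizes.
#' @param q proposal from [importance_distribution()].
#' @param seed optional seed for the layer draws.
#' @param exhaustive evaluate exactly instead of sampling.
#' @return scalar loss.
#' @export
batch_loss <- function(weights, graph, batch, t, q, seed = NULL,
                       exhaustive = FALSE) {
  if (length(batch) == 0L) stop("empty batch")
  y <- graph$labels[batch]
  if (anyNA(y)) stop("batch contains unlabelled nodes")
  if (exhaustive) {
    h1 <- full_layer(graph$features, graph$a_hat, weights$w0, act = relu)
    p <- softmax_rows(full_layer(h1, graph$a_hat, weights$w1)[batch, ,
                                                              drop = FALSE])
    return(cross_entropy(p, y))
  }
  if (!is.null(seed)) set.seed(seed)
  fw <- gcn_sampled_forward(weights, graph, batch, q, t)
  cross_entropy(fw$p, y)
}

#' Train the sampled graph convolutional network
#'
#' Two-layer GCN (hidden ReLU layer, softmax output) trained by Adam on the
#' importance-sampled minibatch loss. Only nodes flagged in `train_mask`
#' contribute to the loss; all nodes participate in propagation
#' (transductive protocol), so labels of non-training nodes never influence
#' the weights.
#'
#' @param graph a `sample_graph` with `labels` (integer 0-based classes; NA
#'   allowed off the training mask) and logical `train_mask`.
#' @param config a [gcn_config()].
#' @return a `gcn_model`: list with `weights`, `config`, `loss_trace`, `q`.
#' @export
train_fastgcn <- function(graph, config = gcn_config()) {
  stopifnot(inherits(graph, "sample_graph"))
  if (is.null(graph$labels) || is.null(graph$train_mask)) {
    stop("graph must carry labels and a train_mask before training")
  }
  train_nodes <- which(graph$train_mask)
  y_train <- graph$labels[train_nodes]
  if (anyNA(y_train)) stop("training nodes must all be labelled")
  if (length(unique(y_train)) < 2L) {
    stop("training labels contain a single class; cannot fit a classifier")
  }
  weights <- init_gcn(ncol(graph$features), config)
  q <- importance_distribution(graph$a_hat, config$sampling)
  t <- rep_len(config$sample_sizes, 2L)
  t <- pmin(t, graph$n)
  lr <- config$learning_rate
  adam <- list(m = lapply(weights, function(w) w * 0),
               v = lapply(weights, function(w) w * 0), step = 0L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(0)
  set.seed(config$seed + 1L)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(train_nodes)
    starts <- seq(1L, length(perm), by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      batch <- perm[s:min(s + config$batch_size - 1L, length(perm))]
      fw <- gcn_sampled_forward(weights, graph, batch, q, t)
      yb <- graph$labels[batch]
      epoch_loss <- epoch_loss + cross_entropy(fw$p, yb) * length(batch)
      # backprop through softmax cross-entropy, sampled propagation, ReLU
      dlogits <- fw$p
      dlogits[cbind(seq_along(yb), yb + 1L)] <-
        dlogits[cbind(seq_along(yb), yb + 1L)] - 1
      dlogits <- dlogits / length(yb)
      grad <- list(
        w1 = crossprod(fw$ah1, dlogits),
        w0 = crossprod(fw$ax0,
                       (t(fw$a1) %*% dlogits %*% t(weights$w1)) *
                         (fw$pre1 > 0))
      )
      adam$step <- adam$step + 1L
      for (nm in names(weights)) {
        adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * grad[[nm]]
        adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * grad[[nm]]^2
        mhat <- adam$m[[nm]] / (1 - b1^adam$step)
        vhat <- adam$v[[nm]] / (1 - b2^adam$step)
        weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_trace <- c(loss_trace, epoch_loss / length(train_nodes))
  }
  structure(list(weights = weights, config = config, q = q,
                 loss_trace = loss_trace),
            class = "gcn_model")
}

#' @export
print.gcn_model <- function(x, ...) {
  cat("sampled GCN model: ", nrow(x$weights$w0), " -> ",
      ncol(x$weights$w0), " -> ", ncol(x$weights$w1), " units; ",
      length(x$loss_trace), " epochs",
      if (length(x$loss_trace) > 0)
        paste0(", final loss ", signif(utils::tail(x$loss_trace, 1L), 4)),
      "\n", sep = "")
  invisible(x)
}

#' Extract high-level node features
#'
#' Runs the exact (non-sampled) forward pass and returns the penultimate
#' (hidden ReLU) embeddings for every node; these are the features handed to
#' the downstream classifier.
#'
#' @param model a trained `gcn_model`.
#' @param graph the `sample_graph` it was trained on.
#' @return n x hidden_dim embedding matrix.
#' @export
extract_features <- function(model, graph) {
  full_layer(graph$features, graph$a_hat, model$weights$w0, act = relu)
}

#' Class probabilities from the GCN head
#'
#' Exact forward pass through both layers with a softmax output; mainly a
#' diagnostic, since classification is delegated to the decision forest.
#'
#' @param model a trained `gcn_model`.
#' @param graph the `sample_graph`.
#' @return n x n_classes probability matrix.
#' @export
predict_gcn <- function(model, graph) {
  h1 <- extract_features(model, graph)
  softmax_rows(full_layer(h1, graph$a_hat, model$weights$w1))
}
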