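#' Weight range for a penalized attribute
#'
#' Attributes tested near the root of the latest tree are penalized hardest:
#' an attribute tested at level `lambda` draws its next weight uniformly from
#' `[0, e^-1]` when `lambda = 1` and from
#' `[e^{-1/(lambda-1)} + rho, e^{-1/lambda}]` when `lambda > 1`. The upper
#' bound increases toward 1 with depth, so deep attributes are barely
#' penalized.
#'
#' @param lambda level of the attribute's shallowest test (root = 1).
#' @param rho separation constant > 0 keeping consecutive ranges disjoint.
#' @return numeric length-2 vector `c(lower, upper)`.
#' @export
weight_range <- function(lambda, rho = 0.01) {
  if (lambda < 1) stop("lambda must be at least 1")
  if (rho <= 0) stop("rho must be positive")
  if (lambda == 1) return(c(0, exp(-1)))
  lo <- exp(-1 / (lambda - 1)) + rho
  hi <- exp(-1 / lambda)
  if (lo > hi) {
    stop("empty weight range at level ", lambda, ": rho = ", rho,
         " is too large")
  }
  c(lo, hi)
}

#' Merit of a candidate split
#'
#' A split's merit is its impurity gain damped by the current weight of the
#' attribute it tests; the tree greedily maximizes merit rather than raw
#' gain.
#'
#' @param gain nonnegative split quality (Gini gain).
#' @param weight attribute weight in (0, 1].
#' @return `gain * weight`.
#' @export
merit <- function(gain, weight) {
  if (any(gain < 0)) stop("gain must be nonnegative")
  if (any(weight <= 0 | weight > 1)) stop("weight must lie in (0, 1]")
  gain * weight
}

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best Gini-gain split of one numeric attribute. Returns gain, threshold
# (midpoint, the lowest among ties) or NULL when no valid split exists.
best_split_1d <- function(x, y_idx, n_classes, min_leaf) {
  n <- length(x)
  ord <- order(x, method = "radix")
  xs <- x[ord]
  ys <- y_idx[ord]
  i <- seq_len(n - 1L)
  valid <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & ((n - i) >= min_leaf)
  if (!any(valid)) return(NULL)
  nl <- i; nr <- n - i
  if (n_classes == 2L) {
    # fast path: weighted Gini of a binary split reduces to 2 p (n - p) / n
    pl <- cumsum(ys == 2L)[i]
    pt <- pl[1L] + sum(ys[-1L] == 2L)
    pr <- pt - pl
    parent <- 2 * pt * (n - pt) / n^2
    gain <- parent - 2 * (pl * (nl - pl) / nl + pr * (nr - pr) / nr) / n
  } else {
    cum <- matrix(0, n, n_classes)
    cum[cbind(seq_len(n), ys)] <- 1
    cum <- apply(cum, 2L, cumsum)
    tot <- cum[n, ]
    left <- cum[i, , drop = FALSE]
    right <- rep(tot, each = n - 1L)
    dim(right) <- c(n - 1L, n_classes)
    right <- right - left
    imp_l <- 1 - rowSums((left / nl)^2)
    imp_r <- 1 - rowSums((right / nr)^2)
    gain <- gini_impurity(tot) - (nl * imp_l + nr * imp_r) / n
  }
  gain[!valid] <- -Inf
  b <- which.max(gain)  # first max = lowest threshold among ties
  if (!is.finite(gain[b]) || gain[b] <= 0) return(NULL)
  list(gain = gain[b], threshold = (xs[b] + xs[b + 1L]) / 2)
}

#' Grow one penalized-attribute CART tree
#'
#' Binary CART on numeric attributes with the Gini gain of each candidate
#' split damped by the attribute's current weight (merit = gain x weight).
#' The split with the largest merit wins; ties break toward the lowest
#' attribute index, then the lowest threshold. Growth stops at pure nodes,
#' at `min_leaf`, at `max_depth`, or when no split has positive gain.
#'
#' @param x numeric feature matrix (one bootstrap sample).
#' @param y integer class labels (0-based).
#' @param weights per-attribute weights in (0,1].
#' @param n_classes number of classes (defaults to `max(y)+1`).
#' @param min_leaf minimum samples on each side of a split.
#' @param max_depth maximum depth (root = depth 1).
#' @return a `pa_tree`: list with parallel node vectors (`feature`,
#'   `threshold`, `left`, `right`, `is_leaf`), a `dist` matrix of leaf class
#'   distributions, and `tested_levels` (named: shallowest level per tested
#'   attribute).
#' @export
build_pa_tree <- function(x, y, weights = rep(1, ncol(x)),
                          n_classes = max(y) + 1L, min_leaf = 2L,
                          max_depth = Inf) {
  if (nrow(x) == 0L) stop("cannot grow a tree from an empty sample")
  if (length(weights) != ncol(x)) stop("one weight per attribute required")
  y_idx <- as.integer(y) + 1L
  nodes <- new.env(parent = emptyenv())
  nodes$feature <- integer(0); nodes$threshold <- numeric(0)
  nodes$left <- integer(0); nodes$right <- integer(0)
  nodes$is_leaf <- logical(0); nodes$dist <- NULL
  nodes$tested <- integer(0)  # named by attribute index: min level

  new_node <- function() {
    id <- length(nodes$feature) + 1L
    nodes$feature[id] <- NA_integer_; nodes$threshold[id] <- NA_real_
    nodes$left[id] <- NA_integer_; nodes$right[id] <- NA_integer_
    nodes$is_leaf[id] <- TRUE
    id
  }
  leaf_dist <- function(rows) {
    tabulate(y_idx[rows], nbins = n_classes) / length(rows)
  }
  grow <- function(rows, depth) {
    id <- new_node()
    counts <- tabulate(y_idx[rows], nbins = n_classes)
    pure <- sum(counts > 0L) <= 1L
    if (pure || length(rows) < 2L * min_leaf || depth > max_depth) {
      nodes$dist <- rbind(nodes$dist, leaf_dist(rows))
      rownames(nodes$dist)[nrow(nodes$dist)] <- id
      return(id)
    }
    best <- NULL
    for (f in seq_len(ncol(x))) {
      sp <- best_split_1d(x[rows, f], y_idx[rows], n_classes, min_leaf)
      if (is.null(sp)) next
      m <- sp$gain * weights[f]
      if (is.null(best) || m > best$merit) {
        best <- list(merit = m, feature = f, threshold = sp$threshold)
      }
    }
    if (is.null(best)) {
      nodes$dist <- rbind(nodes$dist, leaf_dist(rows))
      rownames(nodes$dist)[nrow(nodes$dist)] <- id
      return(id)
    }
    f <- best$feature
    key <- as.character(f)
    prev <- nodes$tested[key]
    if (is.na(prev) || depth < prev) nodes$tested[key] <- depth
    go_left <- x[rows, f] <= best$threshold
    nodes$feature[id] <- f
    nodes$threshold[id] <- best$threshold
    nodes$is_leaf[id] <- FALSE
    nodes$left[id] <- grow(rows[go_left], depth + 1L)
    nodes$right[id] <- grow(rows[!go_left], depth + 1L)
    id
  }
  grow(seq_len(nrow(x)), 1L)
  tested <- as.integer(nodes$tested)
  names(tested) <- names(nodes$tested)
  structure(list(feature = nodes$feature, threshold = nodes$threshold,
                 left = nodes$left, right = nodes$right,
                 is_leaf = nodes$is_leaf, dist = nodes$dist,
                 n_classes = n_classes, tested_levels = tested),
            class = "pa_tree")
}

#' Route samples through one tree
#'
#' @param tree a `pa_tree`.
#' @param x feature matrix.
#' @return n x n_classes matrix of leaf class distributions.
#' @export
predict_tree <- function(tree, x) {
  n <- nrow(x)
  node <- rep(1L, n)
  repeat {
    inner <- !tree$is_leaf[node]
    if (!any(inner)) break
    idx <- which(inner)
    f <- tree$feature[node[idx]]
    thr <- tree$threshold[node[idx]]
    goes_left <- x[cbind(idx, f)] <= thr
    node[idx] <- ifelse(goes_left, tree$left[node[idx]],
                        tree$right[node[idx]])
  }
  tree$dist[match(as.character(node), rownames(tree$dist)), , drop = FALSE]
}

#' Refresh attribute weights after a tree is grown
#'
#' Attributes tested in the latest tree draw a fresh weight uniformly from
#' the [weight_range()] of their shallowest level, and their increment is
#' set so the weight would drift back to 1 linearly over `n_trees` trees.
#' Attributes absent from the latest tree recover: weight increases by their
#' increment, capped at 1.
#'
#' Because consecutive range bounds differ by roughly `1/lambda^2`, the
#' range is empty beyond a `rho`-dependent depth; levels are capped at the
#' deepest level with a nonempty range (attributes tested that deep receive
#' the mildest penalty, consistent with the range schedule's intent).
#'
#' @param state list with numeric vectors `weight` and `increment`.
#' @param tree the latest `pa_tree`.
#' @param rho separation constant for [weight_range()].
#' @param n_trees forest size (sets the recovery rate).
#' @return updated state.
#' @export
update_weights <- function(state, tree, rho = 0.01, n_trees = 100L) {
  tested <- tree$tested_levels
  p <- length(state$weight)
  in_tree <- rep(FALSE, p)
  if (length(tested) > 0L) in_tree[as.integer(names(tested))] <- TRUE
  # recovery first, for attributes resting outside the latest tree
  state$weight[!in_tree] <- pmin(1, state$weight[!in_tree] +
                                   state$increment[!in_tree])
  lam_max <- max_penalty_level(rho)
  for (k in seq_along(tested)) {
    f <- as.integer(names(tested)[k])
    wr <- weight_range(min(tested[k], lam_max), rho)
    w <- stats::runif(1L, wr[1L], wr[2L])
    state$weight[f] <- w
    state$increment[f] <- (1 - w) / n_trees
  }
  state
}

# deepest level whose weight range is still nonempty for this rho
max_penalty_level <- function(rho) {
  lam <- 1L
  while (exp(-1 / lam) + rho <= exp(-1 / (lam + 1L))) lam <- lam + 1L
  lam
}

#' Train a forest by penalizing attributes
#'
#' Grows `n_trees` CART trees on bootstrap samples of the training data.
#' Every attribute starts with weight 1; after each tree, attributes it
#' tested are penalized by a level-dependent random weight (shallower test,
#' harsher penalty) while the rest drift back toward 1. The penalty steers
#' successive trees toward different attributes, trading a little individual
#' accuracy for forest diversity.
#'
#' @param x numeric feature matrix.
#' @param y integer labels (0-based classes).
#' @param n_trees number of trees.
#' @param seed RNG seed (bootstraps + weight draws).
#' @param rho separation constant of the weight ranges.
#' @param min_leaf,max_depth tree growth controls.
#' @param penalize set FALSE to pin all weights at 1 and skip updates, which
#'   reduces the algorithm to plain bagged CART.
#' @return a `pa_forest`: list of trees plus training metadata.
#' @export
train_forest <- function(x, y, n_trees = 100L, seed = 1L, rho = 0.01,
                         min_leaf = 2L, max_depth = Inf, penalize = TRUE) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class")
  }
  n_classes <- max(y) + 1L
  set.seed(seed)
  state <- list(weight = rep(1, ncol(x)), increment = rep(0, ncol(x)))
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    boot <- sample.int(nrow(x), nrow(x), replace = TRUE)
    trees[[i]] <- build_pa_tree(x[boot, , drop = FALSE], y[boot],
                                weights = state$weight,
                                n_classes = n_classes,
                                min_leaf = min_leaf, max_depth = max_depth)
    if (penalize) {
      state <- update_weights(state, trees[[i]], rho = rho,
                              n_trees = n_trees)
    }
  }
  structure(list(trees = trees, n_trees = n_trees, n_classes = n_classes,
                 n_features = ncol(x), seed = seed, rho = rho,
                 penalize = penalize),
            class = "pa_forest")
}

#' @export
print.pa_forest <- function(x, ...) {
  cat("penalized-attribute forest: ", x$n_trees, " trees, ",
      x$n_features, " attributes, ", x$n_classes, " classes",
      if (!x$penalize) " (penalties off: plain bagging)", "\n", sep = "")
  invisible(x)
}

#' Forest class probabilities
#'
#' Mean of the per-tree leaf class distributions.
#'
#' @param forest a `pa_forest`.
#' @param x feature matrix.
#' @return n x n_classes probability matrix (rows sum to 1).
#' @export
predict_forest <- function(forest, x) {
  if (!inherits(forest, "pa_forest")) stop("not a fitted pa_forest")
  x <- as.matrix(x)
  if (ncol(x) != forest$n_features) {
    stop("expected ", forest$n_features, " features, got ", ncol(x))
  }
  acc <- matrix(0, nrow(x), forest$n_classes)
  for (tree in forest$trees) acc <- acc + predict_tree(tree, x)
  acc / forest$n_trees
}

#' Serialize a forest to structured text
#'
#' Writes the complete forest (splits, thresholds, leaf distributions,
#' tested levels) as JSON so fitted models can be inspected and reloaded.
#'
#' @param forest a `pa_forest`.
#' @param path output path.
#' @export
write_forest <- function(forest, path) {
  trees <- lapply(forest$trees, function(tr) {
    list(feature = tr$feature, threshold = tr$threshold, left = tr$left,
         right = tr$right, is_leaf = tr$is_leaf,
         leaf_id = as.integer(rownames(tr$dist)),
         dist = unname(as.matrix(tr$dist)),
         tested_levels = as.list(tr$tested_levels))
  })
  obj <- list(n_trees = forest$n_trees, n_classes = forest$n_classes,
              n_features = forest$n_features, seed = forest$seed,
              rho = forest$rho, penalize = forest$penalize, trees = trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Reload a serialized forest
#'
#' @param path path written by [write_forest()].
#' @return a `pa_forest`.
#' @export
read_forest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) vapply(x, function(v) if (is.null(v)) NA_real_ else
    as.numeric(v), 0)
  trees <- lapply(obj$trees, function(tr) {
    dist <- do.call(rbind, lapply(tr$dist, num))
    rownames(dist) <- as.character(num(tr$leaf_id))
    lvls <- num(tr$tested_levels)
    structure(list(feature = as.integer(num(tr$feature)),
                   threshold = num(tr$threshold),
                   left = as.integer(num(tr$left)),
                   right = as.integer(num(tr$right)),
                   is_leaf = vapply(tr$is_leaf, isTRUE, TRUE),
                   dist = dist,
                   n_classes = as.integer(obj$n_classes),
                   tested_levels = stats::setNames(as.integer(lvls),
                                                   names(tr$tested_levels))),
              class = "pa_tree")
  })
  structure(list(trees = trees, n_trees = obj$n_trees,
                 n_classes = obj$n_classes, n_features = obj$n_features,
                 seed = obj$seed, rho = obj$rho, penalize = obj$penalize),
            class = "pa_forest")
}
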