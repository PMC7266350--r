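# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most naive possible algorithms (explicit set
# enumeration, pairwise loops, recursive unvectorized CART) so they share no
# code path with the package.

# --- ontology semantic similarity -----------------------------------------

# edges: data.frame(child, parent). Ancestor closure by repeated expansion.
oracle_closure <- function(edges, d) {
  nodes <- d
  repeat {
    up <- unique(edges$parent[edges$child %in% nodes])
    new <- setdiff(up, nodes)
    if (length(new) == 0L) return(nodes)
    nodes <- c(nodes, new)
  }
}

oracle_contribution <- function(edges, d, mu) {
  nodes <- oracle_closure(edges, d)
  contrib <- function(s) {
    if (s == d) return(1)
    kids <- intersect(edges$child[edges$parent == s], nodes)
    mu * max(vapply(kids, contrib, 0))
  }
  stats::setNames(vapply(nodes, contrib, 0), nodes)
}

oracle_sv1 <- function(edges, di, dj, mu) {
  ci <- oracle_contribution(edges, di, mu)
  cj <- oracle_contribution(edges, dj, mu)
  shared <- intersect(names(ci), names(cj))
  if (length(shared) == 0L) return(0)
  sum(ci[shared] + cj[shared]) / (sum(ci) + sum(cj))
}

oracle_ic <- function(edges, all_diseases, s) {
  in_dag <- vapply(all_diseases, function(d) s %in% oracle_closure(edges, d),
                   TRUE)
  -log(sum(in_dag) / length(all_diseases))
}

oracle_sv2 <- function(edges, all_diseases, di, dj, mu) {
  ci <- oracle_contribution(edges, di, mu)
  cj <- oracle_contribution(edges, dj, mu)
  shared <- intersect(names(ci), names(cj))
  if (length(shared) == 0L) return(0)
  ic <- vapply(shared, function(s) oracle_ic(edges, all_diseases, s), 0)
  sum(2 * ic) / (sum(ci) + sum(cj))
}

# random small acyclic hierarchy: node i may pick parents among 1..(i-1)
random_hierarchy_edges <- function(n_nodes, p_edge = 0.5) {
  child <- character(0); parent <- character(0)
  ids <- paste0("d", seq_len(n_nodes))
  for (i in seq_len(n_nodes)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (stats::runif(1) < p_edge) {
        child <- c(child, ids[i]); parent <- c(parent, ids[j])
      }
    }
  }
  list(edges = data.frame(child = child, parent = parent,
                          stringsAsFactors = FALSE),
       ids = ids)
}

# --- GIP kernel ------------------------------------------------------------

oracle_gip <- function(profiles) {
  n <- nrow(profiles)
  theta <- 1 / mean(apply(profiles, 1L, function(v) sum(v^2)))
  k <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      k[i, j] <- exp(-theta * sum((profiles[i, ] - profiles[j, ])^2))
    }
  }
  k
}

# --- ROC / AUC -------------------------------------------------------------

oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# --- plain CART / bagging --------------------------------------------------

# Naive recursive CART with Gini gain, midpoint thresholds, ties broken by
# lowest attribute then lowest threshold. Emits nodes in the same pre-order
# as the package (root, left subtree, right subtree) so trees can be
# compared field by field.
oracle_cart <- function(x, y, min_leaf = 2L, n_classes = max(y) + 1L) {
  nodes <- list()
  grow <- function(rows, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list()  # reserve slot for pre-order numbering
    counts <- tabulate(y[rows] + 1L, nbins = n_classes)
    make_leaf <- function() {
      nodes[[id]] <<- list(leaf = TRUE, dist = counts / length(rows))
      id
    }
    if (sum(counts > 0L) <= 1L || length(rows) < 2L * min_leaf) {
      return(make_leaf())
    }
    best <- NULL
    parent_imp <- 1 - sum((counts / length(rows))^2)
    for (f in seq_len(ncol(x))) {
      xv <- x[rows, f]
      sx <- sort(unique(xv))
      if (length(sx) < 2L) next
      for (thr in (sx[-1] + sx[-length(sx)]) / 2) {
        l <- rows[xv <= thr]; r <- rows[xv > thr]
        if (length(l) < min_leaf || length(r) < min_leaf) next
        if (length(l) == 0L || length(r) == 0L) next
        imp <- function(rr) {
          cc <- tabulate(y[rr] + 1L, nbins = n_classes)
          1 - sum((cc / length(rr))^2)
        }
        gain <- parent_imp -
          (length(l) * imp(l) + length(r) * imp(r)) / length(rows)
        if (gain > 0 && (is.null(best) || gain > best$gain)) {
          best <- list(gain = gain, f = f, thr = thr)
        }
      }
    }
    if (is.null(best)) return(make_leaf())
    l <- rows[x[rows, best$f] <= best$thr]
    r <- rows[x[rows, best$f] > best$thr]
    left_id <- grow(l, depth + 1L)
    right_id <- grow(r, depth + 1L)
    nodes[[id]] <<- list(leaf = FALSE, f = best$f, thr = best$thr,
                         left = left_id, right = right_id)
    id
  }
  grow(seq_len(nrow(x)), 1L)
  nodes
}

# compare an oracle tree with a pa_tree node by node
expect_same_tree <- function(tree, oracle) {
  expect_equal(length(tree$feature), length(oracle))
  for (id in seq_along(oracle)) {
    o <- oracle[[id]]
    if (isTRUE(o$leaf)) {
      expect_true(tree$is_leaf[id])
      expect_equal(
        as.numeric(tree$dist[match(as.character(id), rownames(tree$dist)), ]),
        as.numeric(o$dist))
    } else {
      expect_false(tree$is_leaf[id])
      expect_equal(tree$feature[id], o$f)
      expect_equal(tree$threshold[id], o$thr)
      expect_equal(tree$left[id], o$left)
      expect_equal(tree$right[id], o$right)
    }
  }
}

# two separable Gaussian blobs, handy for classifier sanity checks
make_blobs <- function(n_per = 40L, d = 4L, sep = 2, seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per * d, sep), n_per),
             matrix(stats::rnorm(n_per * d, -sep), n_per))
  list(x = x, y = rep(c(1L, 0L), each = n_per))
}
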