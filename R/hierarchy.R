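#' Read a disease hierarchy file
#'
#' Parses a MeSH-style hierarchy given as tab-separated (child_id, parent_id)
#' rows. A disease that is a root of the classification appears either only
#' as a parent, or as a row with an empty parent field. The edge set must be
#' acyclic.
#'
#' @param path path to the hierarchy TSV (optional `child_id<TAB>parent_id`
#'   header).
#' @return a `disease_hierarchy` object: list with `children` (character
#'   vector), `parents` (character vector, aligned), and `diseases` (all ids).
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("hierarchy file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("hierarchy file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  child <- trimws(vapply(fields, function(f) if (length(f) >= 1L) f[[1L]] else "", ""))
  parent <- trimws(vapply(fields, function(f) if (length(f) >= 2L) f[[2L]] else "", ""))
  if (identical(tolower(c(child[1L], parent[1L])), c("child_id", "parent_id"))) {
    child <- child[-1L]; parent <- parent[-1L]
  }
  if (any(!nzchar(child))) {
    stop("hierarchy row with empty child id at line ",
         which(!nzchar(child))[1L])
  }
  keep <- nzchar(parent)
  disease_hierarchy(child[keep], parent[keep],
                    extra = unique(c(child, parent[keep])))
}

#' Construct a disease hierarchy from edge vectors
#'
#' @param children,parents aligned character vectors of child -> parent edges.
#' @param extra additional disease ids that carry no edges (isolated roots).
#' @return a `disease_hierarchy`.
#' @export
disease_hierarchy <- function(children, parents, extra = character(0)) {
  stopifnot(length(children) == length(parents))
  if (length(children) > 0L) {
    dup <- duplicated(paste0(children, "\r", parents))
    children <- children[!dup]; parents <- parents[!dup]
  }
  diseases <- unique(c(children, parents, extra))
  h <- structure(list(children = children, parents = parents,
                      diseases = diseases),
                 class = "disease_hierarchy")
  assert_acyclic(h)
  h
}

#' @export
print.disease_hierarchy <- function(x, ...) {
  cat("disease hierarchy: ", length(x$diseases), " diseases, ",
      length(x$children), " child->parent edges\n", sep = "")
  invisible(x)
}

assert_acyclic <- function(h) {
  # peel nodes with no outgoing (child -> parent) edges; anything left after
  # peeling converges lies on a cycle
  nodeset <- h$diseases
  alive <- rep(TRUE, length(h$children))
  repeat {
    sinks <- setdiff(nodeset, unique(h$children[alive]))
    if (length(sinks) == 0L) break
    alive <- alive & !(h$parents %in% sinks)
    nodeset <- setdiff(nodeset, sinks)
    if (length(nodeset) == 0L) break
  }
  if (length(nodeset) > 0L) {
    stop("hierarchy contains a cycle involving: ",
         paste(utils::head(nodeset, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Ancestor closure of a disease
#'
#' Builds the per-disease DAG: the transitive closure of child -> parent
#' edges starting from `d`, including `d` itself, together with the
#' hierarchy edges restricted to that node set. A disease appearing at
#' several positions in the classification contributes the union of its
#' ancestor closures.
#'
#' @param h a `disease_hierarchy`.
#' @param d disease id.
#' @return a `disease_dag`: list with `root`, `nodes` (ancestor set N_d) and
#'   `edges` (data.frame child/parent restricted to `nodes`).
#' @export
build_disease_dag <- function(h, d) {
  if (!(d %in% h$diseases)) stop("disease not in hierarchy: ", d)
  nodes <- d
  frontier <- d
  while (length(frontier) > 0L) {
    up <- unique(h$parents[h$children %in% frontier])
    frontier <- setdiff(up, nodes)
    nodes <- c(nodes, frontier)
  }
  keep <- h$children %in% nodes & h$parents %in% nodes
  structure(list(root = d, nodes = nodes,
                 edges = data.frame(child = h$children[keep],
                                    parent = h$parents[keep],
                                    stringsAsFactors = FALSE)),
            class = "disease_dag")
}

#' Semantic similarity configuration
#'
#' @param mu semantic contribution decay factor in (0,1); each step up the
#'   hierarchy multiplies a disease's contribution by `mu`. Default 0.5.
#' @param log_base logarithm base for the information-content contribution;
#'   default the natural log.
#' @param clip_sv2 clip the information-content similarity at 1 (default
#'   FALSE: the model is reported as defined, and rare shared ancestors can
#'   push it above 1).
#' @param ic_n_diseases optional override for the disease count used in the
#'   information-content denominator; defaults to the number of diseases in
#'   the hierarchy.
#' @return a `semantic_config` list.
#' @export
semantic_config <- function(mu = 0.5, log_base = exp(1), clip_sv2 = FALSE,
                            ic_n_diseases = NULL) {
  if (!(mu > 0 && mu < 1)) stop("mu must lie in (0,1)")
  structure(list(mu = mu, log_base = log_base, clip_sv2 = clip_sv2,
                 ic_n_diseases = ic_n_diseases),
            class = "semantic_config")
}

#' Per-ancestor semantic contributions
#'
#' The root contributes 1; every other node of the per-disease DAG
#' contributes `mu` times the largest contribution among its children inside
#' the DAG, so contributions decay geometrically with distance from the root.
#'
#' @param dag a `disease_dag`.
#' @param cfg a [semantic_config()].
#' @return named numeric vector of contributions over `dag$nodes`.
#' @export
contribution <- function(dag, cfg = semantic_config()) {
  vals <- stats::setNames(rep(NA_real_, length(dag$nodes)), dag$nodes)
  vals[dag$root] <- 1
  # contributions depend on children already computed; iterate until stable
  # (closure depth is bounded by the node count)
  for (pass in seq_along(dag$nodes)) {
    pending <- names(vals)[is.na(vals)]
    if (length(pending) == 0L) break
    for (s in pending) {
      ch <- dag$edges$child[dag$edges$parent == s]
      ch_vals <- vals[ch]
      if (length(ch_vals) > 0L && !anyNA(ch_vals)) {
        vals[s] <- cfg$mu * max(ch_vals)
      }
    }
  }
  if (anyNA(vals)) {
    stop("unreachable nodes in disease DAG for ", dag$root, ": ",
         paste(names(vals)[is.na(vals)], collapse = ", "))
  }
  vals
}

#' Semantic value of a disease
#'
#' Sum of the contributions of all nodes in the disease's ancestor DAG.
#'
#' @param table named contribution vector from [contribution()].
#' @return a single number >= 1.
#' @export
semantic_value <- function(table) {
  if (length(table) == 0L) stop("empty contribution table")
  sum(table)
}

#' First (hierarchy-decay) disease semantic similarity
#'
#' Similarity of two diseases as the contribution mass of their shared
#' ancestors, relative to their total semantic values:
#' `sum over shared s of (D_i(s) + D_j(s)) / (DV(i) + DV(j))`.
#'
#' @param d_i,d_j disease ids present in the hierarchy.
#' @param h a `disease_hierarchy`.
#' @param cfg a [semantic_config()].
#' @return similarity in `[0, 1]`; 1 iff the diseases share their full DAGs.
#' @export
sv1 <- function(d_i, d_j, h, cfg = semantic_config()) {
  di <- build_disease_dag(h, d_i); dj <- build_disease_dag(h, d_j)
  ci <- contribution(di, cfg); cj <- contribution(dj, cfg)
  shared <- intersect(di$nodes, dj$nodes)
  if (length(shared) == 0L) return(0)
  sum(ci[shared] + cj[shared]) / (semantic_value(ci) + semantic_value(cj))
}

#' Information-content contribution of a disease term
#'
#' `-log` of the fraction of diseases whose ancestor DAG contains the term:
#' terms shared by few diseases are more informative.
#'
#' @param s disease id.
#' @param h a `disease_hierarchy`.
#' @param cfg a [semantic_config()].
#' @return nonnegative number (0 for a term present in every DAG).
#' @export
ic_contribution <- function(s, h, cfg = semantic_config()) {
  ic_contribution_table(h, cfg)[s]
}

# IC contributions for every term in the hierarchy at once.
# num_dags(s) = #{d : s in N_d}; computed by propagating reachability down
# the hierarchy once rather than closing every disease separately.
ic_contribution_table <- function(h, cfg = semantic_config()) {
  n_dis <- if (is.null(cfg$ic_n_diseases)) length(h$diseases) else cfg$ic_n_diseases
  counts <- vapply(h$diseases, function(s) {
    # descendants of s (diseases whose closure contains s), including s
    down <- s
    frontier <- s
    while (length(frontier) > 0L) {
      kids <- unique(h$children[h$parents %in% frontier])
      frontier <- setdiff(kids, down)
      down <- c(down, frontier)
    }
    length(down)
  }, 0L)
  vals <- -log(counts / n_dis) / log(cfg$log_base)
  stats::setNames(pmax(vals, 0), h$diseases)
}

#' Second (information-content) disease semantic similarity
#'
#' Shares the structure of [sv1()] but scores each shared ancestor by its
#' information content instead of its decayed contribution; the denominator
#' keeps the semantic values of the decay model. The result is nonnegative
#' but not bounded by 1 unless `cfg$clip_sv2` is set.
#'
#' @inheritParams sv1
#' @return similarity >= 0.
#' @export
sv2 <- function(d_i, d_j, h, cfg = semantic_config()) {
  di <- build_disease_dag(h, d_i); dj <- build_disease_dag(h, d_j)
  shared <- intersect(di$nodes, dj$nodes)
  if (length(shared) == 0L) return(0)
  ic <- ic_contribution_table(h, cfg)
  ci <- contribution(di, cfg); cj <- contribution(dj, cfg)
  val <- sum(ic[shared] + ic[shared]) /
    (semantic_value(ci) + semantic_value(cj))
  if (isTRUE(cfg$clip_sv2)) val <- min(val, 1)
  val
}

#' Semantic similarity matrices over an ordered disease list
#'
#' Computes both semantic similarity models for every pair of diseases that
#' the hierarchy covers, plus a coverage mask. Diseases absent from the
#' hierarchy get `mask = FALSE` everywhere (their similarity later falls
#' through to the interaction-profile kernel).
#'
#' @param diseases ordered character vector of disease ids (e.g. the columns
#'   of an association matrix).
#' @param h a `disease_hierarchy`.
#' @param cfg a [semantic_config()].
#' @return list with symmetric matrices `sv1`, `sv2` (NA where uncovered)
#'   and logical matrix `mask`.
#' @export
semantic_similarity_matrices <- function(diseases, h,
                                         cfg = semantic_config()) {
  n <- length(diseases)
  covered <- diseases %in% h$diseases
  m1 <- matrix(NA_real_, n, n, dimnames = list(diseases, diseases))
  m2 <- m1
  mask <- outer(covered, covered, `&`)
  dimnames(mask) <- dimnames(m1)
  if (any(covered)) {
    idx <- which(covered)
    dags <- lapply(diseases[idx], build_disease_dag, h = h)
    tabs <- lapply(dags, contribution, cfg = cfg)
    dvs <- vapply(tabs, semantic_value, 0)
    ic <- ic_contribution_table(h, cfg)
    for (a in seq_along(idx)) {
      for (b in seq_len(a)) {
        shared <- intersect(dags[[a]]$nodes, dags[[b]]$nodes)
        denom <- dvs[a] + dvs[b]
        if (length(shared) == 0L) {
          v1 <- 0; v2 <- 0
        } else {
          v1 <- sum(tabs[[a]][shared] + tabs[[b]][shared]) / denom
          v2 <- sum(2 * ic[shared]) / denom
          if (isTRUE(cfg$clip_sv2)) v2 <- min(v2, 1)
        }
        m1[idx[a], idx[b]] <- m1[idx[b], idx[a]] <- v1
        m2[idx[a], idx[b]] <- m2[idx[b], idx[a]] <- v2
      }
    }
  }
  list(sv1 = m1, sv2 = m2, mask = mask)
}
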