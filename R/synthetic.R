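#' Specification of a synthetic benchmark
#'
#' Describes a planted-block association matrix and an accompanying disease
#' hierarchy: circRNAs and diseases are partitioned into functional blocks,
#' within-block pairs associate with probability `within_density` and all
#' other pairs with `background_density` — a direct encoding of the guilt-
#' by-association hypothesis that functionally similar circRNAs share
#' disease spectra. Defaults give a desk-scale problem a full
#' cross-validation run completes on in minutes.
#'
#' @param n_circ,n_dis entity counts.
#' @param n_blocks planted blocks (`<= min(n_circ, n_dis)`).
#' @param within_density,background_density association probabilities.
#' @param hierarchy_branching,hierarchy_depth shape of the scaffold
#'   hierarchy tree.
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_circ = 120L, n_dis = 30L, n_blocks = 4L,
                           within_density = 0.35,
                           background_density = 0.02,
                           hierarchy_branching = 3L, hierarchy_depth = 3L,
                           seed = 1L) {
  stopifnot(within_density >= 0, within_density <= 1,
            background_density >= 0, background_density <= 1,
            n_blocks <= min(n_circ, n_dis), hierarchy_depth >= 1L)
  structure(list(n_circ = as.integer(n_circ), n_dis = as.integer(n_dis),
                 n_blocks = as.integer(n_blocks),
                 within_density = within_density,
                 background_density = background_density,
                 hierarchy_branching = as.integer(hierarchy_branching),
                 hierarchy_depth = as.integer(hierarchy_depth),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

block_of <- function(n, n_blocks) {
  # contiguous near-equal partition: entity i -> block in 1..n_blocks
  rep(seq_len(n_blocks), length.out = n_blocks)[
    ceiling(seq_len(n) / (n / n_blocks))]
}

#' Generate a scaffold disease hierarchy
#'
#' Builds a balanced tree of category ids with the spec's branching and
#' depth (depth 1 means roots only, no edges). When `diseases` and
#' `dis_block` are supplied, each observed disease is attached as a child of
#' the leaf category assigned to its block, so block-mates share a parent
#' and are semantically close.
#'
#' @param spec a [synthetic_spec()].
#' @param diseases optional character vector of observed disease ids.
#' @param dis_block optional block id per disease.
#' @param path optional output path (hierarchy TSV dialect).
#' @return a `disease_hierarchy` (invisibly also written to `path`).
#' @export
gen_hierarchy <- function(spec, diseases = NULL, dis_block = NULL,
                          path = NULL) {
  b <- spec$hierarchy_branching
  children <- character(0); parents <- character(0)
  level_ids <- list("H1")
  if (spec$hierarchy_depth > 1L) {
    for (lvl in 2:spec$hierarchy_depth) {
      prev <- level_ids[[lvl - 1L]]
      ids <- paste0(rep(prev, each = b), ".", seq_len(b))
      children <- c(children, ids)
      parents <- c(parents, rep(prev, each = b))
      level_ids[[lvl]] <- ids
    }
  }
  isolated <- if (spec$hierarchy_depth == 1L) "H1" else character(0)
  if (!is.null(diseases)) {
    stopifnot(length(diseases) == length(dis_block))
    leaves <- level_ids[[length(level_ids)]]
    anchor <- leaves[(dis_block - 1L) %% length(leaves) + 1L]
    if (spec$hierarchy_depth == 1L) {
      # no internal structure: all observed diseases hang off the sole root
      children <- c(children, diseases)
      parents <- c(parents, rep("H1", length(diseases)))
      isolated <- character(0)
    } else {
      children <- c(children, diseases)
      parents <- c(parents, anchor)
    }
  }
  h <- disease_hierarchy(children, parents, extra = isolated)
  if (!is.null(path)) write_hierarchy(h, path)
  h
}

#' Write a hierarchy in the TSV dialect
#'
#' Emits `child_id<TAB>parent_id` rows (header included); roots that carry
#' no edge are written with an empty parent field.
#'
#' @param h a `disease_hierarchy`.
#' @param path output path.
#' @export
write_hierarchy <- function(h, path) {
  edged <- unique(c(h$children, h$parents))
  lone <- setdiff(h$diseases, edged)
  out <- c("child_id\tparent_id",
           paste(h$children, h$parents, sep = "\t"),
           if (length(lone) > 0L) paste0(lone, "\t"))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Generate a planted-block association matrix
#'
#' @param spec a [synthetic_spec()].
#' @param path optional output path (edge-list TSV dialect).
#' @return list with `am` (an `assoc_matrix`), `circ_block`, `dis_block`
#'   (ground-truth block labels).
#' @export
gen_associations <- function(spec, path = NULL) {
  set.seed(spec$seed)
  cb <- block_of(spec$n_circ, spec$n_blocks)
  db <- block_of(spec$n_dis, spec$n_blocks)
  p <- ifelse(outer(cb, db, `==`), spec$within_density,
              spec$background_density)
  m <- matrix(stats::rbinom(length(p), 1L, p), spec$n_circ, spec$n_dis)
  dimnames(m) <- list(sprintf("circ_%03d", seq_len(spec$n_circ)),
                      sprintf("disease_%03d", seq_len(spec$n_dis)))
  am <- structure(m, class = c("assoc_matrix", "matrix", "array"))
  if (!is.null(path)) write_associations(am, path)
  list(am = am, circ_block = cb, dis_block = db)
}

#' Generate a complete synthetic benchmark
#'
#' Associations plus a hierarchy covering the observed diseases, plus the
#' ground truth, optionally written to disk in the formats the pipeline
#' consumes.
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; writes `associations.tsv`,
#'   `hierarchy.tsv` and `ground_truth.json` there.
#' @return list with `am`, `hierarchy`, `circ_block`, `dis_block`, `spec`.
#' @export
gen_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  assoc <- gen_associations(spec)
  h <- gen_hierarchy(spec, diseases = colnames(assoc$am),
                     dis_block = assoc$dis_block)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_associations(assoc$am, file.path(dir, "associations.tsv"))
    write_hierarchy(h, file.path(dir, "hierarchy.tsv"))
    jsonlite::write_json(list(spec = unclass(spec),
                              circ_block = assoc$circ_block,
                              dis_block = assoc$dis_block),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(am = assoc$am, hierarchy = h, circ_block = assoc$circ_block,
       dis_block = assoc$dis_block, spec = spec)
}

#' Documentation micro-fixture with hand-checked values
#'
#' A two-circRNA / two-disease identity association matrix and a
#' three-disease chain hierarchy (C is a child of B, B a child of A), with
#' every intermediate quantity of the pipeline worked out by hand (brute
#' force over the tiny closure sets): kernel widths, GIP kernels, semantic
#' contributions, semantic values, both semantic similarity models, the
#' fused disease similarity and the descriptor for the (c1, A) pair. Used
#' throughout the documentation and tests as a known-answer reference.
#'
#' @return list with `am`, `hierarchy`, and the expected values `theta_c`,
#'   `theta_d`, `gc`, `gd`, `contrib_C`, `dv`, `sv1_AB`, `sv2_AB`, `sv1`,
#'   `sv2`, `dsim`, `fv_c1_A`.
#' @export
worked_example <- function() {
  am <- assoc_matrix_from_pairs(c("c1", "c2"), c("A", "B"))
  h <- disease_hierarchy(children = c("B", "C"), parents = c("A", "B"))
  e2 <- exp(-2)
  icB <- -log(2 / 3)  # B sits in its own and C's closure, of 3 diseases
  sv2_BB <- 2 * icB / 3  # (DV(B) + DV(B)) = 3
  list(
    am = am,
    hierarchy = h,
    theta_c = 1,
    theta_d = 1,
    gc = matrix(c(1, e2, e2, 1), 2, dimnames = list(c("c1", "c2"),
                                                    c("c1", "c2"))),
    gd = matrix(c(1, e2, e2, 1), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B"))),
    contrib_C = c(C = 1, B = 0.5, A = 0.25),
    dv = c(A = 1, B = 1.5, C = 1.75),
    sv1_AB = 0.6,
    sv2_AB = 0,
    sv1 = matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("A", "B"),
                                                       c("A", "B"))),
    sv2 = matrix(c(0, 0, 0, sv2_BB), 2, dimnames = list(c("A", "B"),
                                                        c("A", "B"))),
    dsim = matrix(c(0.5, 0.3, 0.3, (1 + sv2_BB) / 2), 2,
                  dimnames = list(c("A", "B"), c("A", "B"))),
    fv_c1_A = c(1, e2, 0.5, 0.3)
  )
}
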