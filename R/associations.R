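#' Load a circRNA-disease association edge list
#'
#' Reads a two-column delimited text file of (circRNA id, disease id) pairs
#' and builds a binary association matrix with circRNAs as rows and diseases
#' as columns. Identifiers are ordered by first appearance in the file;
#' duplicate pairs collapse to a single entry.
#'
#' The dialect is UTF-8 tab-separated values. An optional header line is
#' detected automatically: if the first row's ids never reappear in the body
#' and look like column labels (both fields match `circ`/`disease`-style
#' names case-insensitively, or the file declares `circ_id<TAB>disease_id`),
#' it is skipped. Files written by [write_associations()] always carry the
#' canonical header.
#'
#' @param path path to a tab-delimited edge list.
#' @param sep field separator (default tab).
#' @return an `assoc_matrix` object: a binary integer matrix with
#'   `rownames` = circRNA ids and `colnames` = disease ids.
#' @seealso [write_associations()], [make_balanced_dataset()]
#' @export
load_associations <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("association file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("association file is empty: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 2L)
  if (length(bad) > 0L) {
    stop("malformed association row (need 2 ",
         if (sep == "\t") "tab" else "delimiter", "-separated fields) at line ",
         bad[1L], ": '", lines[bad[1L]], "'")
  }
  circ <- trimws(vapply(fields, `[[`, "", 1L))
  dis  <- trimws(vapply(fields, `[[`, "", 2L))
  if (any(!nzchar(circ)) || any(!nzchar(dis))) {
    stop("empty identifier at line ", which(!nzchar(circ) | !nzchar(dis))[1L])
  }
  # header detection: canonical header, or a first row whose ids are unique
  # to row 1 and look like axis labels
  if (length(circ) > 1L) {
    canonical <- identical(tolower(c(circ[1L], dis[1L])),
                           c("circ_id", "disease_id"))
    labelish <- grepl("^circ", circ[1L], ignore.case = TRUE) &&
      grepl("^dis", dis[1L], ignore.case = TRUE) &&
      !(circ[1L] %in% circ[-1L]) && !(dis[1L] %in% dis[-1L])
    if (canonical || labelish) {
      circ <- circ[-1L]
      dis <- dis[-1L]
    }
  }
  if (length(circ) == 0L) stop("association file has a header but no data rows")
  assoc_matrix_from_pairs(circ, dis)
}

#' Build an association matrix from id vectors
#'
#' @param circ,dis character vectors of equal length giving the pairs.
#' @return an `assoc_matrix`.
#' @keywords internal
assoc_matrix_from_pairs <- function(circ, dis) {
  circ_ids <- unique(circ)
  disease_ids <- unique(dis)
  am <- matrix(0L, length(circ_ids), length(disease_ids),
               dimnames = list(circ_ids, disease_ids))
  am[cbind(match(circ, circ_ids), match(dis, disease_ids))] <- 1L
  structure(am, class = c("assoc_matrix", "matrix", "array"))
}

#' @export
print.assoc_matrix <- function(x, ...) {
  cat("circRNA-disease association matrix: ",
      nrow(x), " circRNAs x ", ncol(x), " diseases, ",
      sum(x), " known associations\n", sep = "")
  invisible(x)
}

#' Write an association matrix back to an edge-list file
#'
#' Emits one `circ_id<TAB>disease_id` row per known association, with a
#' canonical header, in row-major order of the matrix so that reloading
#' reproduces the matrix exactly (same ids, same order, same entries).
#'
#' @param am an `assoc_matrix`.
#' @param path output path.
#' @export
write_associations <- function(am, path) {
  stopifnot(inherits(am, "assoc_matrix"))
  idx <- which(t(am) == 1L)  # transpose => row-major pair order
  j <- (idx - 1L) %% ncol(am) + 1L
  i <- (idx - 1L) %/% ncol(am) + 1L
  out <- c("circ_id\tdisease_id",
           paste(rownames(am)[i], colnames(am)[j], sep = "\t"))
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Sample unobserved pairs as negatives
#'
#' Draws `n_neg` distinct zero cells of the association matrix uniformly
#' at random without replacement, to serve as label-0 training pairs.
#'
#' @param am an `assoc_matrix`.
#' @param n_neg number of negatives to draw.
#' @param seed RNG seed; a fixed seed gives a reproducible draw.
#' @return a data.frame with columns `circ_index`, `disease_index`, `label`
#'   (all 0), `circ_id`, `disease_id`.
#' @export
sample_negatives <- function(am, n_neg, seed = 1L) {
  stopifnot(inherits(am, "assoc_matrix"))
  zeros <- which(am == 0L)
  if (n_neg > length(zeros)) {
    stop("requested ", n_neg, " negatives but only ", length(zeros),
         " unobserved pairs are available")
  }
  if (n_neg == 0L) return(pair_samples(am, integer(0), integer(0)))
  set.seed(seed)
  # index into the candidate list: sample(zeros, ...) would misbehave when
  # only one unobserved pair remains (scalar first argument)
  picked <- zeros[sample.int(length(zeros), n_neg, replace = FALSE)]
  i <- (picked - 1L) %% nrow(am) + 1L
  j <- (picked - 1L) %/% nrow(am) + 1L
  pair_samples(am, i, j, label = 0L)
}

pair_samples <- function(am, i, j, label = integer(length(i))) {
  data.frame(
    circ_index = as.integer(i),
    disease_index = as.integer(j),
    label = as.integer(rep_len(label, length(i))),
    circ_id = rownames(am)[i],
    disease_id = colnames(am)[j],
    stringsAsFactors = FALSE
  )
}

#' Construct the balanced labelled dataset
#'
#' Returns the union of all verified associations (label 1) and an equally
#' sized random sample of unobserved pairs (label 0), the standard balanced
#' down-sampling construction for bipartite link prediction.
#'
#' @param am an `assoc_matrix` with at least one positive entry.
#' @param seed RNG seed for the negative draw.
#' @return a data.frame of pair samples (positives first), columns as in
#'   [sample_negatives()].
#' @export
make_balanced_dataset <- function(am, seed = 1L) {
  stopifnot(inherits(am, "assoc_matrix"))
  ones <- which(am == 1L)
  if (length(ones) == 0L) stop("association matrix has no positive entries")
  i <- (ones - 1L) %% nrow(am) + 1L
  j <- (ones - 1L) %/% nrow(am) + 1L
  pos <- pair_samples(am, i, j, label = 1L)
  neg <- sample_negatives(am, length(ones), seed = seed)
  rbind(pos, neg)
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds, stratified by label so that each
#' fold's class ratio matches the whole dataset to within one sample, with
#' overall fold sizes differing by at most one. Deterministic for a fixed
#' seed.
#'
#' @param samples a data.frame with a `label` column (as returned by
#'   [make_balanced_dataset()]).
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return integer vector of fold ids in `0:(k-1)`, one per sample.
#' @export
kfold_split <- function(samples, k = 5L, seed = 1L) {
  n <- nrow(samples)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  set.seed(seed)
  fold <- integer(n)
  totals <- integer(k)
  for (lab in sort(unique(samples$label))) {
    idx <- sample(which(samples$label == lab))
    q <- length(idx) %/% k
    r <- length(idx) %% k
    counts <- rep(q, k)
    if (r > 0L) {
      # put the leftover samples on the currently smallest folds so overall
      # sizes stay within one of each other
      extra <- order(totals, seq_len(k))[seq_len(r)]
      counts[extra] <- counts[extra] + 1L
    }
    fold[idx] <- rep.int(seq_len(k) - 1L, counts)
    totals <- totals + counts
  }
  fold
}

#' Write the balanced dataset with fold labels
#'
#' @param samples data.frame from [make_balanced_dataset()].
#' @param fold integer fold assignment from [kfold_split()].
#' @param path output TSV path.
#' @export
write_balanced_dataset <- function(samples, fold, path) {
  out <- data.frame(circ_id = samples$circ_id,
                    disease_id = samples$disease_id,
                    label = samples$label, fold = fold)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
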