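#' Assemble the disease similarity matrix
#'
#' Where the hierarchy covers a disease pair, the disease similarity is the
#' mean of the two semantic models; elsewhere it falls back to the disease
#' GIP kernel:
#' `DSim(i,j) = (SV1 + SV2)/2` if covered, else `GD(i,j)`.
#'
#' @param sv1,sv2 semantic similarity matrices (NA allowed where uncovered).
#' @param gd disease GIP kernel matrix (defined everywhere).
#' @param mask logical coverage matrix.
#' @return symmetric disease similarity matrix with a `provenance` attribute
#'   ("semantic" or "gip" per cell).
#' @export
build_dsim <- function(sv1, sv2, gd, mask) {
  dims <- dim(gd)
  if (!all(dim(sv1) == dims) || !all(dim(sv2) == dims) ||
      !all(dim(mask) == dims)) {
    stop("similarity matrices have mismatched shapes")
  }
  dsim <- gd
  dsim[mask] <- (sv1[mask] + sv2[mask]) / 2
  prov <- matrix("gip", dims[1L], dims[2L], dimnames = dimnames(gd))
  prov[mask] <- "semantic"
  attr(dsim, "provenance") <- prov
  dsim
}

#' Fusion descriptor for a circRNA-disease pair
#'
#' Concatenates the circRNA's similarity row with the disease's similarity
#' column into one numeric vector describing the candidate pair:
#' `[RSim(i, ), DSim( , j)]`.
#'
#' @param rsim circRNA similarity matrix.
#' @param dsim disease similarity matrix.
#' @param i circRNA (row) index; `j` disease (column) index.
#' @param j disease index.
#' @return numeric vector of length `nrow(rsim) + nrow(dsim)`.
#' @export
fuse <- function(rsim, dsim, i, j) {
  if (i < 1L || i > nrow(rsim)) stop("circRNA index out of range: ", i)
  if (j < 1L || j > ncol(dsim)) stop("disease index out of range: ", j)
  c(rsim[i, ], dsim[, j])
}

#' Feature table for a set of pair samples
#'
#' One fusion descriptor per sample row, with the aligned label vector.
#'
#' @param rsim,dsim similarity matrices.
#' @param samples data.frame with `circ_index`, `disease_index`, `label`.
#' @return list with `x` (samples x features matrix, columns named
#'   `circ_sim_*` then `dis_sim_*`) and `y` (integer labels).
#' @export
assemble_feature_table <- function(rsim, dsim, samples) {
  n <- nrow(samples)
  p <- nrow(rsim) + nrow(dsim)
  x <- matrix(0, n, p)
  if (n > 0L) {
    x[, seq_len(nrow(rsim))] <- rsim[samples$circ_index, , drop = FALSE]
    x[, nrow(rsim) + seq_len(nrow(dsim))] <-
      t(dsim[, samples$disease_index, drop = FALSE])
  }
  colnames(x) <- c(paste0("circ_sim_", seq_len(nrow(rsim))),
                   paste0("dis_sim_", seq_len(nrow(dsim))))
  list(x = x, y = as.integer(samples$label))
}

#' Write a labelled similarity matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path output path.
#' @export
write_similarity <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
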