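#' Gaussian interaction profile kernel width
#'
#' The kernel bandwidth is the inverse of the mean squared norm of the
#' interaction profiles, so that the average profile contributes unit scale:
#' `theta = 1 / (mean of ||V(i)||^2 over the N profiles)`.
#'
#' The denominator averages over the number of profiles being summed. Setting
#' `literal_n` replaces that count with an explicit value (e.g. the opposite
#' axis length of the association matrix) for compatibility with formulations
#' that normalise by the profile dimension instead.
#'
#' @param profiles numeric matrix, one interaction profile per row.
#' @param literal_n optional explicit normalisation count.
#' @return the width parameter `theta` (> 0).
#' @export
gip_width <- function(profiles, literal_n = NULL) {
  profiles <- as.matrix(profiles)
  sq <- rowSums(profiles^2)
  if (all(sq == 0)) {
    stop("all interaction profiles are zero; kernel width is undefined")
  }
  n <- if (is.null(literal_n)) nrow(profiles) else literal_n
  1 / (sum(sq) / n)
}

#' Gaussian interaction profile kernel similarity
#'
#' Similarity between entities i and j from their binary interaction
#' profiles: `K(i,j) = exp(-theta * ||V(i) - V(j)||^2)`. For circRNAs the
#' profiles are the rows of the association matrix; for diseases, the
#' columns.
#'
#' @param profiles numeric matrix, one profile per row (pass `t(am)` for the
#'   disease axis).
#' @param literal_n passed to [gip_width()].
#' @return list with `matrix` (symmetric, unit diagonal, entries in (0,1])
#'   and `theta`.
#' @export
gip_kernel <- function(profiles, literal_n = NULL) {
  profiles <- as.matrix(profiles)
  theta <- gip_width(profiles, literal_n = literal_n)
  sq <- rowSums(profiles^2)
  # ||Vi - Vj||^2 = ||Vi||^2 + ||Vj||^2 - 2 Vi.Vj
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # numerical guard
  k <- exp(-theta * d2)
  diag(k) <- 1
  dimnames(k) <- list(rownames(profiles), rownames(profiles))
  list(matrix = k, theta = theta)
}

#' GIP similarities for both axes of an association matrix
#'
#' @param am an `assoc_matrix`.
#' @param paper_literal_width if TRUE, normalise the circRNA width by the
#'   number of diseases and the disease width by the number of circRNAs
#'   (the opposite-axis counts) instead of by the number of profiles.
#' @return list with `gc` (circRNA kernel) and `gd` (disease kernel), each
#'   as returned by [gip_kernel()].
#' @export
gip_similarities <- function(am, paper_literal_width = FALSE) {
  stopifnot(inherits(am, "assoc_matrix"))
  m <- unclass(am)
  list(
    gc = gip_kernel(m, literal_n = if (paper_literal_width) ncol(m) else NULL),
    gd = gip_kernel(t(m), literal_n = if (paper_literal_width) nrow(m) else NULL)
  )
}
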