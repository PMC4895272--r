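#' Collaboration-score matrix from interaction weights
#'
#' The collaboration score between two miRNAs i and j measures how strongly
#' they share weighted interactions with mRNAs:
#'
#' \deqn{v_{ij} = \frac{\left(\sum_k w_{ik} w_{jk}\right)^2}
#'                     {\sum_k w_{ik} \cdot \sum_k w_{jk}}}
#'
#' with the sum over all l mRNAs. The mRNA-mRNA scores are the same formula
#' applied to the transpose of W (sum over miRNAs). For a binary W this is
#' exactly \eqn{|N(i) \cap N(j)|^2 / (|N(i)| |N(j)|)}, the squared shared-target
#' count over the product of target counts, and lies in \[0, 1\]; for general
#' weighted W only nonnegativity is guaranteed. Scaling all of W by c > 0
#' scales every score by c^2.
#'
#' Conventions: the diagonal is 0 (a feature does not collaborate with
#' itself, and total-collaboration sums thus exclude the self term); a
#' feature whose row sum is 0 (no surviving interactions) scores 0 against
#' everything — isolated features stay clusterable as singletons that the
#' size filters later discard.
#'
#' @param W An `interaction_weights` matrix (or any nonnegative numeric
#'   matrix with dimnames).
#' @param axis `"mirna"` (rows of W) or `"mrna"` (columns of W).
#' @return A symmetric nonnegative matrix with zero diagonal; feature IDs as
#'   dimnames; attribute `side` set to `axis`.
#' @export
collaboration_scores <- function(W, axis = c("mirna", "mrna")) {
  axis <- match.arg(axis)
  if (!is.matrix(W) || !is.numeric(W) || any(W < 0) || any(!is.finite(W))) {
    abort_mircore("W must be a nonnegative finite numeric matrix", "mircore_type_error")
  }
  M <- if (axis == "mirna") unclass_weights(W) else t(unclass_weights(W))
  cross <- tcrossprod(M)            # (i,j) -> sum_k w_ik w_jk
  rs <- rowSums(M)
  denom <- outer(rs, rs)
  V <- cross^2
  nz <- denom > 0
  V[nz] <- V[nz] / denom[nz]
  V[!nz] <- 0
  diag(V) <- 0
  V <- (V + t(V)) / 2               # enforce exact symmetry against fp drift
  dimnames(V) <- list(rownames(M), rownames(M))
  attr(V, "side") <- axis
  V
}

#' Rank features by total collaboration
#'
#' The total collaboration of a feature is the sum of its collaboration
#' scores against all other features (the zero diagonal makes the
#' self-inclusive and self-exclusive readings coincide). The ranking seeds
#' the greedy clustering. Ties are broken by lexicographic feature ID, so
#' the order is stable across runs.
#'
#' @param C A collaboration matrix from [collaboration_scores()].
#' @return A data frame with columns `id` and `total`, sorted by descending
#'   total.
#' @export
total_collaboration_ranking <- function(C) {
  if (!is.matrix(C) || is.null(rownames(C))) {
    abort_mircore("C must be a named collaboration matrix", "mircore_type_error")
  }
  totals <- rowSums(C)
  ord <- order(-totals, rownames(C), method = "radix")
  data.frame(id = rownames(C)[ord], total = unname(totals[ord]),
             stringsAsFactors = FALSE)
}

#' Write a collaboration matrix as TSV
#' @param C Collaboration matrix.
#' @param path Output path.
#' @export
write_collaboration <- function(C, path) {
  attr(C, "side") <- NULL
  write_expression(C, path)
}
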