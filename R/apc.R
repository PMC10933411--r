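#' Average product correction of a score matrix
#'
#' Subtracts the product-of-means background
#' `mean_i(S) * mean_j(S) / mean(S)` from a square symmetric score matrix.
#' Means are taken over the full matrix, which makes the correction
#' annihilate any rank-one (product-structured) matrix exactly — the null
#' property that motivates APC. A zero overall mean leaves the matrix
#' uncorrected with a warning.
#'
#' @param S Square symmetric numeric matrix.
#' @return Corrected symmetric matrix of the same dimension.
#' @export
apc_residue <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    coev_stop("APC expects a square matrix")
  if (max(abs(S - t(S))) > 1e-8)
    coev_stop("APC expects a symmetric matrix")
  mu <- mean(S)
  if (mu == 0) {
    coev_warn("overall mean of score matrix is zero; returning raw scores")
    return(S)
  }
  mi <- rowMeans(S)
  out <- S - outer(mi, mi) / mu
  (out + t(out)) / 2
}

#' Protein-level average product correction
#'
#' Re-ranks protein-pair scores by subtracting each protein's tendency to
#' score highly with everything: the pairwise score table is embedded in a
#' symmetric protein x protein matrix (absent pairs contribute 0 to the
#' means), APC is applied, and the observed pairs are returned with their
#' corrected scores in descending order.
#'
#' @param pairs Data frame with columns `protein_a`, `protein_b`, `score`.
#' @param universe Optional character vector of proteins defining the matrix
#'   (defaults to proteins observed in `pairs`).
#' @return `pairs` with an added `apc_score` column, sorted by it
#'   descending (ties by protein ids).
#' @export
apc_protein <- function(pairs, universe = NULL) {
  need <- c("protein_a", "protein_b", "score")
  if (!all(need %in% names(pairs)))
    coev_stop("pairs needs columns protein_a, protein_b, score")
  prots <- universe %||% sort(unique(c(pairs$protein_a, pairs$protein_b)))
  P <- length(prots)
  S <- matrix(0, P, P, dimnames = list(prots, prots))
  ia <- match(pairs$protein_a, prots)
  ib <- match(pairs$protein_b, prots)
  if (anyNA(ia) || anyNA(ib))
    coev_stop("universe does not cover all proteins in pairs")
  S[cbind(ia, ib)] <- pairs$score
  S[cbind(ib, ia)] <- pairs$score
  mu <- mean(S)
  if (mu == 0) {
    coev_warn("overall mean of protein score matrix is zero; ranking by raw scores")
    out <- pairs
    out$apc_score <- pairs$score
  } else {
    C <- apc_residue(S)
    out <- pairs
    out$apc_score <- C[cbind(ia, ib)]
  }
  out[order(-out$apc_score, out$protein_a, out$protein_b), , drop = FALSE]
}
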