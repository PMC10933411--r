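#' Sequence reweighting
#'
#' Each row's weight is the reciprocal of the number of rows (itself
#' included) with fractional identity at least `theta`; the effective
#' sequence count `m_eff` is the sum of weights. Identity counts gap-gap
#' positions as matches, consistently with the rest of the package.
#'
#' @param aln Alignment (or integer residue matrix).
#' @param theta Identity threshold for the neighbourhood count (default 0.8).
#' @return List with `weights` and `m_eff`.
#' @export
sequence_weights <- function(aln, theta = 0.8) {
  M <- if (is.matrix(aln)) aln else aln_matrix(aln)
  if (nrow(M) == 0L) coev_stop("empty alignment")
  idm <- identity_matrix(M)
  w <- 1 / rowSums(idm >= theta)
  list(weights = w, m_eff = sum(w))
}

#' Pseudocounted frequency estimates
#'
#' Computes reweighted single-column and pair frequencies over the 21-state
#' alphabet with a relative pseudocount `lam_frac`:
#' with `lambda = lam_frac / (1 - lam_frac) * m_eff`,
#' `f1(i,a) = (lambda/q + sum_m w_m [A_i^m = a]) / (lambda + m_eff)` and
#' `f2` analogously with `lambda/q^2`; the diagonal blocks of `f2` are set to
#' `f2(i,i,a,b) = delta_ab f1(i,a)`.
#'
#' @param aln Alignment or integer matrix.
#' @param weights Row weights from [sequence_weights()].
#' @param lam_frac Relative pseudocount in \[0, 1) (default 0.5, i.e.
#'   `lambda = m_eff`).
#' @param q Alphabet size (default 21).
#' @return List with `f1` (L x q matrix) and `f2` ((L*q) x (L*q) matrix,
#'   block (i,a),(j,b) indexed as `(i-1)*q + a`).
#' @export
frequencies <- function(aln, weights, lam_frac = 0.5, q = COEV_Q) {
  if (lam_frac < 0 || lam_frac >= 1)
    coev_stop("lam_frac must lie in [0, 1)")
  M <- if (is.matrix(aln)) aln else aln_matrix(aln)
  L <- ncol(M)
  w <- weights$weights %||% weights
  m_eff <- sum(w)
  lam <- lam_frac / (1 - lam_frac) * m_eff
  X <- one_hot(M, q)
  c1 <- as.vector(crossprod(X, w))
  f1 <- matrix((lam / q + c1) / (lam + m_eff), nrow = L, ncol = q, byrow = TRUE)
  f2 <- (lam / q^2 + crossprod(X, X * w)) / (lam + m_eff)
  for (i in seq_len(L)) {
    blk <- (i - 1L) * q + seq_len(q)
    f2[blk, blk] <- diag(f1[i, ], q)
  }
  list(f1 = f1, f2 = f2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean-field coupling estimation
#'
#' Builds the connected-correlation matrix
#' `C_ij(a,b) = f2(i,j,a,b) - f1(i,a) f1(j,b)` over the first `q - 1` states
#' per column (state `q`, the gap, is the gauge reference) and estimates
#' couplings as `e = -C^{-1}` (off-diagonal blocks). The result is embedded
#' in the full `q`-state space with gauge rows/columns zero, diagonal site
#' blocks zeroed, and symmetrized.
#'
#' @param f1,f2 Frequencies from [frequencies()] (pseudocount required for
#'   invertibility).
#' @param q Alphabet size.
#' @return `(L*q) x (L*q)` coupling matrix `E` with
#'   `E[(i-1)*q + a, (j-1)*q + b] = e_ij(a,b)`.
#' @export
fit_couplings <- function(f1, f2, q = COEV_Q) {
  q <- as.integer(q)
  L <- nrow(f1)
  sel <- as.vector(vapply(seq_len(L), function(i) (i - 1L) * q + seq_len(q - 1L),
                          integer(q - 1L)))
  f1v <- as.vector(t(f1))
  C <- f2[sel, sel] - tcrossprod(f1v[sel])
  inv <- tryCatch(solve(C), error = function(e)
    coev_stop(paste0("connected-correlation matrix is singular (",
                     conditionMessage(e),
                     "); raise the pseudocount lam_frac"),
              "coev_numerical_error"))
  E <- matrix(0, L * q, L * q)
  E[sel, sel] <- -inv
  for (i in seq_len(L)) {
    blk <- (i - 1L) * q + seq_len(q)
    E[blk, blk] <- 0
  }
  (E + t(E)) / 2
}

#' Direct information
#'
#' For every column pair (i, j) a two-site model
#' `P_ij(a,b) ~ exp(e_ij(a,b)) mu_i(a) mu_j(b)` is fitted by iterative
#' proportional scaling until its marginals match `f1(i,.)` and `f1(j,.)`
#' within `tol`; the direct information is the Kullback-Leibler divergence of
#' `P_ij` from the product of marginals (natural log). Pairs that do not
#' converge within `max_iter` keep their best-effort value and are reported
#' via a warning.
#'
#' @param couplings Coupling matrix from [fit_couplings()].
#' @param f1 Single-column frequencies.
#' @param tol Marginal-matching tolerance (default 1e-4).
#' @param max_iter Maximum scaling iterations per pair (default 500).
#' @param q Alphabet size.
#' @return Symmetric L x L matrix of DI values (diagonal zero), with a
#'   logical attribute `converged`.
#' @export
direct_information <- function(couplings, f1, tol = 1e-4, max_iter = 500,
                               q = COEV_Q) {
  res <- di_ipf_cpp(couplings, f1, as.integer(q), tol, as.integer(max_iter))
  di <- res$di
  conv <- res$converged
  if (!all(conv)) {
    bad <- which(!conv & upper.tri(conv), arr.ind = TRUE)
    coev_warn(sprintf(
      "direct information did not converge for %d column pair(s), e.g. (%d,%d); best-effort values kept",
      nrow(bad), bad[1, 1], bad[1, 2]))
  }
  attr(di, "converged") <- conv
  di
}

#' Fit a mean-field DCA model to an alignment
#'
#' Convenience wrapper running [sequence_weights()], [frequencies()],
#' [fit_couplings()] and [direct_information()], and applying the
#' residue-level average product correction to the DI matrix.
#'
#' @param aln Alignment (typically the `aln` of a paired alignment).
#' @param theta Reweighting identity threshold.
#' @param lam_frac Relative pseudocount.
#' @param tol,max_iter Passed to [direct_information()].
#' @param q Alphabet size.
#' @return A `coev_dca` object: `L`, `q`, `theta`, `lam_frac`, `weights`,
#'   `m_eff`, `f1`, `couplings`, `di_raw`, `di_apc`.
#' @export
mfdca <- function(aln, theta = 0.8, lam_frac = 0.5, tol = 1e-4,
                  max_iter = 500, q = COEV_Q) {
  M <- if (is.matrix(aln)) aln else aln_matrix(aln)
  sw <- sequence_weights(M, theta = theta)
  fr <- frequencies(M, sw, lam_frac = lam_frac, q = q)
  E <- fit_couplings(fr$f1, fr$f2, q = q)
  di <- direct_information(E, fr$f1, tol = tol, max_iter = max_iter, q = q)
  structure(
    list(L = ncol(M), q = q, theta = theta, lam_frac = lam_frac,
         weights = sw$weights, m_eff = sw$m_eff, f1 = fr$f1,
         couplings = E, di_raw = di, di_apc = apc_residue(di)),
    class = "coev_dca")
}

#' @export
print.coev_dca <- function(x, ...) {
  cat(sprintf("<coev_dca> L=%d q=%d m_eff=%.1f theta=%.2f lam_frac=%.2f\n",
              x$L, x$q, x$m_eff, x$theta, x$lam_frac))
  invisible(x)
}

#' Inter-protein score table
#'
#' Extracts from a fitted DCA model the scores of all inter-protein column
#' pairs (`i <= split < j`) of a paired alignment, reported in 1-based
#' positions of each original query protein via the per-block
#' column-to-query maps.
#'
#' @param model A `coev_dca` fit of the paired alignment.
#' @param paln The paired alignment (for `split`, maps, clade, query pair).
#' @return Data frame (`clade`, `query_a`, `query_b`, `pos_a`, `pos_b`,
#'   `raw_di`, `apc_di`), one row per inter-protein column pair.
#' @export
inter_scores <- function(model, paln) {
  if (is.null(paln$split) || is.na(paln$split))
    coev_stop("paired alignment has no split index")
  L <- model$L
  split <- paln$split
  ii <- rep(seq_len(split), each = L - split)
  jj <- rep((split + 1L):L, times = split)
  data.frame(
    clade = paln$clade,
    query_a = unname(paln$query_pair["a"]),
    query_b = unname(paln$query_pair["b"]),
    pos_a = paln$map_a[ii],
    pos_b = paln$map_b[jj - split],
    raw_di = model$di_raw[cbind(ii, jj)],
    apc_di = model$di_apc[cbind(ii, jj)],
    stringsAsFactors = FALSE)
}

#' Top-k inter-protein scores
#'
#' Returns the `k` largest scores of a score table in descending order, ties
#' broken by ascending (`pos_a`, `pos_b`).
#'
#' @param table Score table from [inter_scores()].
#' @param k Number of scores (default 5).
#' @param field `"raw_di"` or `"apc_di"`.
#' @return The top-k rows of `table`, ordered.
#' @export
top_k <- function(table, k = 5, field = c("raw_di", "apc_di")) {
  field <- match.arg(field)
  if (nrow(table) < k)
    coev_stop(sprintf("pair %s-%s has %d inter-protein entries, fewer than k=%d",
                      table$query_a[1], table$query_b[1], nrow(table), k))
  ord <- order(-table[[field]], table$pos_a, table$pos_b)
  out <- table[ord[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Persist a fitted DCA model
#'
#' Writes the model to an RDS container next to a human-readable JSON header
#' (`<prefix>.json`) carrying the model dimensions and parameters (`L`, `q`,
#' `theta`, `lam_frac`, `m_eff`).
#'
#' @param model A `coev_dca` fit.
#' @param prefix Path prefix; writes `<prefix>.rds` and `<prefix>.json`.
#' @return The prefix, invisibly (writer); a `coev_dca` (reader).
#' @export
write_dca_model <- function(model, prefix) {
  jsonlite::write_json(
    list(format = "coev_dca", version = 1L, L = model$L, q = model$q,
         theta = model$theta, lam_frac = model$lam_frac,
         m_eff = model$m_eff),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  saveRDS(model, paste0(prefix, ".rds"))
  invisible(prefix)
}

#' @rdname write_dca_model
#' @export
read_dca_model <- function(prefix) {
  header <- jsonlite::read_json(paste0(prefix, ".json"))
  if (!identical(header$format, "coev_dca"))
    coev_stop("not a coev_dca model dump", "coev_format_error")
  model <- readRDS(paste0(prefix, ".rds"))
  if (model$L != header$L || model$q != header$q)
    coev_stop("model dump header does not match its payload",
              "coev_format_error")
  model
}

#' Write a score table as TSV
#'
#' @param table Score table (or several, row-bound).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_scores <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
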