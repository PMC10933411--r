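#' Default clade order
#'
#' The four bacterial phyla integrated by default, in fixed feature order.
#' @return Character vector of clade labels.
#' @export
default_clade_order <- function() {
  c("Proteobacteria", "Firmicutes", "Actinobacteria", "Bacteroidota")
}

#' Assemble a clade-blocked feature vector
#'
#' Concatenates, per clade in a fixed order, the top-k inter-protein DCA
#' scores of that clade (descending); clades without a usable paired
#' alignment contribute `k` copies of the fill value -1. With the default
#' four clades and k = 5 this yields the 20-element integration vector.
#'
#' @param tables Named list mapping clade label to a score table
#'   ([inter_scores()]) or `NULL` for a missing clade.
#' @param clade_order Fixed clade order (default [default_clade_order()]).
#' @param k Scores kept per clade (default 5; `k * length(clade_order)` is
#'   capped at 20 features by default).
#' @param fill Imputation value for missing clades (default -1).
#' @param field Score field to rank by (default `"raw_di"`).
#' @return Named numeric vector of length `k * length(clade_order)` with a
#'   logical `missing_mask` attribute (one flag per clade).
#' @export
build_feature_vector <- function(tables, clade_order = default_clade_order(),
                                 k = 5, fill = -1,
                                 field = c("raw_di", "apc_di")) {
  field <- match.arg(field)
  vals <- numeric(0)
  mask <- logical(length(clade_order))
  names(mask) <- clade_order
  for (ci in seq_along(clade_order)) {
    cl <- clade_order[ci]
    tab <- tables[[cl]]
    if (is.null(tab) || nrow(tab) == 0L) {
      mask[ci] <- TRUE
      vals <- c(vals, rep(fill, k))
    } else {
      vals <- c(vals, top_k(tab, k = k, field = field)[[field]])
    }
  }
  names(vals) <- paste0(rep(clade_order, each = k), "_", rep(seq_len(k),
                        times = length(clade_order)))
  attr(vals, "missing_mask") <- mask
  vals
}

#' Assemble a labelled interaction benchmark
#'
#' Positives are scored pairs with `score > score_min`. Negatives are
#' seed-deterministic random pairings of proteins from the positive set,
#' rejecting (1) pairs already positive, (2) proteins absent from every
#' positive, (3) self pairs, (4) explicitly excluded (e.g. self-homologous)
#' pairs, and capping each protein's negative frequency at `freq_cap`.
#'
#' @param positives Data frame (`protein_a`, `protein_b`, `score`).
#' @param score_min Positive-score threshold, strict (default 500).
#' @param freq_cap Maximum negatives per protein (default 60).
#' @param n_negatives Optional cap on total negatives (default: all
#'   drawable under the frequency cap).
#' @param exclude_pairs Optional data frame (`protein_a`, `protein_b`) of
#'   pairs to exclude from negatives.
#' @param family_map Optional named vector protein -> family id; defaults to
#'   each protein being its own family.
#' @param seed Seed for the negative draw.
#' @return Data frame (`pair_id`, `protein_a`, `protein_b`, `label`,
#'   `family_a`, `family_b`, `family_group`).
#' @export
assemble_benchmark <- function(positives, score_min = 500, freq_cap = 60,
                               n_negatives = NULL, exclude_pairs = NULL,
                               family_map = NULL, seed = NULL) {
  pos <- positives[positives$score > score_min, , drop = FALSE]
  if (nrow(pos) == 0L)
    coev_stop("no positives above score_min")
  pos_key <- pair_key(pos$protein_a, pos$protein_b)
  prots <- sort(unique(c(pos$protein_a, pos$protein_b)))
  if (length(prots) < 3L)
    coev_stop("too few proteins in the positive set to draw negatives")
  excl_key <- if (is.null(exclude_pairs)) character(0)
              else pair_key(exclude_pairs$protein_a, exclude_pairs$protein_b)
  ## enumerate candidate negative pairs, shuffle, greedily honour the cap
  cand <- t(utils::combn(prots, 2L))
  ck <- pair_key(cand[, 1], cand[, 2])
  cand <- cand[!(ck %in% pos_key) & !(ck %in% excl_key), , drop = FALSE]
  ord <- with_seed(seed, sample.int(nrow(cand)))
  freq <- setNames(integer(length(prots)), prots)
  keep <- logical(nrow(cand))
  n_kept <- 0L
  target <- n_negatives %||% Inf
  for (r in ord) {
    a <- cand[r, 1]; b <- cand[r, 2]
    if (freq[a] >= freq_cap || freq[b] >= freq_cap) next
    keep[r] <- TRUE
    freq[a] <- freq[a] + 1L
    freq[b] <- freq[b] + 1L
    n_kept <- n_kept + 1L
    if (n_kept >= target) break
  }
  neg <- cand[keep, , drop = FALSE]
  fam <- function(p) if (is.null(family_map)) p else unname(family_map[p])
  out <- data.frame(
    protein_a = c(pos$protein_a, neg[, 1]),
    protein_b = c(pos$protein_b, neg[, 2]),
    label = rep(c(1L, 0L), c(nrow(pos), nrow(neg))),
    stringsAsFactors = FALSE)
  out$pair_id <- pair_key(out$protein_a, out$protein_b)
  out$family_a <- fam(out$protein_a)
  out$family_b <- fam(out$protein_b)
  out$family_group <- pair_key(out$family_a, out$family_b)
  out[, c("pair_id", "protein_a", "protein_b", "label",
          "family_a", "family_b", "family_group")]
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

#' Equalize class balance across missing-data strata
#'
#' Phylogenetic coverage confounds interaction labels: interacting pairs
#' tend to have fewer missing clades. To stop a classifier from exploiting
#' this, negatives are down-sampled (seed-deterministically) within every
#' stratum of `n_missing` so that each stratum's negative:positive ratio
#' equals the smallest ratio observed in any stratum with positives;
#' positives are never discarded. Strata with positives but no negatives are
#' kept as-is with a warning.
#'
#' @param bench Benchmark data frame with `label` and `n_missing` columns.
#' @param seed Seed for the down-sampling.
#' @return The balanced benchmark (subset of rows of `bench`).
#' @export
balance_by_missingness <- function(bench, seed = NULL) {
  if (!all(c("label", "n_missing") %in% names(bench)))
    coev_stop("benchmark needs label and n_missing columns")
  strata <- split(seq_len(nrow(bench)), bench$n_missing)
  ratios <- vapply(strata, function(idx) {
    np <- sum(bench$label[idx] == 1L)
    nn <- sum(bench$label[idx] == 0L)
    if (np == 0L) NA_real_ else nn / np
  }, numeric(1))
  if (all(is.na(ratios)))
    coev_stop("no stratum contains positives")
  if (any(ratios == 0, na.rm = TRUE)) {
    coev_warn("a stratum has positives but no negatives; kept as-is")
    ratios[ratios == 0] <- NA_real_
  }
  if (all(is.na(ratios)))
    coev_stop("no stratum contains both positives and negatives")
  r0 <- min(ratios, na.rm = TRUE)
  seeds <- child_seeds(seed %||% 1L, length(strata))
  keep <- unlist(lapply(seq_along(strata), function(s) {
    idx <- strata[[s]]
    pos <- idx[bench$label[idx] == 1L]
    neg <- idx[bench$label[idx] == 0L]
    if (length(pos) == 0L) return(integer(0))
    n_keep <- min(length(neg), floor(length(pos) * r0))
    c(pos, with_seed(seeds[s], sample(neg, n_keep)))
  }))
  out <- bench[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum-DCA baseline ranking
#'
#' Ranks protein pairs by their single highest raw inter-protein DCA score
#' across all clades, without any learning; pairs with every clade missing
#' score -1.
#'
#' @param feature_matrix Numeric matrix of clade-blocked features (rows =
#'   pairs); because each present clade block is stored descending with
#'   missing clades at -1, the row maximum is exactly the max-DCA statistic.
#' @return Data frame (`pair_id`, `method`, `score`, `rank`), descending.
#' @export
baseline_max_dca <- function(feature_matrix) {
  score <- apply(feature_matrix, 1, max)
  ranked_predictions(rownames(feature_matrix) %||%
                       as.character(seq_len(nrow(feature_matrix))),
                     score, method = "max_dca")
}

ranked_predictions <- function(pair_id, score, method) {
  ord <- order(-score, pair_id)
  data.frame(pair_id = pair_id[ord], method = method, score = score[ord],
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Precision-recall curve and AUC-PR
#'
#' Computes precision and recall at every distinct score threshold and the
#' area under the PR curve by right-continuous step integration
#' `sum (R_t - R_(t-1)) P_t`.
#'
#' @param scores Numeric prediction scores (higher = more likely positive).
#' @param labels Binary labels (1 = positive).
#' @return List with `curve` (data frame `threshold`, `precision`,
#'   `recall`), `auc_pr`, and `prevalence`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    coev_stop("scores and labels must have equal length")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L)
    coev_stop("precision-recall undefined without positives")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  tp <- cumsum(y); fp <- cumsum(1L - y)
  at <- which(!duplicated(s, fromLast = TRUE))
  prec <- tp[at] / (tp[at] + fp[at])
  rec <- tp[at] / n_pos
  auc <- sum(diff(c(0, rec)) * prec)
  list(curve = data.frame(threshold = s[at], precision = prec, recall = rec),
       auc_pr = auc, prevalence = n_pos / length(labels))
}

#' Classify a protein pair contact as direct or not
#'
#' A pair of coordinate sets is `direct` when at least `min_atoms`
#' inter-set atom pairs lie within `cutoff` angstroms (Euclidean).
#'
#' @param atoms_a,atoms_b Numeric matrices of 3-D coordinates (rows =
#'   atoms, columns = x, y, z), in angstroms.
#' @param cutoff Distance cutoff in angstroms (default 5).
#' @param min_atoms Minimum number of inter-set contacts (default 10).
#' @return List with `status` (`"direct"` / `"not_direct"`) and
#'   `n_contact_pairs`.
#' @export
classify_contact <- function(atoms_a, atoms_b, cutoff = 5, min_atoms = 10) {
  atoms_a <- as.matrix(atoms_a); atoms_b <- as.matrix(atoms_b)
  if (nrow(atoms_a) == 0L || nrow(atoms_b) == 0L)
    coev_stop("empty coordinate set")
  if (ncol(atoms_a) != 3L || ncol(atoms_b) != 3L)
    coev_stop("coordinates must be n x 3 matrices")
  d2 <- outer(rowSums(atoms_a^2), rowSums(atoms_b^2), "+") -
    2 * tcrossprod(atoms_a, atoms_b)
  n_contact <- sum(d2 <= cutoff^2 + 1e-12)
  list(status = if (n_contact >= min_atoms) "direct" else "not_direct",
       n_contact_pairs = n_contact)
}
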