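#' Configuration for the synthetic multi-clade generator
#'
#' Defines the conditions under which synthetic paired alignments are drawn
#' from a pairwise Potts model: protein lengths, clade count and depth,
#' planted intra- and inter-protein couplings, clade-specific random fields,
#' and Gibbs sampling controls. Couplings share one topology across clades
#' while fields are clade-specific, so clades carry the same interaction
#' signal but share no sequences.
#'
#' @param n_clades Number of clades (default 4).
#' @param rows_per_clade Sequences sampled per clade: either a fixed count or
#'   a `c(min, max)` range from which each (pair, clade) depth is drawn
#'   uniformly (default `c(60, 200)`, spanning near-threshold to comfortably
#'   deep paired alignments; depth heterogeneity across clades is a central
#'   feature of real orthologous alignments).
#' @param len_a,len_b Protein lengths (default 6 each).
#' @param q Alphabet size (default 21).
#' @param planted_pairs Data frame (`pos_a`, `pos_b`, `strength`) of planted
#'   inter-protein couplings for interacting pairs (default two pairs of
#'   strength 2).
#' @param intra_coupling_density Fraction of within-protein position pairs
#'   receiving a coupling (default 0.15).
#' @param intra_strength Strength of within-protein couplings (default 1).
#' @param field_scale Standard deviation of the clade-specific random fields
#'   (default 0.5).
#' @param burn_in,thin Gibbs sweeps discarded before sampling and between
#'   samples (defaults 1000 and 10).
#' @param missing_prob Probability that a non-query clade is missing for a
#'   pair (default 0.3; the first clade, seeded from the query species, is
#'   always present).
#' @return A `coev_gen_config` list.
#' @export
generator_config <- function(n_clades = 4, rows_per_clade = c(60, 200),
                             len_a = 6, len_b = 6, q = COEV_Q,
                             planted_pairs = data.frame(
                               pos_a = c(2L, 5L), pos_b = c(1L, 4L),
                               strength = c(2, 2)),
                             intra_coupling_density = 0.15,
                             intra_strength = 1, field_scale = 0.5,
                             burn_in = 1000, thin = 10,
                             missing_prob = 0.3) {
  if (any(rows_per_clade < 2) || !length(rows_per_clade) %in% c(1L, 2L))
    coev_stop("rows_per_clade must be a count >= 2 or a c(min, max) range")
  if (any(planted_pairs$pos_a < 1 | planted_pairs$pos_a > len_a) ||
      any(planted_pairs$pos_b < 1 | planted_pairs$pos_b > len_b))
    coev_stop("planted positions out of bounds")
  if (any(!is.finite(planted_pairs$strength)))
    coev_stop("planted coupling strengths must be finite")
  structure(list(n_clades = n_clades, rows_per_clade = rows_per_clade,
                 len_a = len_a, len_b = len_b, q = q,
                 planted_pairs = planted_pairs,
                 intra_coupling_density = intra_coupling_density,
                 intra_strength = intra_strength, field_scale = field_scale,
                 burn_in = burn_in, thin = thin,
                 missing_prob = missing_prob),
            class = "coev_gen_config")
}

match_coupling <- function(strength, q) diag(strength, q)

draw_depth <- function(rows_per_clade, seed) {
  if (length(rows_per_clade) == 1L) return(as.integer(rows_per_clade))
  with_seed(seed, sample(seq(rows_per_clade[1], rows_per_clade[2]), 1L))
}

## Sample intra-protein edges within blocks of given lengths at `density`.
sample_intra_edges <- function(lens, density, seed) {
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  n_cand <- sum(choose(lens, 2))
  u <- with_seed(seed, runif(max(n_cand, 1L)))
  taken <- 0L
  edges <- NULL
  for (b in seq_along(lens)) {
    if (lens[b] < 2) next
    cand <- t(utils::combn(seq_len(lens[b]), 2L)) + offsets[b]
    ub <- u[taken + seq_len(nrow(cand))]
    taken <- taken + nrow(cand)
    edges <- rbind(edges, cand[ub < density, , drop = FALSE])
  }
  if (is.null(edges)) matrix(integer(0), 0, 2) else edges
}

## Build the shared coupling topology for one protein pair.
## Returns list(edges = m x 2 matrix, J = list of q x q matrices).
build_pair_couplings <- function(cfg, positive, seed) {
  edges <- sample_intra_edges(c(cfg$len_a, cfg$len_b),
                              cfg$intra_coupling_density, seed)
  J <- rep(list(match_coupling(cfg$intra_strength, cfg$q)), nrow(edges))
  if (positive && nrow(cfg$planted_pairs) > 0) {
    inter <- cbind(cfg$planted_pairs$pos_a, cfg$len_a + cfg$planted_pairs$pos_b)
    edges <- rbind(edges, inter)
    J <- c(J, lapply(cfg$planted_pairs$strength, match_coupling, q = cfg$q))
  }
  list(edges = edges, J = J)
}

#' Sample sequences from a pairwise Potts model
#'
#' Single-site heat-bath Gibbs sampling from
#' `P(s) ~ exp(sum_i h_i(s_i) + sum_(ij) J_ij(s_i, s_j))`, discarding
#' `burn_in` sweeps and keeping one sample every `thin` sweeps. Deterministic
#' under `seed`.
#'
#' @param h L x q field matrix.
#' @param edges m x 2 matrix of coupled site pairs (1-based).
#' @param J List of q x q coupling matrices, one per edge.
#' @param n_rows Number of samples.
#' @param burn_in,thin Sampler controls.
#' @param seed Integer seed.
#' @return Integer matrix (`n_rows` x L) of states in 1..q.
#' @export
sample_potts <- function(h, edges, J, n_rows, burn_in = 1000, thin = 10,
                         seed = NULL) {
  if (NROW(edges) != length(J))
    coev_stop("edges and J must have matching lengths")
  if (NROW(edges) > 0 && (min(edges) < 1 || max(edges) > nrow(h)))
    coev_stop("edge indices out of bounds")
  storage.mode(edges) <- "integer"
  with_seed(seed, potts_gibbs_cpp(h, edges, J, as.integer(n_rows),
                                  as.integer(burn_in), as.integer(thin)))
}

#' Exact single-column marginals of a tiny Potts model
#'
#' Brute-force enumeration of all `q^L` states; only feasible for toy
#' systems (roughly `q^L <= 1e6`). Serves as the ground-truth oracle for
#' validating the Gibbs sampler.
#'
#' @inheritParams sample_potts
#' @return L x q matrix of exact marginal probabilities.
#' @export
potts_exact_marginals <- function(h, edges, J) {
  L <- nrow(h); q <- ncol(h)
  if (q^L > 1e6) coev_stop("system too large for exact enumeration")
  states <- as.matrix(expand.grid(rep(list(seq_len(q)), L)))
  logw <- rowSums(matrix(h[cbind(rep(seq_len(L), each = nrow(states)),
                                 as.vector(states))],
                         nrow = nrow(states)))
  if (NROW(edges) > 0) {
    for (e in seq_len(NROW(edges))) {
      logw <- logw + J[[e]][cbind(states[, edges[e, 1]], states[, edges[e, 2]])]
    }
  }
  w <- exp(logw - max(logw))
  w <- w / sum(w)
  f <- matrix(0, L, q)
  for (i in seq_len(L))
    f[i, ] <- vapply(seq_len(q), function(a) sum(w[states[, i] == a]), numeric(1))
  f
}

states_to_rows <- function(M, q = COEV_Q) {
  letters21 <- COEV_ALPHABET[seq_len(q)]
  apply(M, 1, function(r) paste(letters21[r], collapse = ""))
}

#' Generate one synthetic protein pair across clades
#'
#' Draws, for every present clade, an independent Potts sample of the paired
#' proteins (shared coupling topology, clade-specific random fields and
#' seeds, hence disjoint sequence pools), and packages the result as the
#' single-protein alignments, ortholog tables and clade table the real
#' pipeline consumes.
#'
#' @param cfg A [generator_config()].
#' @param pair_name Base name for the pair (query ids become
#'   `<pair_name>A`, `<pair_name>B`).
#' @param positive Whether inter-protein couplings are planted.
#' @param present Logical vector over clades (default all present).
#' @param seed Integer seed.
#' @param clade_order Clade labels (default [default_clade_order()]).
#' @return List with `pair_id`, `label`, `clades` (per present clade:
#'   `msa_a`, `msa_b`, `orth`), `clade_table`, and `truth` (planted pairs
#'   and presence mask).
#' @export
make_clade_set <- function(cfg, pair_name = "P1", positive = TRUE,
                           present = rep(TRUE, cfg$n_clades), seed = 1L,
                           clade_order = default_clade_order()) {
  clades <- clade_order[seq_len(cfg$n_clades)]
  seeds <- child_seeds(seed, cfg$n_clades * 2L + 1L)
  coup <- build_pair_couplings(cfg, positive, seeds[1])
  qa <- paste0(pair_name, "A"); qb <- paste0(pair_name, "B")
  L <- cfg$len_a + cfg$len_b
  out <- list()
  clade_table <- NULL
  for (c in seq_len(cfg$n_clades)) {
    if (!present[c]) { out[[clades[c]]] <- NULL; next }
    h <- with_seed(seeds[1 + c],
                   matrix(rnorm(L * cfg$q, sd = cfg$field_scale), L, cfg$q))
    depth <- draw_depth(cfg$rows_per_clade, seeds[1 + c])
    M <- sample_potts(h, coup$edges, coup$J, depth,
                      burn_in = cfg$burn_in, thin = cfg$thin,
                      seed = seeds[1 + cfg$n_clades + c])
    species <- sprintf("c%ds%d", c, seq_len(depth))
    sub_a <- paste0(species, ".", qa)
    sub_b <- paste0(species, ".", qb)
    rows_a <- states_to_rows(M[, seq_len(cfg$len_a), drop = FALSE], cfg$q)
    rows_b <- states_to_rows(M[, cfg$len_a + seq_len(cfg$len_b), drop = FALSE],
                             cfg$q)
    msa_a <- new_alignment(rows_a, sub_a, species, query_index = 1L,
                           col_to_query = seq_len(cfg$len_a))
    msa_b <- new_alignment(rows_b, sub_b, species, query_index = 1L,
                           col_to_query = seq_len(cfg$len_b))
    orth <- data.frame(
      query_id = rep(c(sub_a[1], sub_b[1]), each = depth),
      species_id = rep(species, 2L),
      subject_id = c(sub_a, sub_b),
      bitscore = 100,
      stringsAsFactors = FALSE)
    out[[clades[c]]] <- list(msa_a = msa_a, msa_b = msa_b, orth = orth)
    clade_table <- rbind(clade_table,
                         data.frame(species_id = species, clade = clades[c],
                                    stringsAsFactors = FALSE))
  }
  list(pair_id = pair_name, label = as.integer(positive), clades = out,
       clade_table = clade_table,
       truth = list(label = as.integer(positive),
                    planted = if (positive) cfg$planted_pairs
                              else cfg$planted_pairs[0, ],
                    present = setNames(present, clades)))
}

#' Simulate a mediated A-B-C coupling chain
#'
#' Samples a joint Potts model over three concatenated proteins where only
#' the A-B and B-C interfaces carry direct couplings; A and C have no direct
#' coupling, so any apparent A-C signal is transitively mediated through B.
#' Each interface carries two contact pairs routed through shared mediating
#' positions on B (real bridged complexes couple via several interface
#' contacts, and the mediated second-order signal scales with the square of
#' the direct coupling — hence the tight-interface default strength).
#'
#' @param cfg A [generator_config()] (`len_a` is used for all three
#'   proteins).
#' @param n_rows Rows to sample (default: the maximum of
#'   `cfg$rows_per_clade`).
#' @param seed Integer seed.
#' @param couple Logical; `FALSE` samples the matched null with no
#'   inter-protein couplings at all.
#' @param strength Interface coupling strength (default 3).
#' @return List with the sampled state `matrix`, per-protein `len`, the
#'   interface positions (`ab`, `bc`), and `truth` marking A-C as mediated
#'   with zero direct couplings.
#' @export
make_mediated_chain <- function(cfg, n_rows = max(cfg$rows_per_clade),
                                seed = 1L, couple = TRUE, strength = 3) {
  len <- cfg$len_a
  if (len < 4L) coev_stop("mediated chain needs proteins of length >= 4")
  L <- 3L * len
  seeds <- child_seeds(seed, 3L)
  q <- cfg$q
  ## interfaces: A2-B3 / A5-B6 and B3-C4 / B6-C1 (two mediation channels)
  ab <- cbind(a = c(2L, min(5L, len)), b = c(3L, min(6L, len)))
  bc <- cbind(b = c(3L, min(6L, len)), c = c(4L, 1L))
  edges <- sample_intra_edges(rep(len, 3L), cfg$intra_coupling_density,
                              seeds[1])
  J <- rep(list(match_coupling(cfg$intra_strength, q)), nrow(edges))
  if (couple) {
    edges <- rbind(edges,
                   cbind(ab[, "a"], len + ab[, "b"]),
                   cbind(len + bc[, "b"], 2L * len + bc[, "c"]))
    J <- c(J, rep(list(match_coupling(strength, q)), nrow(ab) + nrow(bc)))
  }
  h <- with_seed(seeds[2], matrix(rnorm(L * q, sd = cfg$field_scale), L, q))
  M <- sample_potts(h, edges, J, n_rows, burn_in = cfg$burn_in,
                    thin = cfg$thin, seed = seeds[3])
  list(matrix = M, len = c(a = len, b = len, c = len),
       interface = list(ab = ab, bc = bc),
       truth = list(ac_direct_couplings = 0L, mediated = couple))
}

#' Paired alignment views of a mediated chain
#'
#' @param chain Result of [make_mediated_chain()].
#' @param drop_b If `TRUE`, returns the (A, C) paired alignment with B's
#'   columns removed; otherwise the full A-B-C alignment.
#' @return A `coev_paired` object (split after A's block).
#' @export
chain_paired <- function(chain, drop_b = TRUE) {
  len <- chain$len["a"]
  keep <- if (drop_b) c(seq_len(len), 2L * len + seq_len(len))
          else seq_len(3L * len)
  M <- chain$matrix[, keep, drop = FALSE]
  n <- nrow(M)
  species <- sprintf("s%d", seq_len(n))
  aln <- new_alignment(states_to_rows(M), paste0(species, ".ac"), species,
                       query_index = 1L, col_to_query = seq_len(ncol(M)))
  structure(
    list(aln = aln, split = unname(len),
         query_pair = c(a = "A", b = if (drop_b) "C" else "BC"),
         clade = "chain",
         subject_a = paste0(species, ".A"),
         subject_b = paste0(species, ".C"),
         map_a = seq_len(len),
         map_b = seq_len(ncol(M) - len),
         n90 = n, nf90 = n / sqrt(ncol(M))),
    class = "coev_paired")
}

#' Label-correlated missing-clade masks
#'
#' Generates per-pair per-clade missingness masks. The first clade is always
#' present. For `rho = 0` masks are independent of labels; for `rho > 0`
#' positives are missing non-query clades with probability
#' `missing_prob * (1 - rho)` and negatives with
#' `min(1, missing_prob * (1 + rho))`, so interacting pairs have
#' stochastically fewer missing clades — the phylogenetic-coverage confound.
#'
#' @param labels Binary labels (1 = positive), one per pair.
#' @param n_clades Number of clades (default 4).
#' @param rho Label-missingness correlation strength in \[0, 1\].
#' @param missing_prob Baseline missing probability (default 0.3).
#' @param seed Integer seed.
#' @return List with `mask` (logical matrix pairs x clades, `TRUE` =
#'   missing) and `strata` (contingency table of `n_missing` by label).
#' @export
make_confounded_missingness <- function(labels, n_clades = 4, rho = 0,
                                        missing_prob = 0.3, seed = 1L) {
  if (rho < 0 || rho > 1) coev_stop("rho must lie in [0, 1]")
  n <- length(labels)
  p <- ifelse(labels == 1L, missing_prob * (1 - rho),
              pmin(1, missing_prob * (1 + rho)))
  mask <- matrix(FALSE, n, n_clades)
  if (n_clades > 1) {
    u <- with_seed(seed, matrix(runif(n * (n_clades - 1L)), n))
    mask[, -1] <- u < p
  }
  n_missing <- rowSums(mask)
  list(mask = mask,
       strata = table(n_missing = n_missing, label = labels))
}
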