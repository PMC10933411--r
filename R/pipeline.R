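#' Score one protein pair in every clade
#'
#' Runs the standard per-clade chain on a [make_clade_set()]-style object (or
#' any list of `msa_a`/`msa_b`/`orth` triples): concatenate orthologous rows,
#' reduce redundancy, apply the Nf90 depth filter, fit mean-field DCA, and
#' extract the inter-protein score table. Clades that are absent, lose all
#' rows, fall below the Nf90 threshold, or are flagged self-homologous come
#' back as `NULL` (missing).
#'
#' @param clade_set A [make_clade_set()] result, or a named list of
#'   `list(msa_a, msa_b, orth)` per clade.
#' @param clade_order Clade labels defining the output order.
#' @param nf90_threshold Depth threshold (default 16).
#' @param theta,lam_frac DCA parameters.
#' @param drop_self_homologous Whether self-homologous pairs score as
#'   missing (default TRUE).
#' @return Named list over `clade_order`: score table or `NULL`.
#' @export
score_pair_by_clade <- function(clade_set, clade_order = default_clade_order(),
                                nf90_threshold = 16, theta = 0.8,
                                lam_frac = 0.5, drop_self_homologous = TRUE) {
  clades <- if (!is.null(clade_set$clades)) clade_set$clades else clade_set
  out <- setNames(vector("list", length(clade_order)), clade_order)
  for (cl in clade_order) {
    dat <- clades[[cl]]
    if (is.null(dat)) next
    paln <- concatenate_pair(dat$msa_a, dat$msa_b, dat$orth, clade = cl)
    if (is_empty_pair(paln)) next
    paln <- reduce_redundancy(paln)
    if (paln$nf90 < nf90_threshold) next
    if (drop_self_homologous &&
        shared_sequence_check(paln)$status == "self_homologous") next
    model <- mfdca(paln$aln, theta = theta, lam_frac = lam_frac)
    out[[cl]] <- inter_scores(model, paln)
  }
  out
}

#' Simulate a labelled multi-clade benchmark with features
#'
#' Generates `n_pos` interacting and `n_neg` non-interacting synthetic
#' protein pairs, each with its own Potts sample per present clade, runs the
#' full pairing + DCA pipeline on every pair, and assembles (i) the
#' integrated clade-blocked feature matrix (top-k per clade, -1 for missing
#' clades), (ii) the single-clade feature matrix (top `k * n_clades` scores
#' from the first clade only), and (iii) the benchmark table with
#' missing-clade counts and family groups.
#'
#' @param cfg A [generator_config()].
#' @param n_pos,n_neg Numbers of positive and negative pairs.
#' @param seed Master seed.
#' @param rho Label-missingness correlation (see
#'   [make_confounded_missingness()]).
#' @param k Scores per clade (default 5).
#' @param nf90_threshold Depth filter threshold.
#' @param family_reuse Probability that a protein reuses an existing family
#'   id, creating cross-pair family relationships (default 0.2).
#' @param compute_dca If `FALSE`, skips sequence simulation and DCA and
#'   returns mask-driven features only (observed entries set to +1) — enough
#'   for presence/absence analyses at a fraction of the cost.
#' @return List with `features` (n x 4k matrix), `features_single`
#'   (first-clade top-4k matrix, same shape), `bench` (data frame `pair_id`,
#'   `label`, `n_missing`, `family_group`), and `mask`.
#' @export
simulate_benchmark <- function(cfg = generator_config(), n_pos = 60,
                               n_neg = 600, seed = 1L, rho = 0, k = 5,
                               nf90_threshold = 16, family_reuse = 0.2,
                               compute_dca = TRUE) {
  n <- n_pos + n_neg
  labels <- rep(c(1L, 0L), c(n_pos, n_neg))
  clade_order <- default_clade_order()[seq_len(cfg$n_clades)]
  seeds <- child_seeds(seed, n + 3L)
  miss <- make_confounded_missingness(labels, n_clades = cfg$n_clades,
                                      rho = rho,
                                      missing_prob = cfg$missing_prob,
                                      seed = seeds[n + 1L])
  pair_ids <- sprintf("P%04d", seq_len(n))
  p <- k * cfg$n_clades
  features <- matrix(-1, n, p,
                     dimnames = list(pair_ids,
                                     paste0(rep(clade_order, each = k), "_",
                                            seq_len(k))))
  features_single <- matrix(-1, n, p,
                            dimnames = list(pair_ids,
                                            paste0(clade_order[1], "_",
                                                   seq_len(p))))
  if (compute_dca) {
    for (i in seq_len(n)) {
      cs <- make_clade_set(cfg, pair_name = pair_ids[i],
                           positive = labels[i] == 1L,
                           present = !miss$mask[i, ], seed = seeds[i],
                           clade_order = clade_order)
      tabs <- score_pair_by_clade(cs, clade_order = clade_order,
                                  nf90_threshold = nf90_threshold)
      features[i, ] <- build_feature_vector(tabs, clade_order = clade_order,
                                            k = k)
      if (!is.null(tabs[[1]]))
        features_single[i, ] <- top_k(tabs[[1]], k = p)$raw_di
    }
  } else {
    for (ci in seq_len(cfg$n_clades)) {
      cols <- (ci - 1L) * k + seq_len(k)
      features[!miss$mask[, ci], cols] <- 1
    }
    features_single[, ] <- 1
  }
  fams <- make_families(n, family_reuse, seed = seeds[n + 2L])
  bench <- data.frame(pair_id = pair_ids, label = labels,
                      n_missing = rowSums(miss$mask),
                      family_group = fams, stringsAsFactors = FALSE)
  list(features = features, features_single = features_single,
       bench = bench, mask = miss$mask)
}

make_families <- function(n, reuse, seed) {
  pool_a <- paste0("famA", seq_len(max(2L, ceiling(n * (1 - reuse)))))
  pool_b <- paste0("famB", seq_len(max(2L, ceiling(n * (1 - reuse)))))
  with_seed(seed, paste(sample(pool_a, n, replace = TRUE),
                        sample(pool_b, n, replace = TRUE), sep = "--"))
}

#' Run the full integration comparison on one simulated benchmark
#'
#' Simulates a benchmark, trains the integrated random forest (top-k per
#' clade, all clades), the single-clade random forest (top scores from one
#' clade), and computes the max-DCA baseline, all on the identical grouped
#' train/test split; reports the hold-out AUC-PR of each method.
#'
#' @inheritParams simulate_benchmark
#' @param grid Hyperparameter grid for both forests.
#' @return List with `auc_integrated`, `auc_single`, `auc_max_dca`,
#'   `prevalence`, and the underlying `sim` and fits.
#' @export
compare_integration <- function(cfg = generator_config(), n_pos = 60,
                                n_neg = 600, seed = 1L, rho = 0, k = 5,
                                grid = default_rf_grid()) {
  sim <- simulate_benchmark(cfg, n_pos = n_pos, n_neg = n_neg, seed = seed,
                            rho = rho, k = k)
  fit_int <- train_rf(sim$features, sim$bench$label, sim$bench$family_group,
                      grid = grid, seed = seed)
  fit_sgl <- train_rf(sim$features_single, sim$bench$label,
                      sim$bench$family_group, grid = grid, seed = seed)
  idx <- fit_int$test_idx
  ev_int <- evaluate_holdout(fit_int, sim$features, sim$bench$label)
  ev_sgl <- evaluate_holdout(fit_sgl, sim$features_single, sim$bench$label)
  max_scores <- apply(sim$features[idx, , drop = FALSE], 1, max)
  ev_max <- pr_curve(max_scores, sim$bench$label[idx])
  list(auc_integrated = ev_int$auc_pr, auc_single = ev_sgl$auc_pr,
       auc_max_dca = ev_max$auc_pr, prevalence = ev_int$prevalence,
       sim = sim, fit_integrated = fit_int, fit_single = fit_sgl)
}

#' Write / read feature matrices and benchmark tables as TSV
#'
#' @param features Feature matrix with pair ids as rownames.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_features <- function(features, path) {
  df <- data.frame(pair_id = rownames(features), features,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$pair_id
  m
}
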