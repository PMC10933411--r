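test_that("sequence weights follow the neighbourhood-count formula", {
  same <- matrix(1L, 3, 4)
  sw <- sequence_weights(same)
  expect_equal(sw$weights, rep(1 / 3, 3))
  expect_equal(sw$m_eff, 1)

  two <- rbind(rep(1L, 5), rep(2L, 5))
  expect_equal(sequence_weights(two)$weights, c(1, 1))
  expect_equal(sequence_weights(two)$m_eff, 2)

  four <- rbind(rep(1L, 5), rep(1L, 5), rep(2L, 5), rep(3L, 5))
  expect_equal(sequence_weights(four)$weights, c(0.5, 0.5, 1, 1))
  expect_equal(sequence_weights(four)$m_eff, 3)
})

test_that("pseudocounted frequencies match the closed form and normalize", {
  M <- matrix(1L, 2, 1)            # one column, both rows state 'A'
  w <- list(weights = c(1, 1), m_eff = 2)
  ## lambda = m_eff = 2, q = 21: f1(A) = (2/21 + 2) / 4
  fr <- frequencies(M, w, lam_frac = 0.5)
  expect_equal(fr$f1[1, 1], (2 / 21 + 2) / 4, tolerance = 1e-12)
  expect_equal(sum(fr$f1[1, ]), 1, tolerance = 1e-10)

  ## no-pseudocount limit
  fr0 <- frequencies(M, w, lam_frac = 0)
  expect_equal(fr0$f1[1, 1], 1)

  ## normalization identity on a random alignment
  M2 <- rand_state_matrix(30, 5, 21, seed = 2)
  sw2 <- sequence_weights(M2)
  fr2 <- frequencies(M2, sw2)
  expect_true(all(abs(rowSums(fr2$f1) - 1) < 1e-10))

  expect_error(frequencies(M, w, lam_frac = 1),
               class = "coev_validation_error")
})

test_that("couplings are symmetric and track statistical dependence", {
  set.seed(21)
  n <- 60
  col1 <- sample.int(21, n, TRUE)
  M <- cbind(col1, col1, sample.int(21, n, TRUE), sample.int(21, n, TRUE))
  sw <- sequence_weights(M)
  fr <- frequencies(M, sw)
  E <- fit_couplings(fr$f1, fr$f2)
  expect_equal(E, t(E), tolerance = 1e-12)
  blk <- function(i, j) E[(i - 1) * 21 + 1:21, (j - 1) * 21 + 1:21]
  ## perfectly covarying columns carry far more coupling than independent ones
  expect_gt(norm(blk(1, 2), "F"), 2 * norm(blk(3, 4), "F"))
})

test_that("direct information is zero for zero couplings and symmetric", {
  L <- 4; q <- 21
  f1 <- matrix(1 / q, L, q)
  E0 <- matrix(0, L * q, L * q)
  di0 <- direct_information(E0, f1)
  expect_true(all(abs(di0) < 1e-10))

  M <- rand_state_matrix(50, 4, 21, seed = 3, dup_rows = 5L)
  fit <- mfdca(M)
  expect_equal(fit$di_raw, t(fit$di_raw), tolerance = 1e-12)
  expect_true(all(fit$di_raw >= -1e-9))
})

test_that("the fitted two-site model reproduces the single-column marginals", {
  M <- rand_state_matrix(40, 4, 21, seed = 4)
  sw <- sequence_weights(M)
  fr <- frequencies(M, sw)
  E <- fit_couplings(fr$f1, fr$f2)
  ref <- ref_di_pair(E, fr$f1, 1, 3, q = 21, tol = 1e-8, max_iter = 2000)
  expect_true(ref$converged)
  expect_equal(rowSums(ref$P), fr$f1[1, ], tolerance = 1e-6)
  expect_equal(colSums(ref$P), fr$f1[3, ], tolerance = 1e-6)
})

test_that("inter-protein score extraction counts and remaps correctly", {
  M <- rand_state_matrix(50, 5, 21, seed = 5)
  fit <- mfdca(M)
  paln <- structure(
    list(aln = NULL, split = 2L, query_pair = c(a = "qa", b = "qb"),
         clade = "X", map_a = c(2L, 4L), map_b = c(1L, 5L, 6L)),
    class = "coev_paired")
  tab <- inter_scores(fit, paln)
  expect_equal(nrow(tab), 2L * 3L)
  ## only inter-protein pairs: column indices remapped via the query maps
  expect_setequal(unique(tab$pos_a), c(2L, 4L))
  expect_setequal(unique(tab$pos_b), c(1L, 5L, 6L))
  expect_equal(tab$raw_di[tab$pos_a == 2 & tab$pos_b == 5],
               fit$di_raw[1, 4])
})

test_that("top-k ordering is descending with lexicographic tie-breaks", {
  tab <- data.frame(
    clade = "X", query_a = "qa", query_b = "qb",
    pos_a = c(1L, 1L, 2L, 2L, 3L, 3L),
    pos_b = c(1L, 2L, 1L, 2L, 1L, 2L),
    raw_di = c(0.5, 0.9, 0.9, 0.1, 0.3, 0.2),
    apc_di = c(0.5, 0.9, 0.9, 0.1, 0.3, 0.2))
  top <- top_k(tab, k = 5)
  expect_equal(top$raw_di, sort(tab$raw_di, decreasing = TRUE)[1:5])
  ## tied maxima: (1,2) before (2,1)
  expect_equal(top$pos_a[1:2], c(1L, 2L))
  expect_equal(top_k(tab, k = 1)$raw_di, max(tab$raw_di))
  expect_error(top_k(tab[1:3, ], k = 5), class = "coev_validation_error")
})

test_that("DCA model dumps round-trip with a consistent JSON header", {
  M <- rand_state_matrix(30, 4, 21, seed = 6)
  fit <- mfdca(M)
  prefix <- file.path(withr::local_tempdir(), "model")
  write_dca_model(fit, prefix)
  header <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(header$L, 4L)
  expect_equal(header$q, 21L)
  expect_equal(header$m_eff, fit$m_eff)
  back <- read_dca_model(prefix)
  expect_equal(back$di_raw, fit$di_raw)
  expect_equal(back$couplings, fit$couplings)
})

test_that("planted couplings rank above background (rank-sum, pooled seeds)", {
  cfg <- generator_config(n_clades = 1, rows_per_clade = 150)
  planted <- c("2 1", "5 4")
  sig <- c(); bg <- c()
  for (s in 1:4) {
    cs <- make_clade_set(cfg, positive = TRUE, present = TRUE, seed = s,
                         clade_order = "X")
    tab <- score_pair_by_clade(cs, clade_order = "X")[[1]]
    is_planted <- paste(tab$pos_a, tab$pos_b) %in% planted
    sig <- c(sig, tab$raw_di[is_planted])
    bg <- c(bg, tab$raw_di[!is_planted])
  }
  p <- wilcox.test(sig, bg, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("recovery improves from very shallow to deep alignments", {
  cfg3 <- generator_config(n_clades = 1, rows_per_clade = 3, burn_in = 200)
  cfg100 <- generator_config(n_clades = 1, rows_per_clade = 100,
                             burn_in = 200)
  auc_at <- function(cfg, s) {
    cs <- make_clade_set(cfg, positive = TRUE, present = TRUE, seed = s,
                         clade_order = "X")
    d <- cs$clades[["X"]]
    paln <- concatenate_pair(d$msa_a, d$msa_b, d$orth, clade = "X")
    tab <- inter_scores(mfdca(paln$aln), paln)
    lab <- as.integer(paste(tab$pos_a, tab$pos_b) %in% c("2 1", "5 4"))
    pr_curve(tab$raw_di, lab)$auc_pr
  }
  shallow <- mean(vapply(1:3, function(s) auc_at(cfg3, s), numeric(1)))
  deep <- mean(vapply(1:3, function(s) auc_at(cfg100, s), numeric(1)))
  expect_gte(deep, shallow)
  expect_gt(deep, 2 / 36)   # well above the prevalence of planted pairs
})
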