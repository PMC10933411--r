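test_that("ortholog resolution picks the best bitscore with documented ties", {
  raw <- data.frame(
    query_id = "q1", species_id = c("s1", "s1", "s2", "s3", "s3"),
    subject_id = c("p120", "p95", "only", "tieB", "tieA"),
    bitscore = c(120, 95, 50, 70, 70), stringsAsFactors = FALSE)
  res <- resolve_orthologs(raw)
  expect_equal(res$subject_id[res$species_id == "s1"], "p120")
  expect_equal(res$subject_id[res$species_id == "s2"], "only")
  expect_equal(res$subject_id[res$species_id == "s3"], "tieA")
  expect_equal(nrow(res), 3L)

  r1 <- resolve_orthologs(raw, policy = "random", seed = 9)
  r2 <- resolve_orthologs(raw, policy = "random", seed = 9)
  expect_identical(r1, r2)

  raw$bitscore[1] <- NA
  expect_error(resolve_orthologs(raw), class = "coev_validation_error")
})

test_that("concatenation pairs orthologs by species with the query row first", {
  fx <- mk_pair_fixture(n_species = 6)
  paln <- concatenate_pair(fx$msa_a, fx$msa_b, fx$orth, clade = "X")
  expect_s3_class(paln, "coev_paired")
  expect_equal(n_rows(paln$aln), 6L)
  expect_equal(paln$aln$species[1], "sp1")       # query species first
  expect_equal(paln$split, 8L)
  expect_equal(n_cols(paln$aln), 18L)
  expect_equal(paln$query_pair, c(a = "sp1.pA", b = "sp1.pB"))

  ## B restricted to species 2..5: paired rows are the species intersection
  keep <- 2:5
  msa_b <- new_alignment(fx$msa_b$rows[keep], fx$msa_b$row_ids[keep],
                         fx$msa_b$species[keep], query_index = 1L)
  orth2 <- rbind(fx$orth,
                 data.frame(query_id = "sp2.pB",
                            species_id = fx$msa_b$species[keep],
                            subject_id = fx$msa_b$row_ids[keep],
                            bitscore = 100, stringsAsFactors = FALSE))
  inter <- concatenate_pair(fx$msa_a, msa_b, orth2)
  expect_equal(sort(inter$aln$species), paste0("sp", 2:5))

  ## swapping the inputs swaps the blocks
  rev <- concatenate_pair(fx$msa_b, fx$msa_a, fx$orth, clade = "X")
  expect_equal(substr(rev$aln$rows, rev$split + 1, 18),
               substr(paln$aln$rows, 1, paln$split))
})

test_that("empty species intersections signal a missing pair, not an error", {
  fx <- mk_pair_fixture(n_species = 4)
  msa_b <- fx$msa_b
  msa_b$species <- paste0("other", seq_len(4))
  msa_b$query_index <- 1L
  paln <- concatenate_pair(fx$msa_a, msa_b, fx$orth)
  expect_true(is_empty_pair(paln))

  dup <- fx$msa_a
  dup$species[2] <- dup$species[1]
  expect_error(concatenate_pair(dup, fx$msa_b, fx$orth),
               class = "coev_validation_error")
})

test_that("redundancy reduction enforces the identity cap and coverage floor", {
  fx <- mk_pair_fixture(n_species = 8, seed = 3)
  paln <- concatenate_pair(fx$msa_a, fx$msa_b, fx$orth, clade = "X")
  ## duplicate row 3 into row 5 and make row 6 low-coverage
  paln$aln$rows[5] <- paln$aln$rows[3]
  paln$aln$rows[6] <- paste0(substr(paln$aln$rows[6], 1, 4),
                             strrep("-", n_cols(paln$aln) - 4))
  out <- reduce_redundancy(paln)
  expect_false(paln$aln$row_ids[5] %in% out$aln$row_ids)  # duplicate gone
  expect_false(paln$aln$row_ids[6] %in% out$aln$row_ids)  # low coverage gone
  expect_equal(out$n90, n_rows(out$aln))
  expect_equal(out$nf90, out$n90 / sqrt(n_cols(out$aln)))
  ## exhaustive pairwise identity scan of the survivors
  M <- aln_matrix(out$aln)
  for (i in seq_len(nrow(M) - 1)) for (j in (i + 1):nrow(M))
    expect_lte(mean(M[i, ] == M[j, ]), 0.90)
  ## mutually dissimilar full-coverage rows are untouched
  fresh <- concatenate_pair(fx$msa_a, fx$msa_b, fx$orth)
  expect_equal(n_rows(reduce_redundancy(fresh)$aln), n_rows(fresh$aln))
})

test_that("the Nf90 filter is boundary-inclusive and monotone", {
  mk <- function(n90, L) {
    p <- structure(list(aln = mk_aln(rep(strrep("A", L), 2),
                                     ids = c("a.1", "b.2")),
                        split = L %/% 2, query_pair = c(a = "x", b = "y"),
                        clade = "X", subject_a = "a", subject_b = "b",
                        map_a = seq_len(L %/% 2), map_b = seq_len(L - L %/% 2),
                        n90 = n90, nf90 = NA_real_),
                   class = "coev_paired")
    p
  }
  keep <- nf90_filter(list(mk(160, 100), mk(50, 64)))
  expect_equal(length(keep), 1L)
  expect_equal(keep[[1]]$nf90, 16)          # 160 / sqrt(100), kept at >= 16
  expect_equal(nf90_filter(list()), list())
  ## monotonicity: survivors at a higher threshold are a subset
  palns <- lapply(c(100, 150, 200, 260), mk, L = 100)
  surv <- function(thr) vapply(nf90_filter(palns, thr),
                               function(p) p$n90, numeric(1))
  expect_true(all(surv(20) %in% surv(10)))
  expect_lte(length(surv(20)), length(surv(10)))
  ## missing n90 is a precondition violation
  bad <- mk(160, 100); bad$n90 <- NA_real_
  expect_error(nf90_filter(list(bad)), class = "coev_precondition_error")
})

test_that("shared-sequence artifacts are detected", {
  fx <- mk_pair_fixture(n_species = 4, len_a = 6, len_b = 6, seed = 5)
  paln <- concatenate_pair(fx$msa_a, fx$msa_b, fx$orth)
  expect_equal(shared_sequence_check(paln)$status, "clean")

  selfh <- paln
  selfh$subject_b[2] <- selfh$subject_a[2]
  expect_equal(shared_sequence_check(selfh)$status, "self_homologous")

  ## identical sequences under distinct ids: clean but counted
  shared <- paln
  shared$aln$rows[3] <- paste0(substr(shared$aln$rows[3], 1, 6),
                               substr(shared$aln$rows[3], 1, 6))
  chk <- shared_sequence_check(shared)
  expect_equal(chk$status, "clean")
  expect_gte(chk$n_shared_sequences, 1L)

  noids <- paln; noids$subject_a <- NULL
  expect_error(shared_sequence_check(noids), class = "coev_validation_error")
})

test_that("paired alignments round-trip through FASTA + JSON sidecar", {
  fx <- mk_pair_fixture(n_species = 5)
  paln <- reduce_redundancy(concatenate_pair(fx$msa_a, fx$msa_b, fx$orth,
                                             clade = "Firmicutes"))
  prefix <- file.path(withr::local_tempdir(), "pairX")
  write_paired(paln, prefix)
  back <- read_paired(prefix)
  expect_equal(back$aln$rows, paln$aln$rows)
  expect_equal(back$split, paln$split)
  expect_equal(back$clade, "Firmicutes")
  expect_equal(back$n90, paln$n90)
  expect_equal(back$map_b, paln$map_b)
})
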