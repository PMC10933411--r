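test_that("redundant query pairs drop the shorter protein", {
  base <- rand_seq(120, seed = 11)
  ## ~97% identical over 110/120 of the longer protein: redundant
  short <- substr(base, 1, 110)
  substr(short, 5, 5) <- "W"; substr(short, 50, 50) <- "W"
  res <- deduplicate_queries(c(long = base, short = short))
  expect_equal(names(res$retained), "long")
  expect_equal(res$dropped, "short")
})

test_that("identity exactly at the threshold keeps both proteins", {
  base <- rand_seq(100, seed = 12)
  var <- base
  ## five substitutions -> identity exactly 95/100, not > 0.95
  for (p in c(3, 20, 40, 60, 80)) {
    cur <- substr(var, p, p)
    substr(var, p, p) <- if (cur == "W") "Y" else "W"
  }
  res <- deduplicate_queries(c(a = base, b = var))
  expect_equal(length(res$retained), 2L)
  expect_equal(res$dropped, character(0))
})

test_that("unrelated proteins and empty input pass through deduplication", {
  res <- deduplicate_queries(c(a = rand_seq(80, 1), b = rand_seq(80, 2)))
  expect_equal(length(res$retained), 2L)
  empty <- deduplicate_queries(character(0))
  expect_equal(empty$retained, character(0))
})

test_that("seed tier selection picks the most stringent qualifying tier", {
  ## 30 of 100 pass tier a: 30 > 25 = 25% of 100
  orth <- data.frame(coverage = c(rep(0.9, 30), rep(0.6, 70)),
                     identity = c(rep(0.7, 30), rep(0.3, 70)))
  sel <- select_seed_tier(orth)
  expect_equal(sel$tier$tier, "a")
  expect_equal(sum(sel$selected), 30)
  expect_false(sel$warning_flag)

  ## 10 pass tier a, 40 pass tier b -> tier b
  orth2 <- data.frame(coverage = c(rep(0.9, 10), rep(0.7, 30), rep(0.55, 60)),
                      identity = c(rep(0.6, 10), rep(0.45, 30), rep(0.3, 60)))
  sel2 <- select_seed_tier(orth2)
  expect_equal(sel2$tier$tier, "b")
  expect_equal(sum(sel2$selected), 40)

  ## 4 orthologs all passing tier a: 4 > 1 = 25% of 4
  orth3 <- data.frame(coverage = rep(0.95, 4), identity = rep(0.9, 4))
  expect_equal(select_seed_tier(orth3)$tier$tier, "a")

  ## nothing qualifies -> tier c subset with a warning flag
  orth4 <- data.frame(coverage = rep(0.55, 4), identity = rep(0.3, 4))
  sel4 <- select_seed_tier(orth4, group_size = 100)
  expect_equal(sel4$tier$tier, "c")
  expect_true(sel4$warning_flag)

  expect_error(select_seed_tier(data.frame()), class = "coev_validation_error")
})

test_that("query gap columns are removed and positions remapped", {
  aln <- mk_aln(c("A-C", "AGC"))
  out <- drop_query_gap_columns(aln)
  expect_equal(out$rows, c("AC", "AC"))
  expect_equal(out$col_to_query, c(1L, 2L))

  nogap <- mk_aln(c("ACD", "ACE"))
  expect_equal(drop_query_gap_columns(nogap)$rows, nogap$rows)

  allgap <- mk_aln(c("---", "ACD"))
  expect_warning(out2 <- drop_query_gap_columns(allgap),
                 class = "coev_warning")
  expect_equal(n_cols(out2), 0L)

  noquery <- mk_aln(c("AC", "AD"), query = NA_integer_)
  expect_error(drop_query_gap_columns(noquery),
               class = "coev_precondition_error")
})

test_that("row gap filter is strict and never removes the query", {
  aln <- mk_aln(c("ACDEFGHIKL", "AC--------", "ACDEF-----"))
  out <- filter_gappy_rows(aln)  # 80% gaps dropped, exactly 50% kept
  expect_equal(out$row_ids, c("sp1.p", "sp3.p"))
  ## a gappy query row survives
  qgap <- mk_aln(c("A---", "ACDE"), query = 1L)
  expect_equal(n_rows(filter_gappy_rows(qgap)), 2L)
  ## gap-free alignment unchanged
  clean <- mk_aln(c("ACDE", "ACDF"))
  expect_equal(filter_gappy_rows(clean)$rows, clean$rows)
})

test_that("column gap filter is inclusive at the threshold", {
  ## column 2 has 2/4 = 50% gaps (removed, inclusive rule); column 3 25%
  aln <- mk_aln(c("A-CD", "A-CD", "AGCD", "AG-D"))
  out <- filter_gappy_columns(aln)
  expect_equal(n_cols(out), 3L)
  expect_equal(out$rows[1], "ACD")
  clean <- mk_aln(c("ACDE", "ACDF"))
  expect_equal(filter_gappy_columns(clean)$rows, clean$rows)
})

test_that("filters are idempotent and compose with correct position maps", {
  set.seed(41)
  rows <- replicate(12, paste(sample(c(AA20, "-", "-"), 30, TRUE),
                              collapse = ""))
  rows[1] <- paste(sample(c(AA20, "-"), 30, TRUE, prob = c(rep(1, 20), 5)),
                   collapse = "")
  aln <- mk_aln(rows)
  chain <- function(a) filter_gappy_columns(filter_gappy_rows(
    drop_query_gap_columns(a)))
  once <- chain(aln)
  twice <- chain(once)
  expect_equal(twice$rows, once$rows)
  expect_equal(twice$col_to_query, once$col_to_query)
  ## retained columns map to valid, strictly increasing query positions
  expect_true(all(diff(once$col_to_query) > 0))
  expect_true(all(once$col_to_query >= 1))
  qlen <- sum(strsplit(aln$rows[1], "")[[1]] != "-")
  expect_true(all(once$col_to_query <= qlen))
})

test_that("gap filters match an independent brute-force scan", {
  set.seed(42)
  rows <- replicate(15, paste(sample(c(AA20, "-", "-", "-"), 24, TRUE),
                              collapse = ""))
  aln <- mk_aln(rows, query = NA_integer_)
  ch <- do.call(rbind, strsplit(rows, ""))
  keep_rows <- which(rowMeans(ch == "-") <= 0.5)
  out_r <- filter_gappy_rows(aln)
  expect_equal(n_rows(out_r), length(keep_rows))
  ch2 <- ch[keep_rows, , drop = FALSE]
  keep_cols <- sum(colMeans(ch2 == "-") < 0.5)
  expect_equal(n_cols(filter_gappy_columns(out_r)), keep_cols)
})

test_that("quality metrics match closed forms", {
  same <- mk_aln(c("ACDE", "ACDE", "ACDE"))
  qm <- quality_metrics(same)
  expect_equal(qm$mean_col_entropy, 0)
  expect_equal(qm$mean_pairwise_distance, 0)
  expect_equal(qm$n_rows, 3L)

  ## one column split 50/50 between two residues: entropy 1 bit
  half <- mk_aln(c("A", "A", "C", "C"))
  expect_equal(quality_metrics(half)$mean_col_entropy, 1)

  ## column half gaps half A: gap ratio 0.5 (and entropy 1 bit, gap = state)
  gaps <- mk_aln(c("A", "-", "A", "-"))
  expect_equal(quality_metrics(gaps)$mean_col_gap_ratio, 0.5)

  expect_error(quality_metrics(mk_aln(character(0), character(0),
                                      character(0), query = NA_integer_)),
               class = "coev_validation_error")
})

test_that("downsampling is uniform, seeded, and caps at current depth", {
  set.seed(7)
  rows <- replicate(200, paste(sample(AA20, 10, TRUE), collapse = ""))
  aln <- mk_aln(rows)
  sub <- downsample_rows(aln, 100, seed = 5)
  expect_equal(n_rows(sub), 100L)
  expect_true(all(sub$row_ids %in% aln$row_ids))
  expect_equal(downsample_rows(aln, 100, seed = 5)$row_ids, sub$row_ids)
  expect_equal(n_cols(sub), n_cols(aln))
  small <- mk_aln(rows[1:50])
  expect_identical(downsample_rows(small, 300, seed = 1), small)
  expect_error(downsample_rows(aln, 0), class = "coev_validation_error")
})

test_that("downsampled quality metrics are unbiased for the full alignment", {
  set.seed(8)
  rows <- replicate(40, paste(sample(c(AA20, "-", "-"), 16, TRUE),
                              collapse = ""))
  aln <- mk_aln(rows, query = NA_integer_)
  full <- quality_metrics(aln)
  gaps <- vapply(1:120, function(s)
    quality_metrics(downsample_rows(aln, 15, seed = s))$mean_col_gap_ratio,
    numeric(1))
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - full$mean_col_gap_ratio), 5 * se + 1e-3)
})
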