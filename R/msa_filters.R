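#' Remove redundant query proteins
#'
#' Proteins with more than `id_threshold` pairwise identity over at least
#' `cov_threshold` of the alignment span are treated as redundant and the
#' shorter member of each redundant pair is dropped. Identity is computed
#' from an ends-free pairwise alignment as matches over matched (aligned)
#' columns; coverage is the aligned span over the longer sequence length.
#'
#' @param seqs Named character vector of ungapped query protein sequences.
#' @param id_threshold Identity above which (strictly) a pair is redundant.
#' @param cov_threshold Minimum fraction of the alignment length covered.
#' @return List with `retained` (named character vector) and `dropped`
#'   (character vector of ids).
#' @export
deduplicate_queries <- function(seqs, id_threshold = 0.95, cov_threshold = 0.90) {
  if (length(seqs) == 0L)
    return(list(retained = character(0), dropped = character(0)))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    coev_stop("seqs must have unique names")
  ids <- names(seqs)
  alive <- rep(TRUE, length(seqs))
  data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  for (i in seq_along(seqs)) {
    if (!alive[i]) next
    for (j in seq_along(seqs)) {
      if (j <= i || !alive[j] || !alive[i]) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
        type = "overlap", substitutionMatrix = submat,
        gapOpening = 10, gapExtension = 0.5)
      nmat <- Biostrings::nmatch(pa)
      nmis <- Biostrings::nmismatch(pa)
      aligned_cols <- nmat + nmis
      if (aligned_cols == 0L) next
      identity <- nmat / aligned_cols
      coverage <- aligned_cols / max(nchar(seqs[[i]]), nchar(seqs[[j]]))
      if (identity > id_threshold && coverage >= cov_threshold) {
        ## drop the shorter protein; ties broken by dropping the later id
        drop <- if (nchar(seqs[[i]]) < nchar(seqs[[j]])) i
                else if (nchar(seqs[[j]]) < nchar(seqs[[i]])) j
                else if (ids[i] < ids[j]) j else i
        alive[drop] <- FALSE
      }
    }
  }
  list(retained = seqs[alive], dropped = ids[!alive])
}

#' Seed-alignment stringency tiers
#'
#' The three stringency tiers used to pick seed sequences for profile
#' construction, from most to least stringent:
#' tier a (coverage > 0.8, identity > 0.55), tier b (> 0.65, > 0.4),
#' tier c (> 0.5, > 0.25).
#'
#' @return Data frame of tiers with `min_coverage` and `min_identity`.
#' @export
seed_tiers <- function() {
  data.frame(tier = c("a", "b", "c"),
             min_coverage = c(0.8, 0.65, 0.5),
             min_identity = c(0.55, 0.4, 0.25),
             stringsAsFactors = FALSE)
}

#' Select the seed tier for an orthologous group
#'
#' Keeps orthologs passing the most stringent tier that still selects more
#' than `min(2500, 0.25 * group_size)` orthologs. If no tier qualifies, tier
#' c's subset is returned with `warning_flag = TRUE`.
#'
#' @param orthologs Data frame with columns `coverage` and `identity`
#'   (fractions in \[0, 1\] relative to the query).
#' @param group_size Total size of the orthologous group (defaults to
#'   `nrow(orthologs)`).
#' @return List with `tier` (one-row data frame), `selected` (logical vector
#'   over `orthologs` rows) and `warning_flag`.
#' @export
select_seed_tier <- function(orthologs, group_size = nrow(orthologs)) {
  if (is.null(orthologs) || nrow(orthologs) == 0L)
    coev_stop("empty ortholog list")
  if (any(orthologs$coverage < 0 | orthologs$coverage > 1) ||
      any(orthologs$identity < 0 | orthologs$identity > 1))
    coev_stop("coverage and identity must lie in [0, 1]")
  tiers <- seed_tiers()
  need <- min(2500, 0.25 * group_size)
  for (t in seq_len(nrow(tiers))) {
    sel <- orthologs$coverage > tiers$min_coverage[t] &
           orthologs$identity > tiers$min_identity[t]
    if (sum(sel) > need)
      return(list(tier = tiers[t, ], selected = sel, warning_flag = FALSE))
  }
  sel <- orthologs$coverage > tiers$min_coverage[3] &
         orthologs$identity > tiers$min_identity[3]
  list(tier = tiers[3, ], selected = sel, warning_flag = TRUE)
}

#' Drop columns that are gaps in the query row
#'
#' Removes every column where the query row holds a gap, since such columns
#' cannot be mapped back to query-protein residues; `col_to_query` is updated
#' so each retained column maps to its 1-based query position.
#'
#' @param aln Alignment with a query row.
#' @return Filtered alignment.
#' @export
drop_query_gap_columns <- function(aln) {
  if (is.na(aln$query_index))
    coev_stop("alignment has no query row", "coev_precondition_error")
  qchars <- strsplit(aln$rows[aln$query_index], "")[[1]]
  keep <- qchars != "-"
  if (!any(keep)) {
    coev_warn("query row is all gaps; alignment reduced to zero columns")
    out <- subset_cols(aln, keep)
    return(out)
  }
  out <- subset_cols(aln, keep)
  out$col_to_query <- seq_len(sum(keep))
  out
}

#' Remove gap-rich rows
#'
#' Rows whose gap fraction strictly exceeds `max_gap_frac` are removed; the
#' query row is never removed.
#'
#' @param aln Alignment.
#' @param max_gap_frac Maximum tolerated gap fraction (default 0.5).
#' @return Filtered alignment.
#' @export
filter_gappy_rows <- function(aln, max_gap_frac = 0.5) {
  if (n_rows(aln) == 0L) return(aln)
  M <- aln_matrix(aln)
  gap_frac <- rowMeans(M == COEV_Q)
  keep <- gap_frac <= max_gap_frac
  if (!is.na(aln$query_index)) keep[aln$query_index] <- TRUE
  subset_rows(aln, which(keep))
}

#' Remove gap-rich columns
#'
#' Columns whose gap fraction reaches `max_gap_frac` (inclusive) are removed
#' and `col_to_query` is updated accordingly.
#'
#' @inheritParams filter_gappy_rows
#' @return Filtered alignment.
#' @export
filter_gappy_columns <- function(aln, max_gap_frac = 0.5) {
  if (n_rows(aln) == 0L || n_cols(aln) == 0L) return(aln)
  M <- aln_matrix(aln)
  gap_frac <- colMeans(M == COEV_Q)
  subset_cols(aln, gap_frac < max_gap_frac)
}

#' Alignment quality metrics
#'
#' Per-alignment summary statistics: the mean column gap fraction, the mean
#' column Shannon entropy in bits over the 21-state alphabet (gap counted as
#' a state), and the mean pairwise distance (1 - identity over all columns,
#' gap-gap positions counting as matches).
#'
#' @param aln Non-empty alignment.
#' @return List with `n_rows`, `n_cols`, `mean_col_gap_ratio`,
#'   `mean_col_entropy`, `mean_pairwise_distance`.
#' @export
quality_metrics <- function(aln) {
  if (n_rows(aln) == 0L || n_cols(aln) == 0L)
    coev_stop("quality metrics need a non-empty alignment")
  M <- aln_matrix(aln)
  n <- nrow(M)
  gap_ratio <- mean(colMeans(M == COEV_Q))
  ent <- apply(M, 2, function(col) {
    p <- tabulate(col, COEV_Q) / n
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  mpd <- if (n < 2L) 0 else {
    idm <- identity_matrix(M)
    mean(1 - idm[upper.tri(idm)])
  }
  list(n_rows = n, n_cols = ncol(M),
       mean_col_gap_ratio = gap_ratio,
       mean_col_entropy = mean(ent),
       mean_pairwise_distance = mpd)
}

#' Down-sample alignment rows
#'
#' Samples exactly `n` rows uniformly without replacement (deterministic
#' under `seed`); columns are untouched and no realignment is performed. If
#' the alignment already has `n` rows or fewer, it is returned unchanged.
#'
#' @param aln Alignment.
#' @param n Target row count (>= 1).
#' @param seed Integer seed.
#' @return Down-sampled alignment.
#' @export
downsample_rows <- function(aln, n, seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1L)
    coev_stop("down-sample size must be >= 1")
  if (n >= n_rows(aln)) return(aln)
  idx <- sort(with_seed(seed, sample.int(n_rows(aln), n)))
  subset_rows(aln, idx)
}

#' Write quality metrics for a set of alignments as TSV
#'
#' @param metrics_list Named list of [quality_metrics()] results.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_quality_metrics <- function(metrics_list, path) {
  df <- do.call(rbind, lapply(metrics_list, as.data.frame))
  df <- cbind(alignment = names(metrics_list), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
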