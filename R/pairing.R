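#' Resolve multi-valued ortholog assignments
#'
#' Collapses an ortholog table with possibly several paralogous subjects per
#' (query, species) cell to exactly one subject. Under the `best-score`
#' policy the subject with the highest similarity score (bitscore) wins, ties
#' broken by lexicographically smaller subject id; under `random` one subject
#' is chosen seed-deterministically.
#'
#' @param raw Data frame with columns `query_id`, `species_id`, `subject_id`
#'   and (for `best-score`) `bitscore`.
#' @param policy `"best-score"` or `"random"`.
#' @param seed Seed for the `random` policy.
#' @return Data frame with one row per (query_id, species_id).
#' @export
resolve_orthologs <- function(raw, policy = c("best-score", "random"), seed = NULL) {
  policy <- match.arg(policy)
  need <- c("query_id", "species_id", "subject_id")
  if (!all(need %in% names(raw)))
    coev_stop("ortholog table needs columns query_id, species_id, subject_id")
  key <- paste(raw$query_id, raw$species_id, sep = "\r")
  if (policy == "best-score") {
    if (is.null(raw$bitscore) || anyNA(raw$bitscore))
      coev_stop("best-score policy requires a complete bitscore column")
    ord <- order(key, -raw$bitscore, raw$subject_id)
  } else {
    u <- with_seed(seed, runif(nrow(raw)))
    ord <- order(key, u)
  }
  out <- raw[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), need, drop = FALSE]
  rownames(out) <- NULL
  out
}

lookup_subject <- function(orth, query, species) {
  hit <- orth$query_id == query & orth$species_id == species
  if (!any(hit)) NA_character_ else orth$subject_id[which(hit)[1]]
}

#' Build a paired alignment for one query protein pair
#'
#' Concatenates, per species present in both single MSAs, the resolved
#' ortholog row of protein A with that of protein B. The query species row
#' (when available on both sides) is placed first. An empty species
#' intersection is not an error: it yields an empty paired alignment that
#' downstream feature assembly treats as a missing clade.
#'
#' @param msa_a,msa_b Single-protein alignments with species labels and query
#'   rows.
#' @param orth Resolved ortholog table ([resolve_orthologs()]).
#' @param clade Clade label to record.
#' @return A `coev_paired` object: the concatenated alignment plus `split`
#'   (last column of the A block), `query_pair`, per-row subject ids for both
#'   sides, the two column-to-query maps, and (after
#'   [reduce_redundancy()]) `n90`/`nf90`.
#' @export
concatenate_pair <- function(msa_a, msa_b, orth, clade = NA_character_) {
  for (m in list(msa_a, msa_b)) {
    if (is.na(m$query_index))
      coev_stop("both single MSAs must carry a query row", "coev_precondition_error")
    if (anyDuplicated(m$species))
      coev_stop("species repeated within one single MSA")
  }
  query_a <- msa_a$row_ids[msa_a$query_index]
  query_b <- msa_b$row_ids[msa_b$query_index]
  common <- intersect(msa_a$species, msa_b$species)
  rows_a <- match(common, msa_a$species)
  rows_b <- match(common, msa_b$species)
  sub_a <- msa_a$row_ids[rows_a]
  sub_b <- msa_b$row_ids[rows_b]
  ## keep only species whose rows are the resolved orthologs for both queries
  ok <- vapply(seq_along(common), function(k) {
    ra <- lookup_subject(orth, query_a, common[k])
    rb <- lookup_subject(orth, query_b, common[k])
    identical(ra, sub_a[k]) && identical(rb, sub_b[k])
  }, logical(1))
  common <- common[ok]; rows_a <- rows_a[ok]; rows_b <- rows_b[ok]
  sub_a <- sub_a[ok]; sub_b <- sub_b[ok]
  ## query species first, remaining rows in A's species order
  qs <- msa_a$species[msa_a$query_index]
  ord <- order(common != qs)
  common <- common[ord]; rows_a <- rows_a[ord]; rows_b <- rows_b[ord]
  sub_a <- sub_a[ord]; sub_b <- sub_b[ord]
  rows <- paste0(msa_a$rows[rows_a], msa_b$rows[rows_b])
  aln <- new_alignment(rows, paste(sub_a, sub_b, sep = "|"), common,
                       query_index = if (length(common) && common[1] == qs) 1L
                                     else NA_integer_,
                       col_to_query = if (length(rows)) rep(NA_integer_, nchar(rows[1]))
                                      else NULL)
  structure(
    list(aln = aln, split = n_cols(msa_a),
         query_pair = c(a = query_a, b = query_b), clade = clade,
         subject_a = sub_a, subject_b = sub_b,
         map_a = aln_map_or_identity(msa_a), map_b = aln_map_or_identity(msa_b),
         n90 = NA_real_, nf90 = NA_real_),
    class = "coev_paired")
}

aln_map_or_identity <- function(msa) {
  if (is.null(msa$col_to_query)) seq_len(n_cols(msa)) else msa$col_to_query
}

#' @export
print.coev_paired <- function(x, ...) {
  cat(sprintf("<coev_paired> %s x %s [%s] %d rows, %d+%d cols, nf90=%s\n",
              x$query_pair["a"], x$query_pair["b"],
              ifelse(is.na(x$clade), "?", x$clade),
              n_rows(x$aln), x$split, n_cols(x$aln) - x$split,
              ifelse(is.na(x$nf90), "NA", sprintf("%.2f", x$nf90))))
  invisible(x)
}

#' @rdname concatenate_pair
#' @param paln A paired alignment.
#' @export
is_empty_pair <- function(paln) n_rows(paln$aln) == 0L

subset_pair_rows <- function(paln, idx) {
  paln$aln <- subset_rows(paln$aln, idx)
  paln$subject_a <- paln$subject_a[idx]
  paln$subject_b <- paln$subject_b[idx]
  paln
}

#' Greedy redundancy reduction of a paired alignment
#'
#' Mirrors the master-sequence filtering mode of HH-suite style tools: the
#' first (query) row is always kept; rows with non-gap coverage below
#' `min_cov` percent are dropped; then, scanning in row order, any row whose
#' identity to an already-kept row exceeds `max_id` percent is dropped.
#' Identity is matches over all paired columns with gap-gap counting as a
#' match. Records `n90` (surviving rows) and `nf90 = n90 / sqrt(L)`.
#'
#' @param paln Paired alignment.
#' @param max_id Maximum pairwise identity, percent (default 90).
#' @param min_cov Minimum row coverage, percent (default 75).
#' @return Filtered paired alignment with `n90` and `nf90` set.
#' @export
reduce_redundancy <- function(paln, max_id = 90, min_cov = 75) {
  if (is_empty_pair(paln)) {
    paln$n90 <- 0; paln$nf90 <- 0
    return(paln)
  }
  M <- aln_matrix(paln$aln)
  cov <- 1 - rowMeans(M == COEV_Q)
  keep_cov <- cov >= min_cov / 100
  keep_cov[1] <- TRUE
  idx <- which(keep_cov)
  M2 <- M[idx, , drop = FALSE]
  idm <- identity_matrix(M2)
  kept <- 1L
  for (r in seq_along(idx)[-1]) {
    if (all(idm[r, kept] <= max_id / 100)) kept <- c(kept, r)
  }
  out <- subset_pair_rows(paln, idx[kept])
  out$n90 <- length(kept)
  out$nf90 <- out$n90 / sqrt(n_cols(out$aln))
  out
}

#' Filter paired alignments by depth (Nf90)
#'
#' Retains paired alignments with `n90 / sqrt(L) >= threshold` (inclusive),
#' where `n90` is the row count after [reduce_redundancy()] and `L` the
#' paired alignment length.
#'
#' @param palns List of paired alignments with `n90` computed.
#' @param threshold Nf90 threshold (default 16).
#' @return The surviving sublist, each element with `nf90` recorded.
#' @export
nf90_filter <- function(palns, threshold = 16) {
  if (length(palns) == 0L) return(palns)
  out <- lapply(palns, function(p) {
    if (is.na(p$n90))
      coev_stop("nf90_filter requires n90 (run reduce_redundancy first)",
                "coev_precondition_error")
    p$nf90 <- p$n90 / sqrt(n_cols(p$aln))
    p
  })
  out[vapply(out, function(p) p$nf90 >= threshold, logical(1))]
}

#' Detect shared-sequence artifacts in a paired alignment
#'
#' A pair is flagged `self_homologous` when any row carries the identical
#' subject protein id on both sides of the pairing (the same protein claimed
#' as ortholog of both queries); such pairs are removed from benchmarks
#' because predicting interactions between homologs is trivial. The number
#' of rows whose two sides carry an identical (ungapped) sequence is also
#' reported, supporting shared-sequence removal controls.
#'
#' @param paln Paired alignment.
#' @return List with `status` (`"clean"` or `"self_homologous"`) and
#'   `n_shared_sequences`.
#' @export
shared_sequence_check <- function(paln) {
  if (is.null(paln$subject_a) || is.null(paln$subject_b) ||
      anyNA(paln$subject_a) || anyNA(paln$subject_b))
    coev_stop("paired alignment lacks per-row subject ids")
  same_id <- any(paln$subject_a == paln$subject_b)
  strip <- function(s) gsub("-", "", s, fixed = TRUE)
  side_a <- strip(substr(paln$aln$rows, 1L, paln$split))
  side_b <- strip(substr(paln$aln$rows, paln$split + 1L, n_cols(paln$aln)))
  n_shared <- sum(side_a == side_b & nchar(side_a) > 0L)
  list(status = if (same_id) "self_homologous" else "clean",
       n_shared_sequences = n_shared)
}

#' Write / read a paired alignment (FASTA + JSON sidecar)
#'
#' @param paln Paired alignment.
#' @param prefix Path prefix; writes `<prefix>.fasta` and `<prefix>.json`.
#' @return The prefix, invisibly (writer); a `coev_paired` (reader).
#' @export
write_paired <- function(paln, prefix) {
  write_alignment(paln$aln, paste0(prefix, ".fasta"))
  meta <- list(split = paln$split, clade = paln$clade,
               query_pair = as.list(paln$query_pair),
               subject_a = paln$subject_a, subject_b = paln$subject_b,
               species = paln$aln$species,
               map_a = paln$map_a, map_b = paln$map_b,
               n90 = paln$n90, nf90 = paln$nf90)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_paired
#' @export
read_paired <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  seqs <- Biostrings::readBStringSet(paste0(prefix, ".fasta"))
  aln <- new_alignment(as.character(seqs), names(seqs), meta$species,
                       query_index = 1L,
                       col_to_query = rep(NA_integer_, nchar(as.character(seqs)[1])))
  structure(
    list(aln = aln, split = meta$split, clade = meta$clade,
         query_pair = c(a = meta$query_pair$a, b = meta$query_pair$b),
         subject_a = meta$subject_a, subject_b = meta$subject_b,
         map_a = meta$map_a, map_b = meta$map_b,
         n90 = ifelse(is.null(meta$n90), NA_real_, meta$n90),
         nf90 = ifelse(is.null(meta$nf90), NA_real_, meta$nf90)),
    class = "coev_paired")
}
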