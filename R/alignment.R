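#' Alignment objects
#'
#' An `Alignment` is the package's in-memory model of a protein multiple
#' sequence alignment: equal-length residue strings over the 20 amino acids
#' plus gap `-` (unknown residues such as `X` are treated as gaps in all
#' statistics), one species label per row, an optional query row, and a
#' per-column map to 1-based positions in the original (ungapped) query
#' protein.
#'
#' @param rows Character vector of equal-length aligned sequences.
#' @param row_ids Unique sequence identifiers, one per row.
#' @param species Species identifier per row.
#' @param query_index Row index of the query sequence, or `NA` if none.
#' @param col_to_query Integer vector, one entry per column, giving the
#'   1-based position of that column in the ungapped query protein (`NA`
#'   where undefined). Defaults to `1:n_cols` when a query row without gaps
#'   is present.
#' @return An object of class `coev_alignment`.
#' @export
new_alignment <- function(rows, row_ids, species, query_index = NA_integer_,
                          col_to_query = NULL) {
  rows <- toupper(as.character(rows))
  if (length(rows) == 0L) {
    widths <- integer(0)
  } else {
    widths <- nchar(rows)
    if (length(unique(widths)) > 1L)
      coev_stop("alignment rows have unequal lengths", "coev_format_error")
  }
  if (length(row_ids) != length(rows))
    coev_stop("row_ids must match number of rows")
  if (anyDuplicated(row_ids))
    coev_stop("duplicate row ids in alignment")
  if (length(species) != length(rows))
    coev_stop("species must be defined for every row")
  n_cols <- if (length(rows)) widths[1] else 0L
  if (!is.na(query_index)) {
    query_index <- as.integer(query_index)
    if (query_index < 1L || query_index > length(rows))
      coev_stop("query_index out of range")
    if (is.null(col_to_query)) {
      qchars <- strsplit(rows[query_index], "")[[1]]
      col_to_query <- rep(NA_integer_, n_cols)
      nongap <- qchars != "-" & qchars != "."
      col_to_query[nongap] <- seq_len(sum(nongap))
    }
  }
  if (!is.null(col_to_query) && length(col_to_query) != n_cols)
    coev_stop("col_to_query must have one entry per column")
  structure(
    list(rows = rows, row_ids = as.character(row_ids),
         species = as.character(species),
         query_index = query_index,
         col_to_query = if (is.null(col_to_query)) NULL else as.integer(col_to_query)),
    class = "coev_alignment")
}

#' @export
print.coev_alignment <- function(x, ...) {
  cat(sprintf("<coev_alignment> %d rows x %d cols", n_rows(x), n_cols(x)))
  if (!is.na(x$query_index))
    cat(sprintf(", query row %d (%s)", x$query_index, x$row_ids[x$query_index]))
  cat("\n")
  invisible(x)
}

#' @rdname new_alignment
#' @param aln An alignment.
#' @export
n_rows <- function(aln) length(aln$rows)

#' @rdname new_alignment
#' @export
n_cols <- function(aln) if (length(aln$rows)) nchar(aln$rows[1]) else 0L

#' Integer residue matrix of an alignment
#'
#' Encodes rows as integers 1..21 in the order `ACDEFGHIKLMNPQRSTVWY-`;
#' anything outside the alphabet (`X`, `.`, rare ambiguity codes) maps to the
#' gap state 21.
#'
#' @param aln An alignment.
#' @return Integer matrix with `n_rows(aln)` rows.
#' @export
aln_matrix <- function(aln) {
  if (n_rows(aln) == 0L)
    return(matrix(integer(0), nrow = 0, ncol = n_cols(aln)))
  chars <- strsplit(aln$rows, "")
  m <- matrix(match(unlist(chars), COEV_ALPHABET),
              nrow = n_rows(aln), byrow = TRUE)
  m[is.na(m)] <- COEV_Q
  m
}

## One-hot encoding: n x (L*q) binary matrix, column (i-1)*q + a.
one_hot <- function(M, q = COEV_Q) {
  n <- nrow(M); L <- ncol(M)
  X <- matrix(0, n, L * q)
  if (n > 0L && L > 0L)
    X[cbind(rep(seq_len(n), L),
            (rep(seq_len(L), each = n) - 1L) * q + as.vector(M))] <- 1
  X
}

## Fraction-identical matrix between all row pairs (gap-gap counts as match).
identity_matrix <- function(M, q = COEV_Q) {
  L <- ncol(M)
  X <- one_hot(M, q)
  tcrossprod(X) / L
}

subset_rows <- function(aln, idx) {
  qi <- aln$query_index
  new_qi <- if (!is.na(qi) && qi %in% idx) match(qi, idx) else NA_integer_
  new_alignment(aln$rows[idx], aln$row_ids[idx], aln$species[idx],
                query_index = new_qi, col_to_query = aln$col_to_query)
}

subset_cols <- function(aln, keep) {
  rows <- vapply(strsplit(aln$rows, ""),
                 function(ch) paste(ch[keep], collapse = ""), character(1))
  new_alignment(rows, aln$row_ids, aln$species,
                query_index = aln$query_index,
                col_to_query = if (is.null(aln$col_to_query)) NULL
                               else aln$col_to_query[keep])
}

#' Read an alignment from disk
#'
#' Reads aligned FASTA or Stockholm alignments (via Biostrings) into an
#' [new_alignment()] object. Species labels default to the prefix of each
#' sequence id before the first `.` (the common `taxid.protein` convention);
#' a sidecar TSV with columns `seq_id`, `species_id` overrides this.
#'
#' @param path File path.
#' @param format `"aligned-fasta"` or `"stockholm"`.
#' @param species_map Optional data frame (`seq_id`, `species_id`) or path to
#'   such a TSV.
#' @param query_id Optional row id to mark as the query row.
#' @return A `coev_alignment`.
#' @export
read_alignment <- function(path, format = c("aligned-fasta", "stockholm"),
                           species_map = NULL, query_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    coev_stop(sprintf("file not found: %s", path), "coev_format_error")
  if (format == "aligned-fasta") {
    seqs <- tryCatch(Biostrings::readBStringSet(path),
                     error = function(e) coev_stop(
                       sprintf("cannot parse FASTA %s: %s", path, conditionMessage(e)),
                       "coev_format_error"))
    rows <- as.character(seqs)
    ids <- names(seqs)
  } else {
    ma <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = "stockholm"),
                   error = function(e) coev_stop(
                     sprintf("cannot parse Stockholm %s: %s", path, conditionMessage(e)),
                     "coev_format_error"))
    rows <- as.character(ma)
    ids <- names(rows) %||% rownames(ma)
  }
  ids <- sub("\\s.*$", "", ids)
  rows <- gsub("\\.", "-", toupper(rows))
  if (length(rows) && length(unique(nchar(rows))) > 1L)
    coev_stop("ragged alignment rows", "coev_format_error")
  species <- species_from_ids(ids, species_map)
  qi <- if (is.null(query_id)) NA_integer_ else match(query_id, ids)
  new_alignment(rows, ids, species, query_index = qi)
}

species_from_ids <- function(ids, species_map = NULL) {
  if (!is.null(species_map)) {
    if (is.character(species_map) && length(species_map) == 1L)
      species_map <- read.delim(species_map, stringsAsFactors = FALSE)
    sp <- species_map$species_id[match(ids, species_map$seq_id)]
    if (anyNA(sp))
      coev_stop("species map does not cover all sequence ids")
    return(sp)
  }
  sub("\\..*$", "", ids)
}

#' Write an alignment to disk
#'
#' @inheritParams read_alignment
#' @param aln An alignment.
#' @return The path, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("aligned-fasta", "stockholm")) {
  format <- match.arg(format)
  if (format == "aligned-fasta") {
    set <- Biostrings::BStringSet(setNames(aln$rows, aln$row_ids))
    Biostrings::writeXStringSet(set, path)
  } else {
    pad <- max(nchar(aln$row_ids), 0L)
    lines <- c("# STOCKHOLM 1.0",
               sprintf(paste0("%-", pad, "s %s"), aln$row_ids, aln$rows),
               "//")
    writeLines(lines, path)
  }
  invisible(path)
}
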