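## Small fixture builders used across test files.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

mk_aln <- function(rows, ids = paste0("sp", seq_along(rows), ".p"),
                   species = NULL, query = 1L) {
  species <- species %||% sub("\\..*$", "", ids)
  new_alignment(rows, ids, species, query_index = query)
}

rand_seq <- function(len, seed) {
  set.seed(seed)
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

## Random integer alignment matrix (states 1..q).
rand_state_matrix <- function(n, L, q, seed, dup_rows = 0L) {
  set.seed(seed)
  M <- matrix(sample.int(q, n * L, replace = TRUE), n, L)
  if (dup_rows > 0L)
    for (d in seq_len(dup_rows)) M[n - d + 1L, ] <- M[d, ]
  M
}

state_matrix_to_aln <- function(M, q = 21L) {
  letters_q <- coevclade:::COEV_ALPHABET[seq_len(q)]
  rows <- apply(M, 1, function(r) paste(letters_q[r], collapse = ""))
  mk_aln(rows, ids = paste0("s", seq_len(nrow(M)), ".x"))
}

## Tiny single-MSA pair + ortholog table for pairing tests.
mk_pair_fixture <- function(n_species = 6, len_a = 8, len_b = 10, seed = 1) {
  set.seed(seed)
  species <- paste0("sp", seq_len(n_species))
  rows_a <- replicate(n_species, paste(sample(AA20, len_a, TRUE), collapse = ""))
  rows_b <- replicate(n_species, paste(sample(AA20, len_b, TRUE), collapse = ""))
  ids_a <- paste0(species, ".pA")
  ids_b <- paste0(species, ".pB")
  msa_a <- new_alignment(rows_a, ids_a, species, query_index = 1L,
                         col_to_query = seq_len(len_a))
  msa_b <- new_alignment(rows_b, ids_b, species, query_index = 1L,
                         col_to_query = seq_len(len_b))
  orth <- data.frame(
    query_id = rep(c(ids_a[1], ids_b[1]), each = n_species),
    species_id = rep(species, 2),
    subject_id = c(ids_a, ids_b),
    bitscore = 100, stringsAsFactors = FALSE)
  list(msa_a = msa_a, msa_b = msa_b, orth = orth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}
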