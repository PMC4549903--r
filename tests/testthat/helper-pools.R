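# programmatic fixtures shared across test files

random_sequences <- function(n, L, seed) {
  set.seed(seed)
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                           collapse = ""),
         character(1))
}

random_pool <- function(n, L = 150L, seed = 1L, affinity = NULL) {
  seqs <- random_sequences(n, L, seed)
  if (is.null(affinity)) affinity <- stats::rnorm(n, 0.5, 1)
  oligo_pool(sprintf("r%03d", seq_len(n)), seqs, affinity, L = L)
}

# independent per-(sequence, position) tally of diad frequencies
oracle_position_frequency <- function(sequences, L) {
  diads <- nucleokey::all_diads()
  freq <- matrix(0, nrow = 16L, ncol = L - 1L, dimnames = list(diads, NULL))
  for (s in sequences) {
    for (p in seq_len(L - 1L)) {
      d <- substr(s, p, p + 1L)
      freq[d, p] <- freq[d, p] + 1
    }
  }
  freq / length(sequences)
}

# independent position-by-position scan for (n1, n2)
oracle_count_diads <- function(sequence, partition) {
  n1 <- 0L; n2 <- 0L
  for (p in seq_len(nchar(sequence) - 1L)) {
    d <- substr(sequence, p, p + 1L)
    if (d %in% partition$positive) n1 <- n1 + 1L
    if (d %in% partition$negative) n2 <- n2 + 1L
  }
  c(n1 = n1, n2 = n2)
}

write_pool_files <- function(pool, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "pool.fasta")
  aff <- file.path(dir, "aff.tsv")
  writeLines(paste0(">", pool$id, "\n", pool$sequence), fasta)
  writeLines(c("id\taffinity", sprintf("%s\t%.17g", pool$id, pool$affinity)), aff)
  list(fasta = fasta, affinity = aff)
}
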