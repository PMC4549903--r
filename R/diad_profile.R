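#' The 16 diads (dinucleotides) in lexicographic order
#'
#' "Diad" is the working term here for a dinucleotide; there are 16 over
#' A/C/G/T. The fixed order AA, AC, ..., TT indexes every frequency matrix
#' in the package.
#'
#' @return Character vector of length 16.
#' @export
all_diads <- function() {
  bases <- c("A", "C", "G", "T")
  as.vector(t(outer(bases, bases, paste0)))
}

#' Define a diad partition (the experiment configuration)
#'
#' A partition splits some of the 16 diads into a nucleosome-favouring
#' "positive" set (G/C-rich) and a disfavouring "negative" set (A/T-rich).
#' The two sets must be disjoint, non-empty subsets of the 16 diads.
#'
#' @param positive character vector of positive diads.
#' @param negative character vector of negative diads.
#' @param name label for the partition (e.g. `"4-4"`).
#' @return A `diad_partition` list with elements `positive`, `negative`,
#'   `name`.
#' @export
diad_partition <- function(positive, negative, name = "custom") {
  positive <- toupper(unique(as.character(positive)))
  negative <- toupper(unique(as.character(negative)))
  pool16 <- all_diads()
  bad <- setdiff(c(positive, negative), pool16)
  if (length(bad)) stop("not diads over ACGT: ", paste(bad, collapse = ", "))
  if (!length(positive) || !length(negative)) stop("both diad sets must be non-empty")
  if (length(intersect(positive, negative))) {
    stop("positive and negative diad sets overlap: ",
         paste(intersect(positive, negative), collapse = ", "))
  }
  structure(list(positive = positive, negative = negative,
                 name = as.character(name)),
            class = "diad_partition")
}

#' @export
print.diad_partition <- function(x, ...) {
  cat(sprintf("<diad_partition> %s\n  positive: %s\n  negative: %s\n",
              x$name, paste(x$positive, collapse = "/"),
              paste(x$negative, collapse = "/")))
  invisible(x)
}

#' The three standard diad partitions (4-4, 4-3, 5-4)
#'
#' * `4-4`: positive CC/CG/GC/GG vs negative AA/AT/TA/TT.
#' * `4-3`: TA dropped from the negative set (its frequency does not
#'   separate the classes).
#' * `5-4`: AC added to the positive set (its frequency does).
#'
#' @return Named list of three [diad_partition()] objects.
#' @export
standard_partitions <- function() {
  gc4 <- c("CC", "CG", "GC", "GG")
  at4 <- c("AA", "AT", "TA", "TT")
  list(
    "4-4" = diad_partition(gc4, at4, "4-4"),
    "4-3" = diad_partition(gc4, setdiff(at4, "TA"), "4-3"),
    "5-4" = diad_partition(c("AC", gc4), at4, "5-4")
  )
}

# n x (L-1) character matrix of the diad starting at each position
diad_matrix <- function(sequences, L) {
  n <- length(sequences)
  m <- vapply(seq_len(L - 1L),
              function(p) substr(sequences, p, p + 1L),
              character(n))
  if (n == 1L) m <- matrix(m, nrow = 1L)
  m
}

#' Position-wise diad frequency profile
#'
#' For every diad start position p in 1..L-1 and every diad d, the fraction
#' of sequences in the chosen subset whose diad at p equals d. Columns
#' (positions) therefore sum to 1. This is the per-position frequency curve
#' underlying the exploratory comparison of positive- vs negative-affinity
#' pools: G/C diads run high in positive-affinity sequences and A/T diads in
#' negative ones.
#'
#' @param pool an [oligo_pool()]; for `subset` other than `"all"` it must be
#'   a labeled pool from [filter_by_affinity()].
#' @param subset one of `"all"`, `"positive"`, `"negative"`.
#' @return A `diad_profile`: a 16 x (L-1) numeric matrix (rows = diads in
#'   [all_diads()] order, columns = start positions) with attributes
#'   `n_sequences` and `subset`.
#' @export
position_frequency <- function(pool, subset = c("all", "positive", "negative")) {
  subset <- match.arg(subset)
  stopifnot(inherits(pool, "oligo_pool"))
  L <- pool_length(pool)
  seqs <- pool$sequence
  if (subset != "all") {
    if (!is_labeled_pool(pool)) stop("subset '", subset, "' requires a labeled pool")
    seqs <- seqs[pool$label == subset]
  }
  n <- length(seqs)
  if (n == 0L) stop("empty subset '", subset, "': refusing to build an all-NaN profile")
  dm <- diad_matrix(seqs, L)
  diads <- all_diads()
  freq <- apply(dm, 2L, function(col) {
    tabulate(match(col, diads), nbins = 16L) / n
  })
  dimnames(freq) <- list(diad = diads, position = seq_len(L - 1L))
  structure(freq, n_sequences = n, subset = subset, class = c("diad_profile", "matrix"))
}

#' Write a diad frequency profile as long-format TSV
#'
#' Columns: diad, position, subset, frequency.
#'
#' @param profile a `diad_profile` from [position_frequency()].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_diad_profile <- function(profile, path) {
  stopifnot(inherits(profile, "diad_profile"))
  long <- data.frame(
    diad = rep(rownames(profile), times = ncol(profile)),
    position = rep(as.integer(colnames(profile)), each = nrow(profile)),
    subset = attr(profile, "subset"),
    frequency = as.vector(profile)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count positive and negative diads in a sequence
#'
#' Scans every start position 1..L-1 (overlapping occurrences count: CC
#' appears twice in CCC) and tallies how many diads fall in the partition's
#' positive set (`n1`) and negative set (`n2`).
#'
#' @param sequence a single DNA string of length >= 2.
#' @param partition a [diad_partition()].
#' @return Named integer vector `c(n1 =, n2 =)`.
#' @export
#' @examples
#' count_diads("CCCC", standard_partitions()[["4-4"]])  # n1 = 3, n2 = 0
count_diads <- function(sequence, partition) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(partition, "diad_partition"))
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2L) stop("sequence must have length >= 2 to contain a diad")
  d <- substring(sequence, seq_len(L - 1L), seq_len(L - 1L) + 1L)
  c(n1 = sum(d %in% partition$positive), n2 = sum(d %in% partition$negative))
}

#' Affinity-weighted diad score of a sequence
#'
#' The per-sequence training weight: `af * (n1 - n2)` when the affinity
#' `af >= 0` and `af * (n2 - n1)` when `af < 0`. The two branches collapse
#' to `|af| * (n1 - n2)`, so the score is positive exactly when the diad
#' excess points the same way regardless of the affinity's sign; its
#' magnitude grows with both the affinity magnitude and the diad imbalance.
#' Vectorized over all three arguments.
#'
#' @param affinity finite numeric affinity (log-ratio).
#' @param n1 count of positive diads (>= 0).
#' @param n2 count of negative diads (>= 0).
#' @return Numeric score(s).
#' @export
#' @examples
#' affinity_weight(2, 5, 3)   #  4
#' affinity_weight(-2, 5, 3)  #  4  (branch equivalence)
affinity_weight <- function(affinity, n1, n2) {
  if (any(!is.finite(affinity))) stop("affinity must be finite")
  if (any(n1 < 0) || any(n2 < 0)) stop("diad counts must be non-negative")
  ifelse(affinity >= 0, affinity * (n1 - n2), affinity * (n2 - n1))
}

#' Diad counts and affinity-weighted scores for a whole pool
#'
#' @param pool an [oligo_pool()].
#' @param partition a [diad_partition()].
#' @return data.frame with columns `id`, `n1`, `n2`, `w` (the
#'   affinity-weighted score of each record).
#' @export
diad_scores <- function(pool, partition) {
  stopifnot(inherits(pool, "oligo_pool"), inherits(partition, "diad_partition"))
  L <- pool_length(pool)
  dm <- diad_matrix(pool$sequence, L)
  n1 <- rowSums(matrix(dm %in% partition$positive, nrow = nrow(dm)))
  n2 <- rowSums(matrix(dm %in% partition$negative, nrow = nrow(dm)))
  data.frame(id = pool$id, n1 = as.integer(n1), n2 = as.integer(n2),
             w = affinity_weight(pool$affinity, n1, n2))
}
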