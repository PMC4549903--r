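#' Specification for a synthetic oligo pool
#'
#' The generator emulates the structure the analysis assumes in a measured
#' oligonucleotide pool: fixed-length sequences, a real-valued affinity per
#' sequence whose sign tracks the class, and class-dependent diad biases
#' concentrated at a small set of planted "key" positions.
#'
#' Defaults mirror the desk-scale study conditions used throughout the
#' package: 2000 sequences of 150 bp, 10 planted positions spread across the
#' oligo, an excess probability of 0.30 for a class-consistent diad at each
#' planted position, class balance 0.573 (the positive fraction of the real
#' microarray pool), and class-conditional Gaussian affinities
#' N(1.5, 0.5) / N(-1, 0.5) chosen so the strict affinity filter (> 1, < 0)
#' keeps most records.
#'
#' @param n_sequences number of records.
#' @param L sequence length (default 150).
#' @param planted_positions diad start positions carrying the class signal
#'   (default 10 positions evenly spread over 1..L-1).
#' @param effect_size excess probability, given the class, that a planted
#'   position carries a class-consistent diad (0 = null pool, 1 = the
#'   position is deterministic).
#' @param class_balance probability a record is class positive.
#' @param affinity_mean_pos,affinity_mean_neg,affinity_sd parameters of the
#'   two-component Gaussian affinity model.
#' @param base_freq named background base probabilities (A/C/G/T), summing
#'   to 1; default uniform.
#' @param seed integer seed; all generation is deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_sequences = 2000L, L = 150L,
                           planted_positions = NULL, effect_size = 0.30,
                           class_balance = 0.573,
                           affinity_mean_pos = 1.5, affinity_mean_neg = -1,
                           affinity_sd = 0.5,
                           base_freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                           seed = 1L) {
  L <- as.integer(L)
  if (is.null(planted_positions)) {
    planted_positions <- as.integer(round(seq(10, L - 5L, length.out = 10L)))
  }
  planted_positions <- sort(unique(as.integer(planted_positions)))
  stopifnot(n_sequences >= 1L, L >= 2L,
            all(planted_positions >= 1L & planted_positions <= L - 1L),
            effect_size >= 0, effect_size <= 1,
            class_balance > 0, class_balance < 1,
            affinity_sd > 0)
  base_freq <- base_freq[c("A", "C", "G", "T")]
  if (any(is.na(base_freq)) || abs(sum(base_freq) - 1) > 1e-8) {
    stop("base_freq must be named A/C/G/T probabilities summing to 1")
  }
  structure(list(n_sequences = as.integer(n_sequences), L = L,
                 planted_positions = planted_positions,
                 effect_size = effect_size, class_balance = class_balance,
                 affinity_mean_pos = affinity_mean_pos,
                 affinity_mean_neg = affinity_mean_neg,
                 affinity_sd = affinity_sd, base_freq = base_freq,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic oligo pool with planted diad biases
#'
#' For each record: the class is drawn with probability `class_balance`, the
#' affinity from that class's Gaussian, and the bases independently from the
#' background. Then, at each planted position in left-to-right order, with
#' probability `effect_size` the diad starting there is overwritten with one
#' drawn uniformly from the class-consistent diad set (the partition's
#' positive diads for class positive, negative diads for class negative).
#' Planted positions closer than 2 bases apart are legal; overlaps resolve
#' left to right, i.e. the later position's overwrite wins on the shared
#' base. Fully deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param partition the [diad_partition()] whose diad sets carry the planted
#'   signal (default the standard 4-4).
#' @return List with `pool` (an [oligo_pool()]), `classes` (character
#'   `"positive"`/`"negative"` per record), `planted_positions`, and `spec`.
#' @export
generate_pool <- function(spec, partition = standard_partitions()[["4-4"]]) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(partition, "diad_partition"))
  n <- spec$n_sequences
  L <- spec$L
  set.seed(spec$seed)
  classes <- ifelse(stats::runif(n) < spec$class_balance, "positive", "negative")
  affinity <- stats::rnorm(n,
                           mean = ifelse(classes == "positive",
                                         spec$affinity_mean_pos,
                                         spec$affinity_mean_neg),
                           sd = spec$affinity_sd)
  bases <- matrix(sample(names(spec$base_freq), n * L, replace = TRUE,
                         prob = spec$base_freq),
                  nrow = n, ncol = L)
  for (p in spec$planted_positions) {
    hit <- stats::runif(n) < spec$effect_size
    if (!any(hit)) next
    for (cls in c("positive", "negative")) {
      idx <- which(hit & classes == cls)
      if (!length(idx)) next
      diad_set <- if (cls == "positive") partition$positive else partition$negative
      d <- diad_set[sample.int(length(diad_set), length(idx), replace = TRUE)]
      bases[idx, p] <- substr(d, 1L, 1L)
      bases[idx, p + 1L] <- substr(d, 2L, 2L)
    }
  }
  seqs <- do.call(paste0, as.data.frame(bases, stringsAsFactors = FALSE))
  ids <- sprintf("syn%0*d", nchar(n), seq_len(n))
  pool <- oligo_pool(ids, seqs, affinity, L = L)
  list(pool = pool, classes = classes,
       planted_positions = spec$planted_positions, spec = spec)
}

#' Write a synthetic pool as plain-text fixture files
#'
#' Emits `pool.fasta` (sequences), `affinities.tsv` (id, affinity at full
#' double precision so a round trip through [read_pool()] is exact), and
#' `truth.tsv` (id, class; the planted positions recorded in a leading
#' comment line). Byte-identical across runs with the same spec.
#'
#' @param sim the list returned by [generate_pool()].
#' @param dir output directory (created if needed).
#' @return Invisibly, named character vector of the three file paths.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(is.list(sim), inherits(sim$pool, "oligo_pool"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "pool.fasta"),
             affinity = file.path(dir, "affinities.tsv"),
             truth = file.path(dir, "truth.tsv"))
  seqs <- Biostrings::DNAStringSet(sim$pool$sequence)
  names(seqs) <- sim$pool$id
  tryCatch(Biostrings::writeXStringSet(seqs, paths[["fasta"]]),
           error = function(e) stop("failed writing ", paths[["fasta"]], ": ",
                                    conditionMessage(e)))
  writeLines(c("id\taffinity",
               sprintf("%s\t%.17g", sim$pool$id, sim$pool$affinity)),
             paths[["affinity"]])
  writeLines(c(sprintf("# planted_positions=%s",
                       paste(sim$planted_positions, collapse = ",")),
               "id\tclass",
               sprintf("%s\t%s", sim$pool$id, sim$classes)),
             paths[["truth"]])
  invisible(paths)
}
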