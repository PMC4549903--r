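#' Construct an oligo pool from ids, sequences and affinities
#'
#' An oligo pool is the atomic container of the analysis: an ordered set of
#' fixed-length DNA sequences, each tagged with a real-valued
#' nucleosome-formation affinity (the log-ratio of a sequence's abundance in
#' the nucleosome-reconstituted fraction over the initial pool; positive
#' values mean preferential nucleosome formation).
#'
#' Sequences are uppercased on construction; only A/C/G/T are accepted
#' (ambiguity codes such as N are rejected because downstream diad counting
#' has no defined behaviour for them). All sequences must share the declared
#' length `L` and ids must be unique.
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of DNA sequences over A/C/G/T.
#' @param affinity numeric vector of finite affinities (log-ratio, unitless).
#' @param L declared sequence length (default 150).
#' @return An `oligo_pool`: a data.frame with columns `id`, `sequence`,
#'   `affinity` and attribute `L`.
#' @export
#' @examples
#' oligo_pool(c("a", "b"), c("ACGTAC", "GGGCCC"), c(1.2, -0.4), L = 6)
oligo_pool <- function(id, sequence, affinity, L = 150L) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  affinity <- as.numeric(affinity)
  if (length(id) != length(sequence) || length(id) != length(affinity)) {
    stop("id, sequence and affinity must have equal length")
  }
  L <- as.integer(L)
  if (length(L) != 1L || is.na(L) || L < 2L) stop("L must be a single integer >= 2")
  if (anyDuplicated(id)) {
    stop("duplicate record ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad_len <- nchar(sequence) != L
  if (any(bad_len)) {
    stop("sequence length differs from declared L = ", L, " for record(s): ",
         paste(utils::head(id[bad_len], 5L), collapse = ", "))
  }
  bad_char <- regexpr("[^ACGT]", sequence)
  if (any(bad_char > 0L)) {
    i <- which(bad_char > 0L)[1L]
    stop("non-ACGT character in record '", id[i], "' at offset ", bad_char[i])
  }
  if (any(!is.finite(affinity))) {
    stop("non-finite affinity for record(s): ",
         paste(utils::head(id[!is.finite(affinity)], 5L), collapse = ", "))
  }
  out <- data.frame(id = id, sequence = sequence, affinity = affinity,
                    stringsAsFactors = FALSE)
  attr(out, "L") <- L
  class(out) <- c("oligo_pool", "data.frame")
  out
}

#' @export
print.oligo_pool <- function(x, ...) {
  cat(sprintf("<oligo_pool> %d record(s) of length %d bp\n", nrow(x), pool_length(x)))
  if ("label" %in% names(x)) {
    cat(sprintf("  labeled: %d positive, %d negative\n",
                sum(x$label == "positive"), sum(x$label == "negative")))
  }
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
`[.oligo_pool` <- function(x, i, j, ...) {
  out <- NextMethod()
  # row subsets keep the container semantics; column drops demote to data.frame
  if (is.data.frame(out) && all(c("id", "sequence", "affinity") %in% names(out))) {
    attr(out, "L") <- attr(x, "L")
    cls <- class(x)
    if (!"label" %in% names(out)) cls <- setdiff(cls, "labeled_pool")
    class(out) <- cls
  }
  out
}

#' Declared sequence length of a pool
#' @param pool an `oligo_pool`.
#' @return Integer sequence length L.
#' @export
pool_length <- function(pool) {
  L <- attr(pool, "L")
  if (is.null(L)) stop("not an oligo_pool: missing L attribute")
  as.integer(L)
}

#' Read an oligo pool from a FASTA file and an affinity table
#'
#' Joins sequences (FASTA) with affinities (tab-separated `id<TAB>affinity`;
#' a header row is optional and auto-detected by whether the second field of
#' the first row parses as a number). Records are returned in FASTA order.
#' Every FASTA id must appear in the affinity table and vice versa.
#'
#' @param fasta_path path to a FASTA file of fixed-length DNA sequences.
#' @param affinity_path path to the affinity TSV.
#' @param L declared sequence length (default 150).
#' @return An [oligo_pool()].
#' @export
read_pool <- function(fasta_path, affinity_path, L = 150L) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("FASTA records must all be named")
  ids <- sub("\\s.*$", "", ids)  # keep the id token, drop description
  aff <- read_affinity_table(affinity_path)
  missing_aff <- setdiff(ids, aff$id)
  if (length(missing_aff)) {
    stop("id(s) present in FASTA but absent from affinity table: ",
         paste(utils::head(missing_aff, 5L), collapse = ", "))
  }
  extra_aff <- setdiff(aff$id, ids)
  if (length(extra_aff)) {
    stop("id(s) present in affinity table but absent from FASTA: ",
         paste(utils::head(extra_aff, 5L), collapse = ", "))
  }
  oligo_pool(ids, as.character(seqs), aff$affinity[match(ids, aff$id)], L = L)
}

read_affinity_table <- function(path) {
  first <- utils::read.table(path, sep = "\t", header = FALSE, nrows = 1L,
                             colClasses = "character")
  if (ncol(first) < 2L) stop("affinity table must have columns (id, affinity): ", path)
  has_header <- is.na(suppressWarnings(as.numeric(first[[2L]])))
  tab <- utils::read.table(path, sep = "\t", header = has_header,
                           colClasses = c("character", "numeric"),
                           col.names = c("id", "affinity"))
  names(tab) <- c("id", "affinity")
  tab
}

#' Filter a pool by affinity and derive binary labels
#'
#' Keeps exactly the records with `affinity > upper` (labeled `"positive"`)
#' or `affinity < lower` (labeled `"negative"`); both inequalities are
#' strict, so with the defaults records with affinity in the closed interval
#' \[0, 1\] are dropped. Record order is preserved. The operation is
#' idempotent: filtering an already-filtered pool changes nothing.
#'
#' @param pool an [oligo_pool()] (a labeled pool is accepted and re-filtered).
#' @param upper positive threshold (default 1): kept if affinity is strictly
#'   greater.
#' @param lower negative threshold (default 0): kept if affinity is strictly
#'   smaller.
#' @return A labeled pool: the input pool restricted to kept records, with a
#'   `label` column of `"positive"`/`"negative"`.
#' @export
#' @examples
#' p <- oligo_pool(letters[1:5],
#'                 rep(strrep("ACGT", 2), 5),
#'                 c(1.2, 0.4, -0.1, 1.0, 0.0), L = 8)
#' filter_by_affinity(p)  # keeps 1.2 (positive) and -0.1 (negative)
filter_by_affinity <- function(pool, upper = 1, lower = 0) {
  stopifnot(inherits(pool, "oligo_pool"))
  if (!(is.numeric(upper) && is.numeric(lower) && upper > lower)) {
    stop("need numeric thresholds with upper > lower")
  }
  keep <- pool$affinity > upper | pool$affinity < lower
  out <- pool[keep, , drop = FALSE]
  out$label <- ifelse(out$affinity > upper, "positive", "negative")
  rownames(out) <- NULL
  attr(out, "L") <- pool_length(pool)
  class(out) <- c("labeled_pool", "oligo_pool", "data.frame")
  out
}

is_labeled_pool <- function(pool) inherits(pool, "labeled_pool") && "label" %in% names(pool)

#' Segment bounds splitting a sequence into front / mid / last
#'
#' The default segmentation of a 150 bp oligo is front = 1-30, mid = 31-120,
#' last = 121-150 (1-based inclusive). The three intervals must be
#' contiguous, non-overlapping, and jointly cover 1..L.
#'
#' @param front,mid,last integer length-2 vectors `c(start, end)`, 1-based
#'   inclusive.
#' @return A `segment_bounds` list.
#' @export
segment_bounds <- function(front = c(1L, 30L), mid = c(31L, 120L), last = c(121L, 150L)) {
  iv <- list(front = as.integer(front), mid = as.integer(mid), last = as.integer(last))
  for (nm in names(iv)) {
    v <- iv[[nm]]
    if (length(v) != 2L || any(is.na(v)) || v[1L] > v[2L] || v[1L] < 1L) {
      stop("invalid interval for '", nm, "': need c(start, end) with 1 <= start <= end")
    }
  }
  if (iv$mid[1L] != iv$front[2L] + 1L || iv$last[1L] != iv$mid[2L] + 1L) {
    stop("intervals must be contiguous and in order (front, mid, last) with no gap or overlap")
  }
  structure(iv, class = "segment_bounds")
}

#' Split a sequence into front / mid / last sub-sequences
#'
#' @param sequence a single DNA string (or a single-row slice of a pool).
#' @param bounds a [segment_bounds()]; must cover `1..nchar(sequence)`.
#' @return Named character vector `c(front=, mid=, last=)` whose
#'   concatenation equals the input.
#' @export
#' @examples
#' segment_sequence(strrep("ACGTA", 30))  # lengths 30 / 90 / 30
segment_sequence <- function(sequence, bounds = segment_bounds()) {
  if (inherits(sequence, "oligo_pool")) {
    if (nrow(sequence) != 1L) stop("pass a single record or a plain sequence string")
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!inherits(bounds, "segment_bounds")) stop("bounds must be a segment_bounds object")
  L <- nchar(sequence)
  if (bounds$front[1L] != 1L || bounds$last[2L] != L) {
    stop("bounds do not cover 1..", L, " (they span ",
         bounds$front[1L], "..", bounds$last[2L], ")")
  }
  vapply(bounds, function(iv) substr(sequence, iv[1L], iv[2L]), character(1L))
}

#' Write a labeled pool as a TSV of (id, affinity, label)
#'
#' @param pool a labeled pool from [filter_by_affinity()].
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_labeled_pool <- function(pool, path) {
  stopifnot(is_labeled_pool(pool))
  utils::write.table(pool[, c("id", "affinity", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
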