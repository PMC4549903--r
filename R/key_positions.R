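#' Select the k key positions with largest weight magnitude
#'
#' Key positions are the diad start positions whose learned weight magnitude
#' ranks in the top k; they are hypothesized to dominate histone-DNA
#' binding. Ranking is by `|weight|` by default (negative-effect positions
#' are kept in the analysis); `signed = TRUE` ranks by the raw weight for
#' sensitivity analysis. Ties break toward the smaller position index, which
#' makes the selection deterministic and the top-k set a subset of the
#' top-(k+1) set.
#'
#' @param weights a `position_weights` object (or a bare numeric vector of
#'   per-position weights).
#' @param k number of positions to select (10 or 20 in the standard
#'   experiments).
#' @param signed rank by raw weight instead of magnitude (default FALSE).
#' @return A `key_positions` object: sorted integer vector of 1-based diad
#'   start positions with attributes `k` and `source_partition`.
#' @export
#' @examples
#' select_key_positions(c(0.1, 0.9, -0.5), k = 2)  # positions 2 and 3
select_key_positions <- function(weights, k, signed = FALSE) {
  if (inherits(weights, "position_weights")) {
    w <- weights$weights
    src <- weights$partition_name
  } else {
    w <- as.numeric(weights)
    if (is.null(names(w))) names(w) <- seq_along(w)
    src <- NA_character_
  }
  k <- as.integer(k)
  if (k < 1L || k > length(w)) stop("k must be in 1..", length(w))
  score <- if (signed) w else abs(w)
  # order by decreasing score, ties toward the smaller position index
  ord <- order(-score, seq_along(w))
  sel <- sort(as.integer(names(w)[ord[seq_len(k)]]))
  structure(sel, k = k, source_partition = src, class = "key_positions")
}

#' @export
print.key_positions <- function(x, ...) {
  src <- attr(x, "source_partition")
  cat(sprintf("<key_positions> k = %d%s\n  %s\n", attr(x, "k"),
              if (is.na(src)) "" else paste0(" (", src, ")"),
              paste(as.integer(x), collapse = ", ")))
  invisible(x)
}

#' Build a key-position set from explicit positions
#'
#' For comparing externally reported position lists with learned ones.
#'
#' @param positions integer vector of 1-based diad start positions.
#' @param source_partition optional label.
#' @return A `key_positions` object.
#' @export
key_position_set <- function(positions, source_partition = NA_character_) {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stop("duplicate positions")
  if (any(positions < 1L)) stop("positions must be >= 1")
  structure(sort(positions), k = length(positions),
            source_partition = as.character(source_partition),
            class = "key_positions")
}

#' Compare key-position sets across experiments
#'
#' Reports, for every pair of sets, the exact overlap, the
#' tolerant overlap (greedy one-to-one matching of positions within
#' `tolerance` bases, closest pairs first), and the exact Jaccard index,
#' plus the multiset of positions shared (exactly) by at least two sets.
#'
#' @param sets named list of `key_positions` (or plain integer vectors).
#' @param tolerance maximum |difference| in bases for a tolerant match
#'   (default 1).
#' @return List with `pairwise` (data.frame: set_a, set_b, exact_overlap,
#'   tolerant_overlap, jaccard) and `shared_positions` (integer vector).
#' @export
compare_key_sets <- function(sets, tolerance = 1L) {
  if (length(sets) < 2L) stop("need at least two key-position sets")
  sets <- lapply(sets, function(s) sort(as.integer(s)))
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  tolerance <- as.integer(tolerance)
  pairs <- utils::combn(names(sets), 2L)
  rows <- apply(pairs, 2L, function(pr) {
    a <- sets[[pr[1L]]]; b <- sets[[pr[2L]]]
    exact <- length(intersect(a, b))
    jac <- exact / length(union(a, b))
    data.frame(set_a = pr[1L], set_b = pr[2L], exact_overlap = exact,
               tolerant_overlap = tolerant_overlap(a, b, tolerance),
               jaccard = jac)
  })
  pairwise <- do.call(rbind, rows)
  rownames(pairwise) <- NULL
  all_pos <- unlist(lapply(sets, unique), use.names = FALSE)
  shared <- sort(unique(all_pos[duplicated(all_pos)]))
  list(pairwise = pairwise, shared_positions = shared)
}

# greedy one-to-one matching: repeatedly pair the closest (a, b) within tol
tolerant_overlap <- function(a, b, tol) {
  if (!length(a) || !length(b)) return(0L)
  d <- abs(outer(a, b, "-"))
  count <- 0L
  while (TRUE) {
    m <- which(d == min(d), arr.ind = TRUE)[1L, , drop = TRUE]
    if (d[m[1L], m[2L]] > tol) break
    count <- count + 1L
    d[m[1L], ] <- Inf
    d[, m[2L]] <- Inf
    if (all(is.infinite(d))) break
  }
  count
}

#' Write a key-position set as TSV and/or BED-like intervals
#'
#' The BED-like file frames each diad as a 0-based half-open interval
#' `[position - 1, position + 1)` over the 150 bp coordinate frame, for
#' genome-browser-style overlays.
#'
#' @param keys a `key_positions` object.
#' @param path output TSV path (one `position` column).
#' @param bed_path optional BED-like output path.
#' @return Invisibly, `path`.
#' @export
write_key_positions <- function(keys, path, bed_path = NULL) {
  stopifnot(inherits(keys, "key_positions"))
  utils::write.table(data.frame(position = as.integer(keys)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    src <- attr(keys, "source_partition")
    bed <- data.frame(chrom = "oligo",
                      start = as.integer(keys) - 1L,
                      end = as.integer(keys) + 1L,
                      name = paste0(if (is.na(src)) "key" else src,
                                    "_pos", as.integer(keys)))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
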