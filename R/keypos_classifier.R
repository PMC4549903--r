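#' Score sequences from key positions only
#'
#' The restricted linear score `s = sum_{p in keys} weights[p] * x[p] + bias`
#' with `x` the ternary diad-class encoding: positions outside the key set
#' contribute nothing, so the classifier uses only the 10 or 20 selected
#' direct factors. Equals the full score with all non-key weights zeroed.
#'
#' @param pool an [oligo_pool()] (any labeling is ignored here).
#' @param weights a `position_weights` object consistent with the pool's L.
#' @param keys a `key_positions` object (or integer vector); `NULL` scores
#'   with all positions.
#' @param partition the [diad_partition()] used for encoding.
#' @return Numeric score per record, named by id.
#' @export
score_sequences <- function(pool, weights, keys = NULL, partition) {
  stopifnot(inherits(pool, "oligo_pool"), inherits(weights, "position_weights"),
            inherits(partition, "diad_partition"))
  L <- pool_length(pool)
  if (length(weights$weights) != L - 1L) {
    stop("weight vector length ", length(weights$weights),
         " does not match pool's L - 1 = ", L - 1L)
  }
  w <- weights$weights
  if (!is.null(keys)) {
    keys <- as.integer(keys)
    if (any(keys < 1L | keys > L - 1L)) {
      stop("key position(s) outside 1..", L - 1L, ": ",
           paste(keys[keys < 1L | keys > L - 1L], collapse = ", "))
    }
    mask <- rep(0, length(w))
    mask[keys] <- 1
    w <- w * mask
  }
  x <- encode_pool(pool, partition)
  s <- drop(x %*% w) + weights$bias
  names(s) <- pool$id
  s
}

#' Threshold a score into a binary class
#'
#' Positive iff `score > threshold` (strict; a score exactly at the
#' threshold is negative).
#'
#' @param score numeric score(s), finite.
#' @param threshold decision threshold (default 0).
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify <- function(score, threshold = 0) {
  if (any(!is.finite(score))) stop("scores must be finite")
  ifelse(score > threshold, "positive", "negative")
}

#' Confusion counts from predictions and labels
#'
#' TP counts predicted-positive records that are labeled positive; FP, TN,
#' FN analogously.
#'
#' @param predictions,labels character vectors of `"positive"`/`"negative"`,
#'   equal length.
#' @return A `confusion_counts` object (named numeric TP/FP/TN/FN).
#' @export
confusion <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length (",
         length(predictions), " vs ", length(labels), ")")
  }
  p <- as_binary_labels(predictions)
  y <- as_binary_labels(labels)
  confusion_counts(TP = sum(p == 1 & y == 1), FP = sum(p == 1 & y == 0),
                   TN = sum(p == 0 & y == 0), FN = sum(p == 0 & y == 1))
}

#' Construct confusion counts
#'
#' Counts may be fractional: per-fold means such as TP = 786.3 are legal
#' because every downstream metric is invariant to a common positive
#' rescaling of the four counts.
#'
#' @param TP,FP,TN,FN non-negative numeric counts.
#' @return A `confusion_counts` named numeric vector.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = as.numeric(TP), FP = as.numeric(FP),
         TN = as.numeric(TN), FN = as.numeric(FN))
  if (any(!is.finite(v)) || any(v < 0)) stop("counts must be finite and >= 0")
  structure(v, class = c("confusion_counts", "numeric"))
}

#' Classification metrics: Acc, Sen, PPV, MCC
#'
#' \deqn{Acc = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{Sen = TP/(TP+FN)}
#' \deqn{PPV = TP/(TP+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FN)(TP+FP)(TN+FN)(TN+FP)}}
#'
#' All four are reported on the x100 scale (MCC in \[-100, 100\], the others
#' in \[0, 100\]); the print method shows one decimal. MCC equals the phi
#' coefficient — the Pearson correlation of the binary prediction and label
#' vectors. A metric whose denominator is zero is returned as `NA` with a
#' note in the `undefined` attribute rather than raising an error.
#'
#' @param counts a `confusion_counts` (fractional per-fold means are fine).
#' @return A `metric_report`: named numeric `c(acc, sen, ppv, mcc)` on the
#'   x100 scale, unrounded, with attribute `counts`.
#' @export
#' @examples
#' metrics(confusion_counts(786.3, 367.5, 1763.1, 105.6))
metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  total <- TP + FP + TN + FN
  if (total <= 0) stop("all four counts are zero: no records to evaluate")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- safe_div(TP + TN, total)
  sen <- safe_div(TP, TP + FN)
  ppv <- safe_div(TP, TP + FP)
  mcc_den <- (TP + FN) * (TP + FP) * (TN + FN) * (TN + FP)
  mcc <- if (mcc_den > 0) (TP * TN - FP * FN) / sqrt(mcc_den) else NA_real_
  out <- 100 * c(acc = acc, sen = sen, ppv = ppv, mcc = mcc)
  undefined <- names(out)[is.na(out)]
  structure(out, counts = counts, undefined = undefined,
            class = c("metric_report", "numeric"))
}

#' @export
print.metric_report <- function(x, ...) {
  v <- unclass(x)
  cat("<metric_report> (x100 scale)\n")
  cat(sprintf("  Acc = %s  Sen = %s  PPV = %s  MCC = %s\n",
              fmt1(v[["acc"]]), fmt1(v[["sen"]]), fmt1(v[["ppv"]]), fmt1(v[["mcc"]])))
  und <- attr(x, "undefined")
  if (length(und)) cat("  undefined (zero denominator):", paste(und, collapse = ", "), "\n")
  invisible(x)
}

fmt1 <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", v)

#' Evaluate a key-position classifier on a labeled pool
#'
#' Scores every record from the key positions only, thresholds at
#' `threshold`, and returns confusion counts plus metrics.
#'
#' @param pool a labeled pool.
#' @param weights a `position_weights` object.
#' @param keys a `key_positions` object (or `NULL` for all positions).
#' @param partition the [diad_partition()] used for encoding.
#' @param threshold decision threshold (default 0).
#' @return List with `scores`, `predictions`, `counts`
#'   (`confusion_counts`), and `report` (`metric_report`).
#' @export
evaluate_keypos_classifier <- function(pool, weights, keys = NULL, partition,
                                       threshold = 0) {
  stopifnot(is_labeled_pool(pool))
  s <- score_sequences(pool, weights, keys, partition)
  pred <- classify(s, threshold)
  cc <- confusion(pred, pool$label)
  list(scores = s, predictions = pred, counts = cc, report = metrics(cc))
}

#' Write confusion counts and metrics as a Table-style TSV row
#'
#' Columns: partition, key_positions (comma-separated), TP, FP, TN, FN,
#' Acc, Sen, PPV, MCC (one decimal, x100).
#'
#' @param report a `metric_report`.
#' @param path output file path.
#' @param partition_name label for the row.
#' @param keys optional `key_positions` for the row.
#' @return Invisibly, the path.
#' @export
write_metric_report <- function(report, path, partition_name = NA_character_,
                                keys = NULL) {
  stopifnot(inherits(report, "metric_report"))
  cc <- attr(report, "counts")
  row <- data.frame(
    partition = partition_name,
    key_positions = if (is.null(keys)) "" else paste(as.integer(keys), collapse = ","),
    TP = cc[["TP"]], FP = cc[["FP"]], TN = cc[["TN"]], FN = cc[["FN"]],
    Acc = round(report[["acc"]], 1L), Sen = round(report[["sen"]], 1L),
    PPV = round(report[["ppv"]], 1L), MCC = round(report[["mcc"]], 1L))
  utils::write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
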