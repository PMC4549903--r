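#' Ternary per-position diad-class encoding of a pool
#'
#' Each sequence becomes a vector of length L-1: entry p is +1 if the diad
#' starting at position p belongs to the partition's positive set, -1 if it
#' belongs to the negative set, and 0 otherwise. This is the feature
#' representation the single-layer network is trained on; summing the +1s
#' and -1s recovers the diad counts (n1, n2) of [count_diads()].
#'
#' @param pool an [oligo_pool()] (or labeled pool).
#' @param partition a [diad_partition()].
#' @return Numeric matrix n x (L-1) with entries in \{-1, 0, +1\}; rows named
#'   by record id, columns by diad start position.
#' @export
encode_pool <- function(pool, partition) {
  stopifnot(inherits(pool, "oligo_pool"), inherits(partition, "diad_partition"))
  L <- pool_length(pool)
  dm <- diad_matrix(pool$sequence, L)
  x <- matrix(0, nrow = nrow(dm), ncol = ncol(dm),
              dimnames = list(pool$id, seq_len(L - 1L)))
  x[matrix(dm %in% partition$positive, nrow = nrow(dm))] <- 1
  x[matrix(dm %in% partition$negative, nrow = nrow(dm))] <- -1
  x
}

#' Encode a single sequence
#'
#' @param sequence a single DNA string.
#' @param partition a [diad_partition()].
#' @return Numeric vector of length `nchar(sequence) - 1` in \{-1, 0, +1\}.
#' @export
#' @examples
#' encode_sequence("CCAA", standard_partitions()[["4-4"]])  # +1, 0, -1
encode_sequence <- function(sequence, partition) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2L) stop("sequence must have length >= 2")
  d <- substring(sequence, seq_len(L - 1L), seq_len(L - 1L) + 1L)
  x <- numeric(L - 1L)
  x[d %in% partition$positive] <- 1
  x[d %in% partition$negative] <- -1
  names(x) <- seq_len(L - 1L)
  x
}

#' Assign records to cross-validation folds
#'
#' Deterministic given the seed. By default folds are stratified by label:
#' records are shuffled within each class and fold indices are assigned
#' cyclically across the concatenated classes, so fold sizes differ by at
#' most one both overall and within each class.
#'
#' @param pool a labeled pool (or any pool when `stratify = FALSE`).
#' @param K number of folds (default 10, the "9-1" protocol).
#' @param seed integer seed controlling the shuffle.
#' @param stratify stratify by the `label` column (default TRUE).
#' @return A `fold_plan`: integer vector of fold indices in 1..K, one per
#'   record, with attributes `K` and `seed`.
#' @export
make_folds <- function(pool, K = 10L, seed = 1L, stratify = TRUE) {
  stopifnot(inherits(pool, "oligo_pool"))
  K <- as.integer(K)
  n <- nrow(pool)
  if (K < 2L) stop("K must be >= 2")
  if (n < K) stop("pool has ", n, " record(s), fewer than K = ", K)
  if (stratify && !is_labeled_pool(pool)) {
    stop("stratified folds require a labeled pool; use stratify = FALSE")
  }
  rng <- local({
    set.seed(as.integer(seed))
    if (stratify) {
      order_within <- unlist(lapply(split(seq_len(n), pool$label), sample), use.names = FALSE)
    } else {
      order_within <- sample(seq_len(n))
    }
    order_within
  })
  folds <- integer(n)
  folds[rng] <- rep_len(seq_len(K), n)
  structure(folds, K = K, seed = as.integer(seed), class = "fold_plan")
}

#' Training configuration for the single-layer network
#'
#' The network is a linear score over the ternary position features passed
#' through a logistic output; it is fit by damped Newton iterations (IRLS)
#' on the sample-weighted logistic loss with a small ridge penalty on the
#' position weights (the bias is unpenalized). Newton from a zero start is
#' deterministic, so the seed only feeds fold assignment and any synthetic
#' generation upstream.
#'
#' @param max_iter maximum Newton iterations (default 50).
#' @param tol relative loss-change convergence tolerance (default 1e-10).
#' @param ridge L2 penalty on the position weights (default 1e-3); keeps the
#'   optimum finite under separable data.
#' @param seed integer seed recorded with the run.
#' @param use_sample_weights weight each record by the magnitude of its
#'   affinity-weighted diad score (default TRUE); weights are normalized to
#'   sum 1, so the data term is a weighted mean loss and `ridge` has the
#'   same meaning at every pool size.
#' @return A `training_config` list.
#' @export
training_config <- function(max_iter = 50L, tol = 1e-10, ridge = 1e-3,
                            seed = 1L, use_sample_weights = TRUE) {
  stopifnot(max_iter >= 1L, tol > 0, ridge >= 0)
  structure(list(max_iter = as.integer(max_iter), tol = tol, ridge = ridge,
                 seed = as.integer(seed),
                 use_sample_weights = isTRUE(use_sample_weights)),
            class = "training_config")
}

#' Fit the single-layer network on encoded features
#'
#' Minimizes the sample-weighted logistic loss of the linear score
#' `s = x %*% weights + bias` by damped Newton (IRLS) with ridge
#' regularization on the weights. Deterministic given (data, config).
#'
#' @param x feature matrix n x (L-1) from [encode_pool()].
#' @param labels per-record class: `"positive"`/`"negative"`, logical, or
#'   0/1 (1 = positive).
#' @param sample_weights optional non-negative per-record weights (the
#'   magnitude of the affinity-weighted diad score); `NULL` means
#'   unweighted.
#' @param config a [training_config()].
#' @return A `position_weights` object: list with `weights` (length L-1,
#'   named by position), `bias`, `partition_name`, `fold_count`,
#'   `converged`, `iterations`.
#' @export
train_single_layer <- function(x, labels, sample_weights = NULL,
                               config = training_config()) {
  stopifnot(is.matrix(x), inherits(config, "training_config"))
  y <- as_binary_labels(labels)
  if (length(y) != nrow(x)) stop("labels length must match nrow(x)")
  if (length(unique(y)) < 2L) {
    stop("all labels identical: a logistic fit is ill-posed; ",
         "use profile_weights_single_class() for single-class profiles")
  }
  sw <- if (is.null(sample_weights)) rep(1, nrow(x)) else as.numeric(sample_weights)
  if (length(sw) != nrow(x) || any(!is.finite(sw)) || any(sw < 0)) {
    stop("sample_weights must be finite, non-negative, one per record")
  }
  if (sum(sw) <= 0) stop("all sample weights are zero")
  # normalize to sum 1: the objective is a weighted MEAN loss plus the ridge,
  # so duplicating every record leaves the optimum unchanged and `ridge` has
  # the same meaning at every pool size
  sw <- sw / sum(sw)

  p_feat <- ncol(x)
  X <- cbind(Intercept = 1, x)
  beta <- numeric(p_feat + 1L)
  pen <- c(0, rep(config$ridge, p_feat))  # bias unpenalized

  loss_fn <- function(b) {
    eta <- drop(X %*% b)
    # numerically stable weighted logistic loss
    ll <- sw * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
    sum(ll) + 0.5 * sum(pen * b^2)
  }
  loss <- loss_fn(beta)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    grad <- drop(crossprod(X, sw * (p - y))) + pen * beta
    wdiag <- pmax(sw * p * (1 - p), 1e-15)
    H <- crossprod(X * wdiag, X)
    diag(H) <- diag(H) + pen
    step <- solve(H, grad)
    # damped Newton: halve the step until the penalized loss decreases
    alpha <- 1
    repeat {
      cand <- beta - alpha * step
      cand_loss <- loss_fn(cand)
      if (cand_loss <= loss || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    delta <- abs(loss - cand_loss) / max(1, abs(loss))
    beta <- cand
    loss <- cand_loss
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  w <- beta[-1L]
  names(w) <- colnames(x)
  structure(list(weights = w, bias = unname(beta[1L]),
                 partition_name = NA_character_, fold_count = 1L,
                 method = "logistic-newton", converged = converged,
                 iterations = iter),
            class = "position_weights")
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), c("positive", "negative"))
    if (length(bad)) stop("labels must be 'positive'/'negative'; saw: ",
                          paste(bad, collapse = ", "))
    as.numeric(labels == "positive")
  } else if (is.logical(labels)) {
    as.numeric(labels)
  } else if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    as.numeric(labels)
  } else {
    stop("unsupported label type")
  }
}

#' @export
print.position_weights <- function(x, ...) {
  cat(sprintf("<position_weights> %d positions (%s, %d fold%s)\n",
              length(x$weights),
              if (is.na(x$partition_name)) x$method else
                paste0(x$partition_name, ", ", x$method),
              x$fold_count, if (x$fold_count == 1L) "" else "s"))
  top <- order(abs(x$weights), decreasing = TRUE)[seq_len(min(10L, length(x$weights)))]
  top <- sort(top)
  cat("  largest |weight| at positions:", paste(names(x$weights)[top], collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated per-position weights (the "9-1" protocol)
#'
#' Splits the labeled pool into K parts; for each part, trains the
#' single-layer network on the other K-1 parts and evaluates on the held-out
#' part at score threshold 0. Returns the across-fold mean weight vector
#' (the per-position weight profile) together with the K held-out confusion
#' quadruples; their mean reproduces the fractional TP/FP/TN/FN convention
#' of per-fold-mean reporting.
#'
#' @param pool a labeled pool from [filter_by_affinity()].
#' @param partition a [diad_partition()].
#' @param folds a [make_folds()] plan (defaults to 10 stratified folds
#'   seeded from `config$seed`).
#' @param config a [training_config()].
#' @return List with `weights` (mean `position_weights`), `fold_weights`
#'   (K x (L-1) matrix), `fold_bias`, `fold_confusion` (data.frame fold /
#'   TP / FP / TN / FN), `mean_confusion` (a `confusion_counts`).
#' @export
cv_position_weights <- function(pool, partition, folds = NULL,
                                config = training_config()) {
  stopifnot(is_labeled_pool(pool), inherits(partition, "diad_partition"))
  if (is.null(folds)) folds <- make_folds(pool, K = 10L, seed = config$seed)
  stopifnot(inherits(folds, "fold_plan"), length(folds) == nrow(pool))
  K <- attr(folds, "K")
  x <- encode_pool(pool, partition)
  y <- pool$label
  sw <- if (config$use_sample_weights) abs(diad_scores(pool, partition)$w) else NULL

  fold_w <- matrix(NA_real_, nrow = K, ncol = ncol(x),
                   dimnames = list(seq_len(K), colnames(x)))
  fold_b <- numeric(K)
  conf <- data.frame(fold = seq_len(K), TP = 0, FP = 0, TN = 0, FN = 0)
  for (k in seq_len(K)) {
    tr <- folds != k
    fit <- train_single_layer(x[tr, , drop = FALSE], y[tr],
                              sample_weights = if (is.null(sw)) NULL else sw[tr],
                              config = config)
    fold_w[k, ] <- fit$weights
    fold_b[k] <- fit$bias
    s <- drop(x[!tr, , drop = FALSE] %*% fit$weights) + fit$bias
    pred <- classify(s, threshold = 0)
    cc <- confusion(pred, y[!tr])
    conf[k, c("TP", "FP", "TN", "FN")] <- cc[c("TP", "FP", "TN", "FN")]
  }
  mean_w <- colMeans(fold_w)
  weights <- structure(list(weights = mean_w, bias = mean(fold_b),
                            partition_name = partition$name, fold_count = K,
                            method = "logistic-newton", converged = TRUE,
                            iterations = NA_integer_),
                       class = "position_weights")
  mean_conf <- confusion_counts(TP = mean(conf$TP), FP = mean(conf$FP),
                                TN = mean(conf$TN), FN = mean(conf$FN))
  list(weights = weights, fold_weights = fold_w, fold_bias = fold_b,
       fold_confusion = conf, mean_confusion = mean_conf)
}

#' Per-position weight profile for a single-class subset
#'
#' For a positive-only or negative-only subset no classification target
#' exists, so the linear score is fit by ridge least squares against the
#' affinity value instead: positions whose diad class tracks affinity within
#' the subset receive large-magnitude weights, giving a profile comparable
#' to the cross-validated logistic one.
#'
#' @param pool a labeled pool (or any pool when `subset = "all"`).
#' @param subset `"positive"`, `"negative"`, or `"all"`.
#' @param partition a [diad_partition()].
#' @param config a [training_config()] (only `ridge` is used).
#' @return A `position_weights` object with `method = "ls-affinity"`.
#' @export
profile_weights_single_class <- function(pool, subset = c("positive", "negative", "all"),
                                         partition, config = training_config()) {
  subset <- match.arg(subset)
  stopifnot(inherits(pool, "oligo_pool"), inherits(partition, "diad_partition"))
  if (subset != "all") {
    if (!is_labeled_pool(pool)) stop("subset '", subset, "' requires a labeled pool")
    pool <- pool[pool$label == subset, , drop = FALSE]
    attr(pool, "L") <- attr(pool, "L")
    class(pool) <- c("labeled_pool", "oligo_pool", "data.frame")
  }
  if (nrow(pool) == 0L) stop("empty subset '", subset, "'")
  x <- encode_pool(pool, partition)
  X <- cbind(Intercept = 1, x)
  pen <- c(0, rep(max(config$ridge, 1e-8), ncol(x)))
  A <- crossprod(X)
  diag(A) <- diag(A) + pen
  beta <- solve(A, crossprod(X, pool$affinity))
  w <- drop(beta)[-1L]
  names(w) <- colnames(x)
  structure(list(weights = w, bias = unname(drop(beta)[1L]),
                 partition_name = partition$name, fold_count = 1L,
                 method = "ls-affinity", converged = TRUE,
                 iterations = NA_integer_),
            class = "position_weights")
}

#' Write a position-weight vector as TSV (position, weight)
#'
#' @param weights a `position_weights` object.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_position_weights <- function(weights, path) {
  stopifnot(inherits(weights, "position_weights"))
  utils::write.table(
    data.frame(position = as.integer(names(weights$weights)),
               weight = unname(weights$weights)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
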