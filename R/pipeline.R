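#' Configuration for an end-to-end experiment run
#'
#' Exactly one input source must be given: either `fasta`/`affinity` file
#' paths, or a [synthetic_spec()]. All randomness in a run (synthetic
#' generation, fold assignment) flows from the single `seed` through derived
#' per-stage seeds.
#'
#' @param fasta,affinity input file paths (both or neither).
#' @param synthetic a [synthetic_spec()] (mutually exclusive with files).
#' @param partition a partition name (`"4-4"`, `"4-3"`, `"5-4"`) or a
#'   [diad_partition()] object.
#' @param upper,lower affinity filter thresholds (strict; defaults 1, 0).
#' @param K number of cross-validation folds (default 10).
#' @param k number of key positions to select (default 10).
#' @param threshold decision threshold on the key-position score.
#' @param seed master seed for the run.
#' @param L declared sequence length for file input.
#' @param training a [training_config()]; its seed is overridden by the
#'   run's derived seed.
#' @param out_dir output directory for run artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(fasta = NULL, affinity = NULL, synthetic = NULL,
                       partition = "4-4", upper = 1, lower = 0,
                       K = 10L, k = 10L, threshold = 0, seed = 1L,
                       L = 150L, training = training_config(),
                       out_dir = tempfile("nucleokey_run_")) {
  file_input <- !is.null(fasta) || !is.null(affinity)
  if (file_input && (is.null(fasta) || is.null(affinity))) {
    stop("file input needs both fasta and affinity paths")
  }
  if (file_input == !is.null(synthetic)) {
    stop("give exactly one input source: (fasta, affinity) or synthetic")
  }
  if (is.character(partition)) {
    std <- standard_partitions()
    if (!partition %in% names(std)) {
      stop("unknown partition name '", partition, "'; standard names: ",
           paste(names(std), collapse = ", "))
    }
    partition <- std[[partition]]
  }
  stopifnot(inherits(partition, "diad_partition"),
            inherits(training, "training_config"))
  structure(list(fasta = fasta, affinity = affinity, synthetic = synthetic,
                 partition = partition, upper = upper, lower = lower,
                 K = as.integer(K), k = as.integer(k), threshold = threshold,
                 seed = as.integer(seed), L = as.integer(L),
                 training = training, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys mirror the [run_config()] arguments; `partition` may be a
#' standard name or a mapping with `positive`/`negative` diad lists and a
#' `name`; `synthetic` is a mapping of [synthetic_spec()] arguments;
#' `training` a mapping of [training_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.list(y$partition)) {
    y$partition <- diad_partition(y$partition$positive, y$partition$negative,
                                  name = y$partition$name %||% "custom")
  }
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_spec, y$synthetic)
  if (!is.null(y$training)) y$training <- do.call(training_config, y$training)
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derived per-stage seeds, kept well below 2^31
derive_seed <- function(seed, stage) (as.integer(seed) * 1009L + stage) %% 2000000011L

#' Run the full key-position analysis end to end
#'
#' Stages: read or generate the pool, filter by affinity, compute diad
#' frequency profiles (all/positive/negative), cross-validated single-layer
#' training, key-position selection, key-position-only classification of
#' every held-out fold, metrics. Each stage logs record counts and elapsed
#' time to `run.log`. Artifacts written to `config$out_dir`:
#'
#' * `profile_<subset>.tsv` — the three frequency profiles
#' * `weights_<partition>.tsv` — the across-fold mean position weights
#' * `key_positions_<partition>.tsv` / `.bed` — the selected key positions
#' * `fold_confusion.tsv` — per-fold held-out confusion counts (full model
#'   and key-restricted)
#' * `metrics_<partition>.tsv` — the Table-style summary row
#' * `manifest.json` — config, seed, and md5 hashes of inputs and outputs
#'
#' Two runs with identical config and seed produce byte-identical artifacts
#' (timestamps appear only in `run.log`).
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the run directory and the in-memory
#'   results (`pool`, `labeled`, `cv`, `keys`, `report`, `manifest`).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  stage <- function(name, n_in, n_out, t0) {
    line <- sprintf("[%s] stage=%s in=%d out=%d elapsed=%.2fs",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), name, n_in, n_out,
                    as.numeric(proc.time()[["elapsed"]]) - t0)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  pn <- config$partition$name

  t0 <- proc.time()[["elapsed"]]
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    spec$seed <- derive_seed(config$seed, 1L)
    sim <- generate_pool(spec, config$partition)
    pool <- sim$pool
    inputs <- list(synthetic = spec[setdiff(names(spec), "base_freq")],
                   base_freq = as.list(spec$base_freq))
  } else {
    pool <- read_pool(config$fasta, config$affinity, L = config$L)
    inputs <- list(fasta = unname(tools::md5sum(config$fasta)),
                   affinity = unname(tools::md5sum(config$affinity)))
  }
  stage("input", nrow(pool), nrow(pool), t0)

  t0 <- proc.time()[["elapsed"]]
  labeled <- filter_by_affinity(pool, upper = config$upper, lower = config$lower)
  if (nrow(labeled) == 0L) stop("stage=filter: no records survive the affinity filter")
  stage("filter", nrow(pool), nrow(labeled), t0)

  t0 <- proc.time()[["elapsed"]]
  outputs <- character(0)
  for (s in c("all", "positive", "negative")) {
    p <- file.path(config$out_dir, paste0("profile_", s, ".tsv"))
    write_diad_profile(position_frequency(labeled, s), p)
    outputs <- c(outputs, p)
  }
  stage("profiles", nrow(labeled), nrow(labeled), t0)

  t0 <- proc.time()[["elapsed"]]
  tr <- config$training
  tr$seed <- derive_seed(config$seed, 2L)
  folds <- make_folds(labeled, K = config$K, seed = tr$seed)
  cv <- cv_position_weights(labeled, config$partition, folds, tr)
  wpath <- file.path(config$out_dir, paste0("weights_", pn, ".tsv"))
  write_position_weights(cv$weights, wpath)
  outputs <- c(outputs, wpath)
  stage("cv_train", nrow(labeled), config$K, t0)

  t0 <- proc.time()[["elapsed"]]
  keys <- select_key_positions(cv$weights, k = config$k)
  kpath <- file.path(config$out_dir, paste0("key_positions_", pn, ".tsv"))
  write_key_positions(keys, kpath, bed_path = sub("\\.tsv$", ".bed", kpath))
  outputs <- c(outputs, kpath, sub("\\.tsv$", ".bed", kpath))
  stage("select_keys", length(cv$weights$weights), config$k, t0)

  t0 <- proc.time()[["elapsed"]]
  keyeval <- cv_keypos_evaluation(labeled, config$partition, folds, cv, keys,
                                  threshold = config$threshold)
  report <- metrics(keyeval$mean_confusion)
  fc <- cbind(cv$fold_confusion,
              stats::setNames(keyeval$fold_confusion[, c("TP", "FP", "TN", "FN")],
                              c("key_TP", "key_FP", "key_TN", "key_FN")))
  fcpath <- file.path(config$out_dir, "fold_confusion.tsv")
  utils::write.table(fc, fcpath, sep = "\t", quote = FALSE, row.names = FALSE)
  mpath <- file.path(config$out_dir, paste0("metrics_", pn, ".tsv"))
  write_metric_report(report, mpath, partition_name = pn, keys = keys)
  outputs <- c(outputs, fcpath, mpath)
  stage("classify", nrow(labeled), nrow(labeled), t0)

  manifest <- list(
    package = "nucleokey",
    seed = config$seed,
    partition = list(name = pn,
                     positive = config$partition$positive,
                     negative = config$partition$negative),
    filter = list(upper = config$upper, lower = config$lower),
    K = config$K, k = config$k, threshold = config$threshold,
    training = unclass(tr),
    inputs = inputs,
    outputs = as.list(stats::setNames(unname(tools::md5sum(outputs)),
                                      basename(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, log_path)
  invisible(list(out_dir = config$out_dir, pool = pool, labeled = labeled,
                 folds = folds, cv = cv, keys = keys, report = report,
                 manifest = manifest))
}

#' Held-out evaluation of the key-position classifier across folds
#'
#' By default reuses the per-fold weights from [cv_position_weights()]:
#' fold k's weights, masked to the key positions, classify fold k's
#' held-out records. With `refit = TRUE` the single-layer network is
#' instead retrained per fold on the key-position features only. The mean
#' of the K confusion quadruples feeds the reported metrics.
#'
#' @param pool the labeled pool the CV ran on.
#' @param partition the [diad_partition()].
#' @param folds the [make_folds()] plan used for the CV.
#' @param cv the result of [cv_position_weights()].
#' @param keys a `key_positions` object.
#' @param threshold decision threshold (default 0).
#' @param refit retrain per fold restricted to the key features instead of
#'   masking the full-model weights (default FALSE).
#' @param config a [training_config()], used only when `refit = TRUE`.
#' @return List with `fold_confusion` (data.frame) and `mean_confusion`.
#' @export
cv_keypos_evaluation <- function(pool, partition, folds, cv, keys,
                                 threshold = 0, refit = FALSE,
                                 config = training_config()) {
  stopifnot(is_labeled_pool(pool), inherits(folds, "fold_plan"))
  K <- attr(folds, "K")
  x <- encode_pool(pool, partition)
  keep <- as.integer(keys)
  mask <- rep(0, ncol(x))
  mask[keep] <- 1
  sw <- if (refit && config$use_sample_weights) abs(diad_scores(pool, partition)$w)
  conf <- data.frame(fold = seq_len(K), TP = 0, FP = 0, TN = 0, FN = 0)
  for (kf in seq_len(K)) {
    held <- folds == kf
    if (refit) {
      fit <- train_single_layer(x[!held, keep, drop = FALSE], pool$label[!held],
                                sample_weights = if (is.null(sw)) NULL else sw[!held],
                                config = config)
      s <- drop(x[held, keep, drop = FALSE] %*% fit$weights) + fit$bias
    } else {
      s <- drop(x[held, , drop = FALSE] %*% (cv$fold_weights[kf, ] * mask)) +
        cv$fold_bias[kf]
    }
    cc <- confusion(classify(s, threshold), pool$label[held])
    conf[kf, c("TP", "FP", "TN", "FN")] <- cc[c("TP", "FP", "TN", "FN")]
  }
  list(fold_confusion = conf,
       mean_confusion = confusion_counts(TP = mean(conf$TP), FP = mean(conf$FP),
                                         TN = mean(conf$TN), FN = mean(conf$FN)))
}

#' Run the three standard experiments (4-4, 4-3, 5-4)
#'
#' Loops [run_experiment()] over the three standard diad partitions (one
#' subdirectory each), then compares their key-position sets and writes
#' `compare_keys.tsv` at the top level.
#'
#' @param config a [run_config()]; its `partition` is ignored and its
#'   `out_dir` becomes the parent directory.
#' @param tolerance tolerant-match distance for the comparison (default 1).
#' @return Invisibly, list of the three run results plus `comparison`.
#' @export
run_standard_experiments <- function(config, tolerance = 1L) {
  stopifnot(inherits(config, "run_config"))
  parent <- config$out_dir
  dir.create(parent, recursive = TRUE, showWarnings = FALSE)
  runs <- list()
  for (part in standard_partitions()) {
    cfg <- config
    cfg$partition <- part
    cfg$out_dir <- file.path(parent, gsub("[^0-9A-Za-z]+", "_", part$name))
    runs[[part$name]] <- run_experiment(cfg)
  }
  keysets <- lapply(runs, function(r) r$keys)
  comparison <- compare_key_sets(keysets, tolerance = tolerance)
  utils::write.table(comparison$pairwise, file.path(parent, "compare_keys.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(runs, list(comparison = comparison)))
}

#' Metrics from externally supplied confusion counts
#'
#' Thin entry point: feed per-fold mean confusion counts (fractional values
#' are fine) straight into the metric formulas.
#'
#' @param TP,FP,TN,FN non-negative counts, or a single `confusion_counts`
#'   object as the first argument.
#' @return A `metric_report`.
#' @export
#' @examples
#' metrics_only(786.3, 367.5, 1763.1, 105.6)  # Acc 84.3, Sen 88.2, PPV 68.1, MCC 66.6
metrics_only <- function(TP, FP = NULL, TN = NULL, FN = NULL) {
  if (inherits(TP, "confusion_counts")) return(metrics(TP))
  metrics(confusion_counts(TP, FP, TN, FN))
}
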