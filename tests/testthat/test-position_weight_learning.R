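test_that("ternary encoding follows the partition and matches count_diads", {
  part <- standard_partitions()[["4-4"]]
  x <- encode_sequence("CCAA", part)
  expect_equal(unname(x), c(1, 0, -1))
  expect_equal(unname(encode_sequence("ACGC", part)), c(0, 1, 1))
  # a sequence with no partition diads encodes to all zeros
  expect_equal(unname(encode_sequence("ACAC", part)), c(0, 0, 0))
  pool <- random_pool(40, L = 60, seed = 31)
  X <- encode_pool(pool, part)
  expect_equal(dim(X), c(40L, 59L))
  for (i in seq_len(40)) {
    cd <- count_diads(pool$sequence[i], part)
    expect_equal(sum(X[i, ] == 1), unname(cd[["n1"]]))
    expect_equal(sum(X[i, ] == -1), unname(cd[["n2"]]))
  }
})

test_that("fold assignment is balanced, stratified, and seed-deterministic", {
  pool <- random_pool(101, L = 10, seed = 32,
                      affinity = c(rep(2, 60), rep(-1, 41)))
  lab <- filter_by_affinity(pool)
  f <- make_folds(lab, K = 10, seed = 5)
  sizes <- tabulate(f, 10)
  expect_equal(sort(sizes), c(rep(10L, 9L), 11L))
  # stratification: positives spread within one of each other
  pos_sizes <- tabulate(f[lab$label == "positive"], 10)
  expect_lte(diff(range(pos_sizes)), 1L)
  expect_identical(as.integer(f), as.integer(make_folds(lab, K = 10, seed = 5)))
  expect_false(identical(as.integer(f), as.integer(make_folds(lab, K = 10, seed = 6))))
  # exact division
  f100 <- make_folds(lab[1:100, ], K = 10, seed = 1)
  expect_equal(tabulate(f100, 10), rep(10L, 10L))
  expect_error(make_folds(lab[1:5, ], K = 10, seed = 1), "fewer than K")
})

test_that("training recovers a single fully informative position", {
  part <- standard_partitions()[["4-4"]]
  set.seed(33)
  n <- 300
  base <- random_sequences(n, 30, seed = 33)
  label <- rep(c("positive", "negative"), length.out = n)
  # plant a deterministic diad at start position 10: class-consistent
  planted <- ifelse(label == "positive", "GG", "AA")
  seqs <- paste0(substr(base, 1, 9), planted, substr(base, 12, 30))
  pool <- oligo_pool(sprintf("p%03d", 1:n), seqs,
                     ifelse(label == "positive", 2, -1), L = 30)
  lab <- filter_by_affinity(pool)
  X <- encode_pool(lab, part)
  fit <- train_single_layer(X, lab$label, config = training_config())
  expect_true(fit$converged)
  expect_equal(which.max(abs(fit$weights)), 10L, ignore_attr = TRUE)
  expect_gt(fit$weights[[10]], 0)
})

test_that("single-class input errors and points to the single-class profiler", {
  pool <- random_pool(20, L = 20, seed = 34, affinity = rep(2, 20))
  lab <- filter_by_affinity(pool)
  X <- encode_pool(lab, standard_partitions()[["4-4"]])
  expect_error(train_single_layer(X, lab$label),
               "profile_weights_single_class")
})

test_that("duplicating every record leaves the fitted weights unchanged", {
  pool <- random_pool(80, L = 40, seed = 35, affinity = rnorm(80, 0.5, 1.5))
  lab <- filter_by_affinity(pool)
  part <- standard_partitions()[["4-4"]]
  X <- encode_pool(lab, part)
  sw <- abs(diad_scores(lab, part)$w)
  fit1 <- train_single_layer(X, lab$label, sw)
  Xd <- rbind(X, X)
  fit2 <- train_single_layer(Xd, c(lab$label, lab$label), c(sw, sw))
  expect_equal(fit2$weights, fit1$weights, tolerance = 1e-6)
  expect_equal(fit2$bias, fit1$bias, tolerance = 1e-6)
})

test_that("training is bit-deterministic given identical data and config", {
  pool <- random_pool(100, L = 50, seed = 36, affinity = rnorm(100, 0.5, 1.5))
  lab <- filter_by_affinity(pool)
  part <- standard_partitions()[["4-3"]]
  X <- encode_pool(lab, part)
  fit1 <- train_single_layer(X, lab$label)
  fit2 <- train_single_layer(X, lab$label)
  expect_identical(fit1$weights, fit2$weights)
  expect_identical(fit1$bias, fit2$bias)
})

test_that("cross-validation conserves held-out sizes and averages weights", {
  sim <- generate_pool(synthetic_spec(n_sequences = 300, seed = 37))
  lab <- filter_by_affinity(sim$pool)
  part <- standard_partitions()[["4-4"]]
  folds <- make_folds(lab, K = 5, seed = 37)
  cv <- cv_position_weights(lab, part, folds, training_config(seed = 37))
  for (k in 1:5) {
    row <- cv$fold_confusion[k, ]
    expect_equal(row$TP + row$FP + row$TN + row$FN, sum(folds == k))
  }
  expect_equal(cv$weights$weights, colMeans(cv$fold_weights))
  expect_equal(cv$weights$fold_count, 5L)
  # per-fold mean counts feed the fractional reporting convention
  expect_equal(unname(cv$mean_confusion[["TP"]]), mean(cv$fold_confusion$TP))
})

test_that("a 2-fold toy pool yields confusion quadruples summing to fold sizes", {
  pool <- oligo_pool(paste0("t", 1:4),
                     c("CCCCCC", "GGGGGG", "AAAAAA", "TTTTTT"),
                     c(2, 2, -1, -1), L = 6)
  lab <- filter_by_affinity(pool)
  folds <- make_folds(lab, K = 2, seed = 1)
  cv <- cv_position_weights(lab, standard_partitions()[["4-4"]], folds,
                            training_config(seed = 1))
  sums <- rowSums(cv$fold_confusion[, c("TP", "FP", "TN", "FN")])
  expect_equal(unname(sums), c(2, 2))
})

test_that("single-class least-squares profile recovers a planted position", {
  part <- standard_partitions()[["4-4"]]
  set.seed(38)
  n <- 400
  base <- random_sequences(n, 30, seed = 38)
  # positive-only subset: affinity rises when position 7 carries a GC diad
  has_sig <- runif(n) < 0.5
  seqs <- ifelse(has_sig,
                 paste0(substr(base, 1, 6), "GC", substr(base, 9, 30)),
                 base)
  aff <- 1.2 + 0.8 * has_sig + rnorm(n, 0, 0.1)
  pool <- oligo_pool(sprintf("q%03d", 1:n), seqs, aff, L = 30)
  lab <- filter_by_affinity(pool)
  fit <- profile_weights_single_class(lab, "positive", part)
  expect_equal(fit$method, "ls-affinity")
  expect_equal(which.max(abs(fit$weights)), 7L, ignore_attr = TRUE)
  # constant affinity leaves (almost) nothing to fit
  pool0 <- oligo_pool(sprintf("c%03d", 1:n), seqs, rep(1.5, n), L = 30)
  lab0 <- filter_by_affinity(pool0)
  fit0 <- profile_weights_single_class(lab0, "positive", part)
  expect_lt(max(abs(fit0$weights)), 1e-6)
  expect_equal(fit0$bias, 1.5, tolerance = 1e-6)
})
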