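toy_weights <- function(w, bias = 0, name = "4-4") {
  structure(list(weights = setNames(w, seq_along(w)), bias = bias,
                 partition_name = name, fold_count = 1L,
                 method = "logistic-newton", converged = TRUE,
                 iterations = 1L),
            class = "position_weights")
}

test_that("key-restricted score equals the full score with non-key weights zeroed", {
  part <- standard_partitions()[["4-4"]]
  pool <- random_pool(200, L = 30, seed = 51)
  set.seed(51)
  w <- toy_weights(rnorm(29), bias = 0.3)
  keys <- key_position_set(c(3, 7, 15, 22))
  restricted <- score_sequences(pool, w, keys, part)
  masked <- w
  masked$weights[setdiff(1:29, as.integer(keys))] <- 0
  full_masked <- score_sequences(pool, masked, NULL, part)
  expect_equal(restricted, full_masked)
  # empty key set scores the bias for every record
  none <- score_sequences(pool, w, integer(0), part)
  expect_equal(unname(none), rep(0.3, 200))
  expect_error(score_sequences(pool, w, c(1, 40), part), "outside")
})

test_that("classification thresholds strictly and sweeps monotonically", {
  expect_equal(classify(0.7), "positive")
  expect_equal(classify(0), "negative")  # boundary is negative
  expect_error(classify(NA_real_), "finite")
  set.seed(52)
  scores <- rnorm(500)
  counts <- vapply(sort(scores), function(th) sum(classify(scores, th) == "positive"),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("confusion tallies the standard 2x2 table", {
  labels <- c(rep("positive", 6), rep("negative", 4))
  perfect <- confusion(labels, labels)
  expect_equal(unname(perfect[c("TP", "FP", "TN", "FN")]), c(6, 0, 4, 0))
  inverted <- confusion(ifelse(labels == "positive", "negative", "positive"), labels)
  expect_equal(unname(inverted[c("TP", "FP", "TN", "FN")]), c(0, 4, 0, 6))
  expect_error(confusion("positive", labels), "length")
  set.seed(53)
  pred <- sample(c("positive", "negative"), 200, replace = TRUE)
  lab <- sample(c("positive", "negative"), 200, replace = TRUE)
  cc <- confusion(pred, lab)
  hand <- c(TP = 0, FP = 0, TN = 0, FN = 0)
  for (i in 1:200) {
    cell <- if (pred[i] == "positive" && lab[i] == "positive") "TP"
            else if (pred[i] == "positive") "FP"
            else if (lab[i] == "positive") "FN" else "TN"
    hand[cell] <- hand[cell] + 1
  }
  expect_equal(unclass(cc), hand, ignore_attr = TRUE)
})

test_that("metric formulas handle perfect, scaled and degenerate counts", {
  perfect <- metrics(confusion_counts(5, 0, 7, 0))
  expect_equal(unname(as.numeric(perfect)), c(100, 100, 100, 100))
  base <- confusion_counts(30, 10, 40, 20)
  m1 <- metrics(base)
  m2 <- metrics(confusion_counts(30 * 2.5, 10 * 2.5, 40 * 2.5, 20 * 2.5))
  expect_equal(as.numeric(m1), as.numeric(m2))  # scale invariance
  # label swap (TP<->TN, FP<->FN) fixes Acc and MCC
  swapped <- metrics(confusion_counts(40, 20, 30, 10))
  expect_equal(m1[["acc"]], swapped[["acc"]])
  expect_equal(m1[["mcc"]], swapped[["mcc"]])
  # zero denominator flags the metric instead of crashing
  noneg <- metrics(confusion_counts(3, 0, 0, 2))
  expect_true(is.na(noneg[["ppv"]]) || noneg[["ppv"]] >= 0)
  nopos <- metrics(confusion_counts(0, 0, 5, 0))
  expect_true(is.na(nopos[["sen"]]))
  expect_true("sen" %in% attr(nopos, "undefined"))
  expect_error(metrics(confusion_counts(0, 0, 0, 0)), "zero")
})

test_that("metrics stay inside their ranges over random counts", {
  set.seed(54)
  for (i in 1:200) {
    cc <- confusion_counts(runif(1, 0, 50), runif(1, 0, 50),
                           runif(1, 0, 50), runif(1, 0, 50))
    m <- metrics(cc)
    vals <- unclass(m)
    expect_true(all(vals[c("acc", "sen", "ppv")] >= 0 &
                      vals[c("acc", "sen", "ppv")] <= 100, na.rm = TRUE))
    if (!is.na(vals[["mcc"]])) expect_true(abs(vals[["mcc"]]) <= 100)
  }
})

test_that("the full evaluator ties scores, predictions, counts and report together", {
  sim <- generate_pool(synthetic_spec(n_sequences = 400, seed = 55))
  lab <- filter_by_affinity(sim$pool)
  part <- standard_partitions()[["4-4"]]
  folds <- make_folds(lab, K = 5, seed = 55)
  cv <- cv_position_weights(lab, part, folds, training_config(seed = 55))
  keys <- select_key_positions(cv$weights, 10)
  ev <- evaluate_keypos_classifier(lab, cv$weights, keys, part)
  expect_equal(length(ev$scores), nrow(lab))
  expect_equal(sum(ev$counts), nrow(lab))
  expect_equal(ev$report, metrics(ev$counts))
  # the key-position classifier must beat the majority-class baseline
  baseline <- 100 * max(table(lab$label)) / nrow(lab)
  expect_gt(ev$report[["acc"]], baseline)
})
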