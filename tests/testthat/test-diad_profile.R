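test_that("the three standard partitions carry the expected diad sets", {
  std <- standard_partitions()
  expect_setequal(std[["4-4"]]$positive, c("CC", "CG", "GC", "GG"))
  expect_setequal(std[["4-4"]]$negative, c("AA", "AT", "TA", "TT"))
  expect_setequal(std[["4-3"]]$negative, c("AA", "AT", "TT"))  # TA dropped
  expect_setequal(std[["4-3"]]$positive, std[["4-4"]]$positive)
  expect_setequal(std[["5-4"]]$positive, c("AC", "CC", "CG", "GC", "GG"))  # AC added
  expect_setequal(std[["5-4"]]$negative, std[["4-4"]]$negative)
})

test_that("diad partitions reject overlap, non-diads and empty sets", {
  expect_error(diad_partition(c("CC", "AA"), c("AA")), "overlap")
  expect_error(diad_partition("CCX", "AA"), "not diads")
  expect_error(diad_partition(character(0), "AA"), "non-empty")
})

test_that("degenerate pools give all-mass frequency columns", {
  pool <- oligo_pool(paste0("s", 1:5), rep("ACGTACGT", 5), rep(0, 5), L = 8)
  prof <- position_frequency(pool, "all")
  expect_equal(dim(prof), c(16L, 7L))
  expect_equal(unname(prof["AC", 1]), 1)
  expect_equal(sum(prof[, 1] == 0), 15L)
  # forced 2-sequence case
  pool2 <- oligo_pool(c("a", "b"), c("AAAA", "AATT"), c(0, 0), L = 4)
  prof2 <- position_frequency(pool2, "all")
  expect_equal(unname(prof2["AA", 1]), 1)
  expect_equal(unname(prof2["AA", 3]), 0.5)
  expect_equal(unname(prof2["TT", 3]), 0.5)
})

test_that("position frequencies match the exhaustive tally oracle and normalize", {
  pool <- random_pool(20, L = 40, seed = 21)
  prof <- position_frequency(pool, "all")
  oracle <- oracle_position_frequency(pool$sequence, 40L)
  expect_equal(unclass(prof), oracle, ignore_attr = TRUE)
  expect_true(all(abs(colSums(prof) - 1) < 1e-9))
})

test_that("subset profiles use only that subset and refuse empty subsets", {
  pool <- random_pool(60, L = 30, seed = 22, affinity = rnorm(60, 0.5, 1.2))
  lab <- filter_by_affinity(pool)
  pos <- position_frequency(lab, "positive")
  expect_equal(attr(pos, "n_sequences"), sum(lab$label == "positive"))
  expect_equal(unclass(pos),
               oracle_position_frequency(lab$sequence[lab$label == "positive"], 30L),
               ignore_attr = TRUE)
  only_pos <- lab[lab$label == "positive", ]
  expect_error(position_frequency(only_pos, "negative"), "empty subset")
})

test_that("count_diads counts overlapping occurrences per the scan oracle", {
  std <- standard_partitions()
  expect_equal(count_diads("CCCC", std[["4-4"]]), c(n1 = 3L, n2 = 0L))
  # ACGT carries CG at start 2 (positive in every partition) plus AC under 5-4
  expect_equal(count_diads("ACGT", std[["4-4"]]), c(n1 = 1L, n2 = 0L))
  expect_equal(count_diads("ACGT", std[["5-4"]]), c(n1 = 2L, n2 = 0L))
  expect_error(count_diads("A", std[["4-4"]]), "length >= 2")
  seqs <- random_sequences(100, 150, seed = 23)
  for (part in std) {
    got <- t(vapply(seqs, count_diads, c(n1 = 0L, n2 = 0L), partition = part))
    want <- t(vapply(seqs, oracle_count_diads, c(n1 = 0L, n2 = 0L), partition = part))
    expect_equal(got, want)
  }
})

test_that("affinity weight follows the two-branch definition and its |af| form", {
  expect_equal(affinity_weight(0, 7, 2), 0)
  expect_equal(affinity_weight(2, 5, 3), 4)
  expect_equal(affinity_weight(-2, 5, 3), 4)
  expect_error(affinity_weight(NaN, 1, 1), "finite")
  expect_error(affinity_weight(1, -1, 0), "non-negative")
})

test_that("pool-level diad scores agree with record-by-record branch evaluation", {
  pool <- random_pool(50, L = 25, seed = 24, affinity = rnorm(50))
  part <- standard_partitions()[["5-4"]]
  sc <- diad_scores(pool, part)
  for (i in seq_len(nrow(pool))) {
    cd <- oracle_count_diads(pool$sequence[i], part)
    af <- pool$affinity[i]
    w <- if (af >= 0) af * (cd[["n1"]] - cd[["n2"]]) else af * (cd[["n2"]] - cd[["n1"]])
    expect_equal(sc$n1[i], unname(cd[["n1"]]))
    expect_equal(sc$n2[i], unname(cd[["n2"]]))
    expect_equal(sc$w[i], w)
  }
  expect_true(all(sc$n1 + sc$n2 <= 24))
})

test_that("profiles serialize to long-format TSV", {
  pool <- random_pool(5, L = 10, seed = 25)
  prof <- position_frequency(pool, "all")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diad_profile(prof, path)
  long <- read.delim(path)
  expect_equal(nrow(long), 16L * 9L)
  expect_equal(sum(long$frequency), 9)  # one unit of mass per position
})
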