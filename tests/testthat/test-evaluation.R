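test_that("confusion counts follow the definitions", {
  gold <- GoldStandard(rep("R1", 6), paste0("T", 1:6), rep(1L, 6))
  # called = positives exactly
  et <- EdgeTable(rep("R1", 6), paste0("T", 1:6), rep(1, 6))
  cc <- confusionCounts(et, gold)
  expect_equal(cc$precision, 1)
  expect_equal(cc$recall, 1)

  # 4 calls, 3 true, 6 gold positives -> precision 0.75, recall 0.5
  gold2 <- GoldStandard(rep("R1", 8), paste0("T", 1:8),
                        c(rep(1L, 6), 0L, 0L))
  et2 <- EdgeTable(rep("R1", 4), paste0("T", c(1, 2, 3, 7)), rep(1, 4))
  cc2 <- confusionCounts(et2, gold2)
  expect_equal(cc2$tp, 3L)
  expect_equal(cc2$fp, 1L)
  expect_equal(cc2$precision, 0.75)
  expect_equal(cc2$recall, 0.5)
  expect_equal(cc2$tp + cc2$fp + cc2$fn + cc2$tn, 8L)  # |universe|

  # empty calls: precision undefined (NA), recall 0
  cc0 <- confusionCounts(EdgeTable(), gold)
  expect_true(is.na(cc0$precision))
  expect_equal(cc0$recall, 0)
  expect_equal(cc0$tp, 0L)
  expect_equal(cc0$fp, 0L)
})

test_that("labeled universe ignores unlisted calls, all universe counts them", {
  gold <- GoldStandard(c("R1", "R1"), c("T1", "T2"), c(1L, 0L))
  et <- EdgeTable(c("R1", "R2"), c("T1", "T9"), c(1, 1))
  lab <- confusionCounts(et, gold, universe = "labeled")
  expect_equal(lab$tp, 1L)
  expect_equal(lab$fp, 0L)       # R2 -> T9 is unlabelled, ignored
  all <- confusionCounts(et, gold, universe = "all")
  expect_equal(all$fp, 1L)       # now a false positive
  expect_equal(all$tp + all$fp + all$fn + all$tn, 3L)
})

test_that("precision/recall sweep matches direct confusion at each cutoff", {
  s <- matrix(c(1, 0.4), 2, 1, dimnames = list(c("R1", "R2"), "T1"))
  sg <- matrix(0L, 2, 1, dimnames = dimnames(s))
  freq <- new("FrequencyTable", score = s, sign = sg, trials = 10L)
  gold <- GoldStandard(c("R1", "R2"), c("T1", "T1"), c(1L, 0L))

  sw <- precisionRecallSweep(freq, gold, cutoffs = c(0, 1))
  expect_equal(sw$precision, c(0.5, 1))     # both called, then true pair only
  expect_equal(sw$cutoff, c(0, 1))          # ordered as given

  one <- precisionRecallSweep(freq, gold, cutoffs = 0.5)
  direct <- confusionCounts(thresholdEdges(freq, 0.5), gold, cutoff = 0.5)
  expect_equal(one, direct)

  expect_error(precisionRecallSweep(freq, gold, numeric(0)), "non-empty")
  expect_error(precisionRecallSweep(freq, gold, 1.2), "0, 1")
})

test_that("rank AUC equals the brute-force pairwise estimator", {
  # 2 positives {0.9, 0.4}, 2 negatives {0.6, 0.1} -> 3 of 4 comparisons won
  s <- matrix(c(0.9, 0.4, 0.6, 0.1), 4, 1,
              dimnames = list(paste0("R", 1:4), "T1"))
  freq <- new("FrequencyTable", score = s,
              sign = matrix(0L, 4, 1, dimnames = dimnames(s)), trials = 10L)
  gold <- GoldStandard(paste0("R", 1:4), rep("T1", 4), c(1L, 1L, 0L, 0L))
  expect_equal(rocAUC(freq, gold), 0.75)
  expect_equal(rocAUC(freq, gold),
               bruteForceAUC(s[, 1], c(1, 1, 0, 0)))

  # separable scores give AUC 1
  s2 <- matrix(c(0.9, 0.8, 0.3, 0.2), 4, 1, dimnames = dimnames(s))
  freq2 <- new("FrequencyTable", score = s2,
               sign = matrix(0L, 4, 1, dimnames = dimnames(s)), trials = 10L)
  expect_equal(rocAUC(freq2, gold), 1)

  # random instances with ties, <= 100 pairs: exact agreement
  for (r in 1:20) {
    set.seed(300 + r)
    n <- sample(10:100, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0 || sum(lb) == n) next
    sm <- matrix(sc, n, 1, dimnames = list(paste0("R", 1:n), "T1"))
    fq <- new("FrequencyTable", score = sm,
              sign = matrix(0L, n, 1, dimnames = dimnames(sm)), trials = 10L)
    gd <- GoldStandard(paste0("R", 1:n), rep("T1", n), as.integer(lb))
    expect_equal(rocAUC(fq, gd), bruteForceAUC(sc, lb))
  }

  # single-class gold is an error
  gpos <- GoldStandard(paste0("R", 1:4), rep("T1", 4), rep(1L, 4))
  expect_error(rocAUC(freq, gpos), "positive and .* negative")
})

test_that("label permutation drives mean AUC to 1/2", {
  set.seed(77)
  n <- 60
  sc <- runif(n)
  sm <- matrix(sc, n, 1, dimnames = list(paste0("R", 1:n), "T1"))
  fq <- new("FrequencyTable", score = sm,
            sign = matrix(0L, n, 1, dimnames = dimnames(sm)), trials = 10L)
  aucs <- vapply(1:1000, function(i) {
    lb <- sample(c(rep(1L, 20), rep(0L, 40)))
    rocAUC(fq, GoldStandard(paste0("R", 1:n), rep("T1", n), lb))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.01)  # ~4 Monte-Carlo sds
})

test_that("pairs the engine never scored count as zeros in the AUC universe", {
  s <- matrix(0.8, 1, 1, dimnames = list("R1", "T1"))
  freq <- new("FrequencyTable", score = s,
              sign = matrix(0L, 1, 1, dimnames = dimnames(s)), trials = 10L)
  # gold mentions a pair outside the score table; it scores 0
  gold <- GoldStandard(c("R1", "R9"), c("T1", "T1"), c(1L, 0L))
  expect_equal(rocAUC(freq, gold), 1)
  gold2 <- GoldStandard(c("R9", "R1"), c("T1", "T1"), c(1L, 0L))
  expect_equal(rocAUC(freq, gold2), 0)
})

test_that("evaluation report writes one row per cutoff plus AUC line", {
  s <- matrix(c(1, 0.4), 2, 1, dimnames = list(c("R1", "R2"), "T1"))
  freq <- new("FrequencyTable", score = s,
              sign = matrix(0L, 2, 1, dimnames = dimnames(s)), trials = 10L)
  gold <- GoldStandard(c("R1", "R2"), c("T1", "T1"), c(1L, 0L))
  sw <- precisionRecallSweep(freq, gold, cutoffs = seq(0.1, 1, by = 0.1))
  f <- tempfile(fileext = ".tsv")
  writeEvaluationReport(sw, f, auc = rocAUC(freq, gold))
  lines <- readLines(f)
  expect_length(lines, 1 + 10 + 1)          # header, 10 cutoffs, AUC
  expect_match(lines[length(lines)], "^# AUC\t1.000000$")
})
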