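test_that("partitions are disjoint, covering, and balanced", {
  p <- partitionSamples(8, 2, seed = 1L)
  expect_length(p, 2L)
  expect_equal(lengths(p), c(4L, 4L))
  expect_setequal(unlist(p), 1:8)

  # 805 = 8 * 100 + 5: five groups of 101, three of 100
  p <- partitionSamples(805, 8, seed = 3L)
  expect_equal(sort(lengths(p), decreasing = TRUE),
               c(rep(101L, 5), rep(100L, 3)))
  expect_setequal(unlist(p), 1:805)

  expect_error(partitionSamples(5, 6), "exceeds n_obs")
  expect_error(partitionSamples(5, 0), "m must be")
  # m = 1 is the degenerate whole-sample group
  expect_setequal(partitionSamples(5, 1, seed = 2L)[[1]], 1:5)
})

test_that("group membership is uniform across seeds", {
  # counting oracle: over many seeded partitions each index lands in group 1
  # with probability ~ 1/m
  n <- 12L; m <- 3L; reps <- 1000L
  inG1 <- matrix(FALSE, reps, n)
  for (r in seq_len(reps)) {
    p <- partitionSamples(n, m, seed = r)
    expect_setequal(unlist(p), seq_len(n))   # disjoint cover each repeat
    inG1[r, p[[1]]] <- TRUE
  }
  freq <- colMeans(inG1)
  ci <- 4 * sqrt((1 / m) * (1 - 1 / m) / reps)
  expect_true(all(abs(freq - 1 / m) < ci))
})

test_that("partitions are a deterministic function of the seed", {
  expect_identical(partitionSamples(60, 4, seed = 9L),
                   partitionSamples(60, 4, seed = 9L))
  expect_false(identical(partitionSamples(60, 4, seed = 9L),
                         partitionSamples(60, 4, seed = 10L)))
})

test_that("runTrial recovers a planted regulator and handles degenerate cases", {
  fx <- makeFixtureMatrix(nObs = 200L, nGenes = 8L, nReg = 3L,
                          noiseSd = 0.1, seed = 1L)
  em <- suppressWarnings(standardizeExpression(fx$em))
  # tgt1 depends on sources fx$truth[[1]]
  sel <- runTrial(em, 1:100, "tgt1", fx$sources, enConfig(), seed = 1L)
  expect_true(all(fx$sources[fx$truth[[1]]] %in% sel$ids))

  # pure-noise target: near-always empty under the sparse 1-SE selector
  set.seed(11)
  v <- matrix(rnorm(120 * 6), 120, 6,
              dimnames = list(NULL, paste0("g", 1:6)))
  emn <- ExpressionMatrix(v)
  empty <- vapply(1:40, function(r) {
    length(runTrial(emn, 1:120, "g6", paste0("g", 1:5),
                    enConfig(lambdaRule = "1se"), seed = r)$ids) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.95)

  # empty candidate set is vacuous, not an error
  sel0 <- runTrial(em, 1:60, "tgt1", character(0), enConfig(), seed = 1L)
  expect_length(sel0$ids, 0L)
  # the target may not be its own candidate
  expect_error(runTrial(em, 1:60, "tgt1", c("tgt1", "src1"), enConfig(), 1L),
               "own candidates")
})

test_that("frequency scores are hits/trials with sign aggregation", {
  hits <- matrix(c(100L, 0L, 50L, 0L), 2, 2,
                 dimnames = list(c("r1", "r2"), c("t1", "t2")))
  sgn <- matrix(c(100L, 0L, -20L, 0L), 2, 2,
                dimnames = dimnames(hits))
  tally <- new("SelectionTally", hits = hits, signSum = sgn, trials = 100L)
  freq <- frequencyScores(tally)
  s <- scoreMatrix(freq)
  expect_identical(s["r1", "t1"], 1)        # hits = trials -> max score 1
  expect_identical(s["r2", "t1"], 0)        # no hits -> 0
  expect_identical(s["r1", "t2"], 0.5)      # 50/100 (n = 25, m = 4)
  expect_equal(signMatrix(freq)["r1", "t2"], -1L)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("tally validity rejects impossible counts and self-selection", {
  h <- matrix(5L, 2, 2, dimnames = list(c("a", "b"), c("a", "c")))
  s <- matrix(0L, 2, 2, dimnames = dimnames(h))
  expect_error(new("SelectionTally", hits = h, signSum = s, trials = 4L),
               "hits must lie")
  h2 <- h; h2[] <- 2L
  expect_error(new("SelectionTally", hits = h2, signSum = s, trials = 4L),
               "self-selection")
})

test_that("m = 1, nIter = 1 reduces to one whole-data fit per target", {
  fx <- makeFixtureMatrix(nObs = 60L, nGenes = 10L, nReg = 4L, seed = 7L)
  cfg <- inferenceConfig(m = 1L, nIter = 1L, cutoff = 1, seed = 5L,
                         regulators = fx$sources, targets = fx$targets)
  tally <- tallySelections(suppressWarnings(standardizeExpression(fx$em)),
                           cfg)
  expect_identical(nTrials(tally), 1L)

  em <- suppressWarnings(standardizeExpression(fx$em))
  v <- exprValues(em)
  for (ti in seq_along(fx$targets)) {
    tgt <- fx$targets[ti]
    fit <- fitElasticNetCV(v[, fx$sources], v[, tgt], cfg@en,
                           seed = deriveStreamSeed(5L, 1L, 1L, ti))
    sup <- selectedSupport(fit)
    got <- rownames(hitCounts(tally))[hitCounts(tally)[, tgt] == 1L]
    expect_setequal(got, sup$ids)
  }
})

test_that("engine tally equals an independent brute-force replay", {
  fx <- makeFixtureMatrix(nObs = 60L, nGenes = 10L, nReg = 4L, seed = 7L)
  cfg <- inferenceConfig(m = 2L, nIter = 5L, cutoff = 0.95, seed = 7L)
  engine <- tallySelections(suppressWarnings(standardizeExpression(fx$em)),
                            cfg)
  brute <- bruteForceTally(fx$em, cfg)
  expect_identical(hitCounts(engine), brute$hits)
  expect_identical(signMatrix(engine), brute$signSum)
  expect_identical(nTrials(engine), brute$trials)
  # no self-selection by construction
  shared <- intersect(rownames(brute$hits), colnames(brute$hits))
  expect_true(all(brute$hits[cbind(shared, shared)] == 0L))
})

test_that("raising the cutoff never adds edges", {
  fx <- makeFixtureMatrix(nObs = 60L, nGenes = 10L, nReg = 4L, seed = 2L)
  cfg <- inferenceConfig(m = 2L, nIter = 5L, cutoff = 0, seed = 3L)
  et <- inferNetwork(fx$em, cfg, fullTable = TRUE)
  freq <- attr(et, "frequencyTable")
  key <- function(e) paste(edges(e)$regulator, edges(e)$target)
  prev <- NULL
  for (ct in c(0.2, 0.5, 0.8, 1)) {
    cur <- key(thresholdEdges(freq, ct))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # cutoff 1 keeps exactly the always-selected pairs
  always <- sum(scoreMatrix(freq) == 1)
  expect_equal(nEdges(thresholdEdges(freq, 1)), always)
  # full-table mode returns every pair selected at least once
  expect_equal(nEdges(et), sum(scoreMatrix(freq) > 0))
})

test_that("identical (matrix, config, seed) gives identical edges for any worker count", {
  fx <- makeFixtureMatrix(nObs = 60L, nGenes = 10L, nReg = 4L, seed = 7L)
  cfg1 <- inferenceConfig(m = 2L, nIter = 4L, cutoff = 0.5, seed = 21L,
                          workers = 1L)
  cfg4 <- inferenceConfig(m = 2L, nIter = 4L, cutoff = 0.5, seed = 21L,
                          workers = 4L)
  e1 <- inferNetwork(fx$em, cfg1)
  e4 <- inferNetwork(fx$em, cfg4)
  f1 <- tempfile(); f4 <- tempfile()
  writeEdgeTable(e1, f1); writeEdgeTable(e4, f4)
  expect_identical(readLines(f1), readLines(f4))
  expect_identical(scoreMatrix(attr(e1, "frequencyTable")),
                   scoreMatrix(attr(e4, "frequencyTable")))
})

test_that("config violations abort before computation", {
  fx <- makeFixtureMatrix(nObs = 20L, nGenes = 6L, nReg = 2L)
  expect_error(
    tallySelections(fx$em, inferenceConfig(m = 21L, nIter = 1L)),
    "exceeds n_obs")
  expect_error(
    tallySelections(fx$em, inferenceConfig(m = 8L, nIter = 1L)),
    "below the .* CV folds")
  expect_error(
    tallySelections(fx$em, inferenceConfig(m = 2L, nIter = 1L,
                                           targets = "nope")),
    "unknown target")
  expect_error(inferenceConfig(cutoff = 1.5), "cutoff")
})

test_that("constant genes are excluded as candidates but retained as targets", {
  fx <- makeFixtureMatrix(nObs = 30L, nGenes = 6L, nReg = 2L, seed = 4L)
  v <- exprValues(fx$em)
  v[, "src2"] <- 7                      # degrade one source to constant
  em <- ExpressionMatrix(v)
  cfg <- inferenceConfig(m = 1L, nIter = 1L, cutoff = 0, seed = 1L)
  et <- inferNetwork(em, cfg, fullTable = TRUE)
  freq <- attr(et, "frequencyTable")
  expect_false("src2" %in% rownames(scoreMatrix(freq)))  # not a candidate
  expect_true("src2" %in% colnames(scoreMatrix(freq)))   # still a target
  expect_true(all(scoreMatrix(freq)[, "src2"] == 0))     # null regression
})
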