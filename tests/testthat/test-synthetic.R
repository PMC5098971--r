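test_that("zero divergence gives identical homolog copies", {
  cfg <- simConfig(nTranscripts = 10L, lenRange = c(300L, 500L),
                   divergence = 0, indelRate = 0,
                   readsPerPopulation = 0L, seed = 61L)
  pair <- generateTranscriptomePair(cfg)
  expect_identical(unname(as.character(pair$transcriptsA)),
                   unname(as.character(pair$transcriptsB)))
  expect_true(all(pair$truth$true_identity == 1))
})

test_that("realized identity tracks the divergence parameter", {
  cfg <- simConfig(nTranscripts = 200L, divergence = 0.04,
                   readsPerPopulation = 0L, seed = 63L)
  pair <- generateTranscriptomePair(cfg)
  m <- mean(pair$truth$true_identity)
  expect_gt(m, 0.95)
  expect_lt(m, 0.97)
})

test_that("the whole dataset is byte-identical under a fixed seed", {
  cfg <- simConfig(nTranscripts = 8L, lenRange = c(300L, 500L),
                   readsPerPopulation = 300L, seed = 65L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateDataset(cfg, d1)
  simulateDataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  expect_true(all(file.size(file.path(d1, list.files(d1))) > 0))
})

test_that("read sampling is weight- and length-proportional", {
  set.seed(67)
  tx <- DNAStringSet(c(t1 = randomDNA(600), t2 = randomDNA(600)))
  cfg <- simConfig(nTranscripts = 2L, readsPerPopulation = 40000L,
                   errorSubRate = 0, homopolymerIndelRate = 0,
                   readLenMean = 400, readLenSd = 60, seed = 1L)
  rd <- simulateReads(tx, c(1, 1), cfg, seed = 67L)
  n1 <- sum(rd$truth$transcript_id == "t1")
  expect_lt(abs(n1 - 20000), 3 * sqrt(40000 * 0.25))

  rd2 <- simulateReads(tx, c(4, 1), cfg, seed = 68L)
  n1 <- sum(rd2$truth$transcript_id == "t1")
  expect_lt(abs(n1 - 40000 * 0.8), 3 * sqrt(40000 * 0.8 * 0.2))
})

test_that("error-free reads from undiverged copies map back perfectly", {
  cfg <- simConfig(nTranscripts = 5L, lenRange = c(400L, 600L),
                   divergence = 0, indelRate = 0, errorSubRate = 0,
                   homopolymerIndelRate = 0, readsPerPopulation = 200L,
                   qualStart = 35L, qualEnd = 30L, seed = 69L)
  pair <- generateTranscriptomePair(cfg)
  rd <- simulateReads(pair$transcriptsA, pair$truth$weight_A, cfg)
  fr <- fragmentReads(trimReadEnds(rd$reads, dropEmpty = TRUE))
  hits <- mapFragments(fr, buildSeedIndex(pair$transcriptsA))
  expect_true(all(!is.na(hits$transcript_id)))
  expect_true(all(hits$n_mismatches == 0L))
})

test_that("realized read-count ratios converge to the true log2 ratios", {
  cfg <- simConfig(nTranscripts = 12L, lenRange = c(600L, 900L),
                   exprLog2fc = rep_len(c(-2, 0, 2), 12L),
                   errorSubRate = 0, homopolymerIndelRate = 0,
                   readsPerPopulation = 30000L, seed = 71L)
  pair <- generateTranscriptomePair(cfg)
  rdA <- simulateReads(pair$transcriptsA, pair$truth$weight_A, cfg, "A")
  rdB <- simulateReads(pair$transcriptsB, pair$truth$weight_B, cfg, "B")
  cA <- table(factor(rdA$truth$transcript_id, levels = pair$truth$id_A))
  cB <- table(factor(rdB$truth$transcript_id, levels = pair$truth$id_B))
  lA <- width(pair$transcriptsA)
  lB <- width(pair$transcriptsB)
  est <- log2((as.numeric(cB) / lB) / (as.numeric(cA) / lA))
  se <- sqrt(1 / as.numeric(cA) + 1 / as.numeric(cB)) / log(2)
  # 4 SE per pair: 24 simultaneous comparisons at 3 SE would flake
  expect_true(all(abs(est - pair$truth$true_log2fc) < 4 * se))
})

test_that("low 3' quality guarantees trimming shortens reads on average", {
  cfg <- simConfig(nTranscripts = 4L, lenRange = c(500L, 700L),
                   readsPerPopulation = 500L, qualStart = 38L,
                   qualEnd = 10L, seed = 73L)
  pair <- generateTranscriptomePair(cfg)
  rd <- simulateReads(pair$transcriptsA, pair$truth$weight_A, cfg)
  tr <- trimReadEnds(rd$reads)
  expect_lt(mean(width(tr)), mean(width(rd$reads)))
})

test_that("contradictory configurations are rejected", {
  expect_error(simConfig(nTranscripts = 0L), "nTranscripts")
  expect_error(simConfig(lenRange = c(500L, 300L)), "lenRange")
  expect_error(simConfig(divergence = 1.5), "rates")
  expect_error(simConfig(nTranscripts = 5L, exprLog2fc = c(1, 2)),
               "per transcript")
  expect_error(simulateReads(DNAStringSet(), numeric(0), simConfig()),
               "empty")
})
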