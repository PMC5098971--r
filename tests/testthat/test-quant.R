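test_that("RPKM follows its closed form and scale invariance", {
  expect_equal(rpkm(10, 500, 1e6), 20)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(3, 1000, 0), 0)
  counts <- c(5, 10, 80)
  lens <- c(300, 500, 900)
  expect_equal(rpkm(2 * counts, lens, 2 * sum(counts)),
               rpkm(counts, lens, sum(counts)))
})

test_that("population averaging and fold-change arithmetic", {
  avg <- averagePopulationRpkm(10, 20, 7, 7)
  expect_equal(avg$rpkm_A, 15)
  expect_equal(avg$rpkm_B, 7)
  expect_equal(foldChange(40, 10), 2)
  expect_equal(foldChange(10, 10), 0)
  expect_true(is.na(foldChange(5, 0)))
  expect_true(is.na(foldChange(0, 5)))
  # pseudocount policy keeps zeros defined
  expect_equal(foldChange(0, 0, pseudocount = 1), 0)
  expect_false(is.na(foldChange(5, 0, pseudocount = 0.5)))
})

test_that("classification thresholds are inclusive on both sides", {
  expect_identical(classifyFoldChange(1.0), "down_in_A")
  expect_identical(classifyFoldChange(-1.0), "up_in_A")
  expect_identical(classifyFoldChange(0.5), "unchanged")
  expect_identical(classifyFoldChange(-0.999), "unchanged")
  expect_identical(classifyFoldChange(NA_real_), "undefined")
  expect_identical(classifyFoldChange(c(2, -3, 0)),
                   c("down_in_A", "up_in_A", "unchanged"))
})

# A tiny hand-checkable dataset: two pairs with known counts.
.tinyPairs <- function() {
  A <- DNAStringSet(c(p1 = strrep("ACGT", 100), p2 = strrep("GGCA", 50)))
  B <- A
  names(B) <- names(A)
  info <- data.frame(pair_id = c("p1", "p2"), id_A = c("a1", "a2"),
                     id_B = c("b1", "b2"), qs = c(0L, 0L),
                     qe = c(400L, 200L), ts = c(0L, 0L), te = c(400L, 200L),
                     strand = "+", score = c(400L, 200L), identity = 1,
                     stringsAsFactors = FALSE)
  names(A) <- names(B) <- info$pair_id
  new("ConsensusPairs", seqA = A, seqB = B, pairInfo = info)
}

test_that("the expression table reproduces hand-computed RPKM and classes", {
  pairs <- .tinyPairs()
  counts <- matrix(c(80L, 20L,    # round1
                     80L, 20L,    # round2
                     20L, 20L,    # round3
                     20L, 20L),   # round4
                   nrow = 2,
                   dimnames = list(c("p1", "p2"), paste0("round", 1:4)))
  rounds <- list(counts = counts,
                 round_totals = colSums(counts),
                 n_fragments = c(A = 100L, B = 40L),
                 remap_fraction = rep(1, 4))
  res <- expressionTable(rounds, pairs)
  rd <- SummarizedExperiment::rowData(res)
  # round1: 1e9 * 80 / (400 * 100) = 2e6 ; round3: 1e9 * 20 / (400 * 40)
  expect_equal(unname(SummarizedExperiment::assay(res, "rpkm")["p1", 1]), 2e6)
  expect_equal(unname(rd["p1", "rpkm_A"]), 2e6)
  expect_equal(unname(rd["p1", "rpkm_B"]), 1.25e6)
  expect_equal(unname(foldChanges(res)["p1"]), log2(1.25 / 2))
  # p2: A rpkm 1e9*20/(200*100)=1e6, B rpkm 1e9*20/(200*40)=2.5e6 -> fc log2(2.5)
  expect_equal(unname(foldChanges(res)["p2"]), log2(2.5))
  expect_identical(unname(deClass(res)), c("unchanged", "down_in_A"))
  s <- deSummary(res)
  expect_equal(unname(sum(s)), 2)

  # swapping population roles negates fc and swaps classes
  swapped <- new("ConsensusPairs", seqA = consensusB(pairs),
                 seqB = consensusA(pairs),
                 pairInfo = within(pairInfo(pairs), {
                   tmp <- qs; qs <- ts; ts <- tmp
                   tmp <- qe; qe <- te; te <- tmp
                   rm(tmp)
                 }))
  roundsSw <- list(counts = counts[, c(3, 4, 1, 2)],
                   round_totals = rounds$round_totals[c(3, 4, 1, 2)],
                   n_fragments = rounds$n_fragments[c(2, 1)],
                   remap_fraction = rounds$remap_fraction[c(3, 4, 1, 2)])
  colnames(roundsSw$counts) <- paste0("round", 1:4)
  resSw <- expressionTable(roundsSw, swapped)
  expect_equal(unname(foldChanges(resSw)), -unname(foldChanges(res)))
  sSw <- deSummary(resSw)
  expect_equal(unname(sSw["n_up"]), unname(s["n_down"]))
  expect_equal(unname(sSw["n_down"]), unname(s["n_up"]))
})

test_that("zero rounds mark pairs undefined under the default policy", {
  pairs <- .tinyPairs()
  counts <- matrix(c(10L, 0L, 10L, 0L, 0L, 5L, 0L, 5L), nrow = 2,
                   dimnames = list(c("p1", "p2"), paste0("round", 1:4)))
  rounds <- list(counts = counts, round_totals = colSums(counts),
                 n_fragments = c(A = 20L, B = 10L),
                 remap_fraction = rep(1, 4))
  res <- expressionTable(rounds, pairs)
  expect_identical(unname(deClass(res)), c("undefined", "undefined"))
  expect_equal(unname(deSummary(res)["n_undefined"]), 2L)
  # with a pseudocount everything is defined
  res2 <- expressionTable(rounds, pairs, pseudocount = 0.1)
  expect_false(any(is.na(foldChanges(res2))))
})

test_that("mismatched pair keys are rejected", {
  pairs <- .tinyPairs()
  counts <- matrix(0L, 2, 4,
                   dimnames = list(c("p1", "zz"), paste0("round", 1:4)))
  rounds <- list(counts = counts, round_totals = colSums(counts),
                 n_fragments = c(A = 0L, B = 0L), remap_fraction = rep(NA, 4))
  expect_error(expressionTable(rounds, pairs), "do not match")
})

test_that("the expression TSV round-trips the table", {
  pairs <- .tinyPairs()
  counts <- matrix(c(8L, 2L, 8L, 2L, 2L, 2L, 2L, 2L), nrow = 2,
                   dimnames = list(c("p1", "p2"), paste0("round", 1:4)))
  rounds <- list(counts = counts, round_totals = colSums(counts),
                 n_fragments = c(A = 10L, B = 4L), remap_fraction = rep(1, 4))
  res <- expressionTable(rounds, pairs)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTable(res, path)
  back <- read.delim(path)
  expect_identical(back$pair_id, c("p1", "p2"))
  expect_equal(back$fc, unname(foldChanges(res)))
  expect_identical(back$c1, c(8L, 2L))
})
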