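test_that("Karlin-Altschul lambda satisfies the identity to 1e-10", {
  for (sc in list(c(1L, -2L), c(1L, -3L), c(2L, -3L))) {
    s <- scoringScheme(sc[1], sc[2])
    p <- s@baseFreqs
    pm <- sum(p^2)
    lhs <- pm * exp(s@lambda * s@match) + (1 - pm) * exp(s@lambda * s@mismatch)
    expect_lt(abs(lhs - 1), 1e-10)
    expect_gt(s@K, 0)
    expect_gt(s@H, 0)
  }
  # a non-negative expected score admits no solution
  expect_error(scoringScheme(4L, -1L), "negative")
})

test_that("bit scores are linear and e-values monotone in the raw score", {
  s <- scoringScheme()
  raw <- 0:50
  bits <- bitScore(raw, s)
  expect_equal(diff(bits), rep(s@lambda / log(2), 50))
  e <- eValue(raw, 500, 1e5, s)
  expect_true(all(diff(e) < 0))
  expect_equal(eValue(30, 500, 2e5, s), 2 * eValue(30, 500, 1e5, s))
  expect_gte(eValue(0, 500, 1e5, s), 1)   # zero score can never be significant
})

test_that("local alignment recovers perfect, mismatched and strand hits", {
  set.seed(3)
  s <- randomDNA(100)
  h <- localAlign(s, s)
  fwd <- h[h$strand == "+", ]
  expect_equal(fwd$score, 100)
  expect_equal(fwd$identity, 1)
  expect_equal(c(fwd$qs, fwd$qe, fwd$ts, fwd$te), c(0, 100, 0, 100))

  h2 <- localAlign("ACGTACGT", "ACGTTCGT")
  fwd2 <- h2[h2$strand == "+", ]
  expect_equal(fwd2$score, 5)           # 7 matches - 1 mismatch * 2
  expect_equal(fwd2$identity, 7 / 8)
  expect_equal(fwd2$n_cols, 8)

  h3 <- localAlign(s, revcompChr(s))
  best <- h3[which.max(h3$score), ]
  expect_equal(best$strand, "-")
  expect_equal(best$score, 100)
  expect_equal(best$identity, 1)
  # minus-strand interval reported in forward-target coordinates
  expect_equal(c(best$ts, best$te), c(0, 100))
})

test_that("alignment scores match the reference DP on gapped relatives", {
  set.seed(17)
  mat <- pwalign_matrix()
  for (i in 1:15) {
    a <- randomDNA(sample(80:180, 1))
    b <- ceact:::cpp_mutate_seqs(a, 0.1, 0.05, 0)   # forces gapped optima
    mine <- localAlign(a, b)
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 2)
    expect_identical(mine$score[mine$strand == "+"],
                     as.integer(Biostrings::score(ref)))
  }
})

test_that("conversion table pairs identical transcriptomes one to one", {
  set.seed(9)
  seqs <- vapply(rep(400, 8), randomDNA, character(1))
  A <- DNAStringSet(seqs); names(A) <- sprintf("a%02d", 1:8)
  B <- DNAStringSet(seqs); names(B) <- sprintf("b%02d", 1:8)
  ct <- buildConversionTable(A, B)
  expect_equal(nrow(ct), 8)
  expect_identical(sub("a", "b", ct$id_A), ct$id_B)
  expect_true(all(ct$identity == 1))
  expect_true(all(ct$evalue <= 1e-20))
})

test_that("transcripts without a homolog are excluded from the table", {
  set.seed(10)
  shared <- randomDNA(500)
  A <- DNAStringSet(c(a1 = shared, a2 = randomDNA(500)))
  B <- DNAStringSet(c(b1 = shared))
  ct <- buildConversionTable(A, B)
  expect_identical(ct$id_A, "a1")
  excl <- attr(ct, "exclusions")
  expect_true("a2" %in% excl$id[excl$reason == "no_significant_match"])
})

test_that("conversion table is symmetric under swapping the populations", {
  cfg <- simConfig(nTranscripts = 12L, lenRange = c(400L, 700L),
                   readsPerPopulation = 0L, seed = 33L)
  pair <- generateTranscriptomePair(cfg)
  ab <- buildConversionTable(pair$transcriptsA, pair$transcriptsB)
  ba <- buildConversionTable(pair$transcriptsB, pair$transcriptsA)
  expect_identical(nrow(ab), nrow(ba))
  expect_identical(sort(paste(ab$id_A, ab$id_B)),
                   sort(paste(ba$id_B, ba$id_A)))
})

test_that("the highest-scoring window follows the documented tie order", {
  hits <- data.frame(score = c(120, 80), qs = c(0, 10), qe = c(100, 60))
  expect_equal(highestScoringWindow(hits)$score, 120)
  ties <- data.frame(score = c(50, 50), qs = c(20, 5), qe = c(120, 65))
  expect_equal(highestScoringWindow(ties)$qe - highestScoringWindow(ties)$qs,
               100)
  ties2 <- data.frame(score = c(50, 50), qs = c(20, 5), qe = c(70, 55))
  expect_equal(highestScoringWindow(ties2)$qs, 5)
  expect_error(highestScoringWindow(NULL), "no hits")
})

test_that("consensus extraction cuts matching windows on the forward strand", {
  set.seed(12)
  seqs <- vapply(rep(300, 5), randomDNA, character(1))
  A <- DNAStringSet(seqs); names(A) <- sprintf("a%d", 1:5)
  B <- DNAStringSet(seqs); names(B) <- sprintf("b%d", 1:5)
  ct <- buildConversionTable(A, B)
  pairs <- extractConsensus(ct, A, B)
  expect_identical(unname(as.character(consensusA(pairs))),
                   unname(as.character(consensusB(pairs))))
  expect_identical(unname(as.character(consensusA(pairs))), unname(seqs))
  info <- pairInfo(pairs)
  expect_identical(width(consensusA(pairs)), info$qe - info$qs)
  expect_identical(width(consensusB(pairs)), info$te - info$ts)

  # a reverse-complemented homolog comes back on the A-forward strand
  Brc <- reverseComplement(A)
  names(Brc) <- sprintf("b%d", 1:5)
  ctrc <- buildConversionTable(A, Brc)
  prc <- extractConsensus(ctrc, A, Brc)
  expect_true(all(pairInfo(prc)$strand == "-"))
  expect_identical(unname(as.character(consensusA(prc))),
                   unname(as.character(consensusB(prc))))
})

test_that("consensus FASTA and conversion-table TSV round out to disk", {
  set.seed(14)
  seqs <- vapply(rep(300, 3), randomDNA, character(1))
  A <- DNAStringSet(seqs); names(A) <- sprintf("a%d", 1:3)
  B <- DNAStringSet(seqs); names(B) <- sprintf("b%d", 1:3)
  ct <- buildConversionTable(A, B)
  pairs <- extractConsensus(ct, A, B)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeConversionTable(ct, tsv)
  back <- read.delim(tsv)
  expect_identical(back$qid, ct$id_A)
  fa <- withr::local_tempfile(fileext = ".fasta")
  fb <- withr::local_tempfile(fileext = ".fasta")
  writeConsensus(pairs, fa, fb)
  consA <- readTranscripts(fa)
  expect_match(names(consA)[1], "^pair000001\\|A\\|src=a1\\|0-300$")
  expect_identical(unname(as.character(consA)),
                   unname(as.character(consensusA(pairs))))
})
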