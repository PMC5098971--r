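test_that("fragmentation follows the greedy 40-60 nt rule", {
  rr <- makeReads(c(strrep("A", 120), strrep("C", 100), strrep("G", 39),
                    strrep("T", 70)), ids = c("a", "b", "c", "d"))
  fg <- fragmentReads(rr)
  expect_identical(names(fg), c("a/1", "a/2", "b/1", "b/2", "d/1"))
  expect_identical(width(fg), c(60L, 60L, 60L, 40L, 60L))
  # qualities stay in register
  expect_identical(width(BStringSet(as.character(quality(fg)))), width(fg))
})

test_that("fragmentation conserves bases with deficit under 40 nt", {
  set.seed(8)
  lens <- sample(10:400, 150, TRUE)
  rr <- makeReads(vapply(lens, randomDNA, character(1)))
  fg <- fragmentReads(rr)
  expect_true(all(width(fg) >= 40L & width(fg) <= 60L))
  got <- tapply(width(fg), sub("/\\d+$", "", names(fg)), sum)
  lens_named <- setNames(lens, names(rr))
  deficit <- lens_named[names(got)] - got
  expect_true(all(deficit >= 0 & deficit < 40))
  # reads that produced nothing are shorter than 40 + nothing keepable
  none <- setdiff(names(rr), names(got))
  expect_true(all(lens_named[none] %% 60 < 40 & lens_named[none] < 100))
})

test_that("seed index lookup finds exact occurrences on both strands", {
  set.seed(19)
  refs <- DNAStringSet(c(t1 = randomDNA(600), t2 = randomDNA(500)))
  idx <- buildSeedIndex(refs)
  km <- substr(as.character(refs[["t1"]]), 201, 228)
  hit <- lookupCandidates(idx, km)
  expect_identical(hit$transcript_id, "t1")
  expect_identical(hit$position, 200L)
  expect_identical(hit$strand, "+")
  rc <- revcompChr(km)
  hit2 <- lookupCandidates(idx, rc)
  expect_identical(hit2$strand, "-")
  expect_identical(hit2$position, 200L)
  expect_identical(nrow(lookupCandidates(idx, strrep("A", 28))), 0L)
})

test_that("fragment mapping handles verbatim, seed-mismatch and short cases", {
  set.seed(23)
  refs <- DNAStringSet(c(t1 = randomDNA(800)))
  idx <- buildSeedIndex(refs)
  frag <- substr(as.character(refs[[1]]), 301, 360)
  hit <- mapFragments(makeReads(frag, ids = "f0"), idx)
  expect_identical(hit$transcript_id, "t1")
  expect_identical(hit$position, 305L)   # source offset + trim5
  expect_identical(hit$n_mismatches, 0L)

  sub1 <- frag
  substr(sub1, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                  substr(frag, 10, 10))[1]
  h1 <- mapFragments(makeReads(sub1, ids = "f1"), idx)
  expect_identical(h1$n_mismatches, 1L)
  expect_identical(h1$position, 305L)

  sub2 <- sub1
  substr(sub2, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                  substr(frag, 20, 20))[1]
  h2 <- mapFragments(makeReads(sub2, ids = "f2"), idx)   # 2 seed mismatches
  expect_true(is.na(h2$transcript_id))

  tiny <- mapFragments(makeReads(strrep("A", 10), ids = "f3"), idx)
  expect_true(is.na(tiny$transcript_id))
})

test_that("mapping agrees with the exhaustive matchPattern oracle", {
  set.seed(29)
  refs <- DNAStringSet(setNames(vapply(rep(1500, 4), randomDNA, character(1)),
                                sprintf("c%02d", 1:4)))
  # fragments: planted copies with errors, reverse strand, and pure noise
  n <- 150
  seqs <- character(n); quals <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(40:60, 1)
    if (i %% 3 == 0) seqs[i] <- randomDNA(len)
    else {
      r <- sample(4, 1); p <- sample(1500 - len, 1)
      x <- substr(as.character(refs[[r]]), p, p + len - 1)
      nmut <- sample(0:3, 1)
      for (j in seq_len(nmut)) {
        at <- sample(len, 1)
        substr(x, at, at) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (i %% 2 == 0) x <- revcompChr(x)
      seqs[i] <- x
    }
    quals[[i]] <- sample(5:40, nchar(seqs[i]), TRUE)
  }
  fr <- makeReads(seqs, quals)
  idx <- buildSeedIndex(refs)
  mine <- mapFragments(fr, idx)
  oracle <- oracleMapFragments(fr, refs)
  expect_identical(is.na(mine$transcript_id), is.na(oracle$transcript_id))
  expect_identical(mine$transcript_id, oracle$transcript_id)
  expect_identical(mine$position, oracle$position)
  expect_identical(mine$strand, oracle$strand)
  expect_identical(mine$n_mismatches, oracle$n_mismatches)
  expect_identical(mine$qual_mismatch_sum, oracle$qual_mismatch_sum)
})

test_that("mapping is deterministic on repeated runs", {
  set.seed(31)
  refs <- DNAStringSet(setNames(vapply(rep(900, 3), randomDNA, character(1)),
                                c("x", "y", "z")))
  fr <- makeReads(vapply(rep(50, 40), randomDNA, character(1)))
  a <- mapFragments(fr, buildSeedIndex(refs))
  b <- mapFragments(fr, buildSeedIndex(refs))
  expect_identical(a, b)
})

test_that("the four rounds are symmetric for identical inputs", {
  set.seed(37)
  seqs <- vapply(rep(400, 6), randomDNA, character(1))
  A <- DNAStringSet(seqs); names(A) <- sprintf("a%d", 1:6)
  B <- DNAStringSet(seqs); names(B) <- sprintf("b%d", 1:6)
  pairs <- extractConsensus(buildConversionTable(A, B), A, B)
  reads <- makeReads(vapply(seq_len(60), function(i) {
    r <- sample(6, 1); p <- sample(340, 1)
    substr(seqs[r], p, p + 59)
  }, character(1)))
  fr <- fragmentReads(reads)
  rounds <- runFourRounds(fr, fr, pairs)
  expect_identical(rounds$counts[, 1], rounds$counts[, 2])
  expect_identical(rounds$counts[, 1], rounds$counts[, 3])
  expect_identical(rounds$counts[, 1], rounds$counts[, 4])

  empty <- fr[0]
  r2 <- runFourRounds(fr, empty, pairs)
  expect_true(all(r2$counts[, 3:4] == 0))
  expect_identical(unname(r2$round_totals[3:4]), c(0L, 0L))
})

test_that("SAM emission produces structurally valid ungapped records", {
  set.seed(41)
  refs <- DNAStringSet(c(ref1 = randomDNA(500)))
  idx <- buildSeedIndex(refs)
  frag <- substr(as.character(refs[[1]]), 101, 160)
  fr <- makeReads(c(frag, randomDNA(50)), ids = c("m1", "m2"))
  hits <- mapFragments(fr, idx)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(hits, fr, idx, mappingPolicy(), sam)
  lines <- readLines(sam)
  expect_match(lines[2], "^@SQ\tSN:ref1\tLN:500$")
  rec <- strsplit(grep("^m1", lines, value = TRUE), "\t")[[1]]
  expect_identical(rec[3], "ref1")
  expect_identical(rec[4], "106")     # 1-based, trim5 applied
  expect_identical(rec[6], "50M")
  expect_match(lines[grep("^m2", lines)], "\t4\t\\*\t0\t")
})
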