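# Shared fixtures and independent oracles used across the suite.

suppressPackageStartupMessages(library(Biostrings))

randomDNA <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

revcompChr <- function(x) as.character(reverseComplement(DNAString(x)))

# Build a QualityScaledDNAStringSet from character sequences and integer
# quality lists (recycled scalars allowed).
makeReads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(n) rep(30L, n))
  if (is.list(quals))
    qstr <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)), character(1))
  else qstr <- quals
  x <- QualityScaledDNAStringSet(DNAStringSet(seqs),
                                 PhredQuality(BStringSet(qstr)))
  names(x) <- if (is.null(ids)) sprintf("r%04d", seq_along(seqs)) else ids
  x
}

# --- Independent fragment-mapping oracle -----------------------------------
# Enumerates candidate placements with Biostrings::matchPattern on the seed
# (never via the package's block index), applies the mapping policy in plain
# R, and picks the best placement under the documented tie order.
oracleMapFragments <- function(fragments, refs, policy = mappingPolicy()) {
  trim5 <- policy@trim5; trim3 <- policy@trim3
  seedLen <- policy@seedLen; maxSeedMM <- policy@maxSeedMismatches
  budget <- policy@maxQualMismatchSum
  spacer <- strrep("N", 200)
  cat_seq <- paste(as.character(refs), collapse = spacer)
  subject <- DNAString(cat_seq)
  refLen <- width(refs)
  refOff <- cumsum(c(0L, head(refLen + 200L, -1L)))  # 0-based starts
  nm <- names(refs)
  rank <- match(nm, sort(nm, method = "radix"))
  nRaw <- as.raw(78L)  # 'N'

  out <- lapply(seq_along(fragments), function(f) {
    full <- as.character(fragments[[f]])
    qall <- as.integer(charToRaw(as.character(quality(fragments))[f])) - 33L
    n <- nchar(full) - trim5 - trim3
    un <- data.frame(fragment_id = names(fragments)[f],
                     transcript_id = NA_character_, position = NA_integer_,
                     strand = NA_character_, n_mismatches = NA_integer_,
                     qual_mismatch_sum = NA_integer_)
    if (n < 1) return(un)
    fwd <- substr(full, trim5 + 1L, trim5 + n)
    qv <- qall[(trim5 + 1L):(trim5 + n)]
    seedL <- min(seedLen, n)
    best <- NULL
    for (st in c("+", "-")) {
      s <- if (st == "+") fwd else revcompChr(fwd)
      sraw <- charToRaw(s)
      seedOff <- if (st == "+") 0L else n - seedL
      seed <- substr(s, seedOff + 1L, seedOff + seedL)
      m <- Biostrings::matchPattern(DNAString(seed), subject,
                                    max.mismatch = maxSeedMM, fixed = TRUE)
      starts <- unique(start(m) - 1L - seedOff)   # 0-based placement starts
      for (g in starts) {
        r <- findInterval(g, refOff)
        if (r < 1L || r > length(refs)) next
        p <- g - refOff[r]
        if (p < 0L || p + n > refLen[r]) next
        wraw <- charToRaw(substr(as.character(refs[[r]]), p + 1L, p + n))
        mism <- (wraw != sraw) | (wraw == nRaw) | (sraw == nRaw)
        if (sum(mism[(seedOff + 1L):(seedOff + seedL)]) > maxSeedMM) next
        readPos <- if (st == "+") which(mism) else n + 1L - which(mism)
        qsum <- sum(qv[readPos])
        if (qsum > budget) next
        cand <- list(mm = sum(mism), qsum = qsum, rank = rank[r],
                     pos = p, minus = (st == "-"), ref = r)
        if (is.null(best)) best <- cand
        else {
          a <- c(cand$mm, cand$qsum, cand$rank, cand$pos, cand$minus)
          b <- c(best$mm, best$qsum, best$rank, best$pos, best$minus)
          d <- a - b
          first <- which(d != 0)[1]
          if (!is.na(first) && d[first] < 0) best <- cand
        }
      }
    }
    if (is.null(best)) return(un)
    data.frame(fragment_id = names(fragments)[f],
               transcript_id = nm[best$ref], position = best$pos,
               strand = if (best$minus) "-" else "+",
               n_mismatches = best$mm, qual_mismatch_sum = best$qsum)
  })
  do.call(rbind, out)
}

# --- Independent longest-ORF oracle ----------------------------------------
# Per-codon translation with the standard code, explicit run scanning over
# all six frames, and the documented tie order (frame +1..+3, -1..-3, then
# leftmost).
oracleLongestOrf <- function(seq, minAa = 80L) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  if (L < 3L) return(NULL)
  code <- Biostrings::GENETIC_CODE
  translateFrame <- function(x, off) {
    n <- nchar(x) - off
    n <- n - n %% 3L
    if (n < 3L) return(character(0))
    starts <- seq.int(off + 1L, off + n, by = 3L)
    codons <- substring(x, starts, starts + 2L)
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"   # codons containing N (or other non-ACGT)
    aa
  }
  rc <- revcompChr(s)
  best <- NULL
  for (fidx in 1:6) {
    x <- if (fidx <= 3L) s else rc
    off <- (fidx - 1L) %% 3L
    aa <- translateFrame(x, off)
    if (!length(aa)) next
    run <- 0L; runStart <- NA_integer_
    for (i in seq_len(length(aa) + 1L)) {
      if (i <= length(aa) && aa[i] != "*") {
        if (run == 0L) runStart <- i
        run <- run + 1L
      } else if (run > 0L) {
        if (is.null(best) || run > best$len) {
          s0 <- off + (runStart - 1L) * 3L
          e0 <- s0 + run * 3L
          if (fidx > 3L) { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }
          best <- list(len = run, fidx = fidx,
                       frame = c("+1", "+2", "+3", "-1", "-2", "-3")[fidx],
                       start = s0, end = e0,
                       peptide = paste(aa[runStart:(runStart + run - 1L)],
                                       collapse = ""))
        }
        run <- 0L
      }
    }
  }
  if (is.null(best) || best$len < minAa) return(NULL)
  best
}

pwalign_matrix <- function()
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                           baseOnly = TRUE)
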