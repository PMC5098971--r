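## Homology search: exact local alignment, Karlin-Altschul e-values,
## reciprocal-best conversion table, consensus window extraction.

# Karlin-Altschul parameters for an ungapped match/mismatch score
# distribution at a given base composition. lambda is the positive root of
# sum_ij p_i p_j exp(lambda s_ij) = 1, found by root bracketing. H is the
# relative entropy (nats per aligned column). K is computed by the renewal
# series of the associated random walk:
#   sigma = sum_{k>=1} (1/k) [ P(S_k >= 0) + E(e^{lambda S_k}; S_k < 0) ],
#   K = d * lambda * exp(-2 sigma) / (H * (1 - exp(-lambda d)))
# with d the lattice span of the score values; both tail terms decay
# geometrically (negative drift / positive tilted drift), so the series is
# truncated when increments fall below 1e-12.
.karlinParams <- function(match, mismatch, baseFreqs = rep(0.25, 4)) {
  pMatch <- sum(baseFreqs^2)
  scores <- c(match, mismatch)
  probs <- c(pMatch, 1 - pMatch)
  if (sum(scores * probs) >= 0)
    stop("expected score must be negative for Karlin-Altschul statistics")
  f <- function(l) sum(probs * exp(l * scores)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-9, hi), tol = 1e-14)$root
  H <- lambda * sum(probs * scores * exp(lambda * scores))
  d <- Reduce(.gcd, abs(scores))

  # pmf of the step on the integer lattice [mismatch, match]
  lo <- min(scores)
  rng <- match - lo
  pmf <- numeric(rng + 1)
  pmf[scores - lo + 1] <- probs
  # distribution of S_k by iterated convolution
  cur <- pmf; curLo <- lo
  sigma <- 0
  for (k in 1:400) {
    vals <- seq.int(curLo, curLo + length(cur) - 1L)
    term <- sum(cur[vals >= 0]) + sum(cur[vals < 0] * exp(lambda * vals[vals < 0]))
    sigma <- sigma + term / k
    if (term / k < 1e-12 && k > 10) break
    cur <- convolve(cur, rev(pmf), type = "open")
    cur[cur < 0] <- 0
    curLo <- curLo + lo
  }
  K <- d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
  list(lambda = lambda, K = K, H = H)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Construct a scoring scheme
#'
#' Builds a [ScoringScheme-class] and solves its Karlin-Altschul parameters
#' numerically, so any match/mismatch combination (with negative expected
#' score) stays self-consistent. Defaults are a conventional
#' megablast-like nucleotide scheme.
#'
#' @param match,mismatch match reward (> 0) and mismatch penalty (< 0).
#' @param gapOpen,gapExtend positive affine gap costs; a gap of length L
#'   costs `gapOpen + L * gapExtend`.
#' @param baseFreqs background base composition (A, C, G, T).
#' @return a [ScoringScheme-class] object.
#' @examples
#' scoringScheme()            # +1/-2, gap 5/2
#' scoringScheme(1L, -3L)
#' @export
scoringScheme <- function(match = 1L, mismatch = -2L,
                          gapOpen = 5L, gapExtend = 2L,
                          baseFreqs = rep(0.25, 4)) {
  ka <- .karlinParams(as.integer(match), as.integer(mismatch), baseFreqs)
  new("ScoringScheme", match = as.integer(match),
      mismatch = as.integer(mismatch), gapOpen = as.integer(gapOpen),
      gapExtend = as.integer(gapExtend), baseFreqs = baseFreqs,
      lambda = ka$lambda, K = ka$K, H = ka$H)
}

#' Optimal local alignment on both strands
#'
#' Exact Smith-Waterman local alignment with affine gaps, run against the
#' target's forward strand and reverse complement. Columns involving N
#' score as mismatches and never count as identities. Coordinates are
#' 0-based half-open; minus-strand target intervals are reported in
#' forward-target coordinates.
#'
#' @param query,target nucleotide sequences (character or
#'   [Biostrings::DNAString]).
#' @param scoring a [scoringScheme()].
#' @return data.frame with one row per strand: `strand`, `score`, `qs`,
#'   `qe`, `ts`, `te`, `n_match`, `n_cols`, `identity`, `bit_score`.
#' @examples
#' localAlign("ACGTACGT", "ACGTTCGT")   # score 5, identity 7/8
#' @export
localAlign <- function(query, target, scoring = scoringScheme()) {
  q <- .normalizeSeq(as.character(query))
  t_fwd <- .normalizeSeq(as.character(target))
  t_rev <- as.character(reverseComplement(DNAString(t_fwd)))
  tl <- nchar(t_fwd)
  row1 <- cpp_sw_align(q, t_fwd, scoring@match, scoring@mismatch,
                       scoring@gapOpen, scoring@gapExtend)
  row2 <- cpp_sw_align(q, t_rev, scoring@match, scoring@mismatch,
                       scoring@gapOpen, scoring@gapExtend)
  out <- data.frame(
    strand = c("+", "-"),
    score = c(row1$score, row2$score),
    qs = c(row1$qs, row2$qs), qe = c(row1$qe, row2$qe),
    ts = c(row1$ts, tl - row2$te), te = c(row1$te, tl - row2$ts),
    n_match = c(row1$n_match, row2$n_match),
    n_cols = c(row1$n_cols, row2$n_cols),
    stringsAsFactors = FALSE)
  out$identity <- ifelse(out$n_cols > 0, out$n_match / out$n_cols, 0)
  out$bit_score <- bitScore(out$score, scoring)
  out
}

#' Bit score of a raw alignment score
#'
#' `(lambda * raw - ln K) / ln 2` for the scheme's Karlin-Altschul
#' parameters.
#'
#' @param rawScore raw alignment score(s).
#' @param scoring a [scoringScheme()].
#' @return numeric bit score(s).
#' @export
bitScore <- function(rawScore, scoring = scoringScheme()) {
  (scoring@lambda * rawScore - log(scoring@K)) / log(2)
}

#' Karlin-Altschul e-value
#'
#' Expected number of chance local alignments at least as good as
#' `rawScore` in a search space of `queryLen * dbTotalLen`:
#' `E = m * n * 2^(-bit score)`. Strictly decreasing in the raw score and
#' exactly linear in the search space.
#'
#' @param rawScore raw alignment score(s).
#' @param queryLen query length in nt.
#' @param dbTotalLen total database length in nt.
#' @param scoring a [scoringScheme()].
#' @return e-value(s).
#' @export
eValue <- function(rawScore, queryLen, dbTotalLen, scoring = scoringScheme()) {
  queryLen * dbTotalLen * 2^(-bitScore(rawScore, scoring))
}

# Best strand of a localAlign() result: higher score, '+' on ties.
.bestStrand <- function(hits) {
  hits[order(-hits$score, hits$strand), , drop = FALSE][1, , drop = FALSE]
}

#' Build the conversion table between two transcriptomes
#'
#' All-vs-all exact local alignment (after a shared-k-mer prefilter that
#' skips pairs with no common word, which chance alone essentially never
#' produces at `prefilterK = 16`), keeping for each transcript its
#' best-scoring partner with e-value at most `eCutoff`, and retaining only
#' reciprocal-best pairs so that every transcript enters at most one pair.
#' Transcripts lacking a significant match are excluded. Ties are broken
#' deterministically: higher raw score, then lexicographically smaller
#' partner id.
#'
#' @param transcriptsA,transcriptsB named [Biostrings::DNAStringSet]s.
#' @param scoring a [scoringScheme()].
#' @param eCutoff e-value cutoff (default 1e-20).
#' @param prefilterK k-mer length for the candidate prefilter; 0 disables
#'   it (full all-vs-all alignment).
#' @return data.frame with one row per reciprocal-best pair: `id_A`,
#'   `id_B`, `qs`, `qe`, `ts`, `te` (0-based half-open; A is the query),
#'   `strand`, `score`, `bit_score`, `evalue`, `identity`, plus an
#'   `exclusions` attribute recording per-transcript reasons for exclusion.
#' @export
buildConversionTable <- function(transcriptsA, transcriptsB,
                                 scoring = scoringScheme(),
                                 eCutoff = 1e-20, prefilterK = 16L) {
  stopifnot(length(transcriptsA) > 0, length(transcriptsB) > 0)
  seqsA <- as.character(transcriptsA); seqsB <- as.character(transcriptsB)
  idsA <- names(transcriptsA); idsB <- names(transcriptsB)
  dbA <- sum(width(transcriptsA)); dbB <- sum(width(transcriptsB))

  cand <- if (prefilterK > 0)
    cpp_kmer_candidates(seqsA, seqsB, as.integer(prefilterK), 1L)
  else rep(list(seq_along(seqsB)), length(seqsA))

  rows <- vector("list", length(seqsA))
  for (i in seq_along(seqsA)) {
    js <- cand[[i]]
    if (!length(js)) next
    hits <- lapply(js, function(j) {
      h <- .bestStrand(localAlign(seqsA[i], seqsB[j], scoring))
      h$id_B <- idsB[j]
      h$j <- j
      h
    })
    hits <- do.call(rbind, hits)
    hits$id_A <- idsA[i]
    hits$lenA <- nchar(seqsA[i])
    rows[[i]] <- hits
  }
  allHits <- do.call(rbind, rows)
  exclusions <- character(0)
  empty <- data.frame(id_A = character(0), id_B = character(0),
                      qs = integer(0), qe = integer(0), ts = integer(0),
                      te = integer(0), strand = character(0),
                      score = integer(0), bit_score = numeric(0),
                      evalue = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(allHits) || !nrow(allHits)) {
    attr(empty, "exclusions") <-
      data.frame(id = c(idsA, idsB), reason = "no_significant_match")
    return(empty)
  }
  # e-value in both search directions; require both below cutoff
  lenB <- nchar(seqsB)[allHits$j]
  allHits$evalue <- pmax(eValue(allHits$score, allHits$lenA, dbB, scoring),
                         eValue(allHits$score, lenB, dbA, scoring))
  sig <- allHits[allHits$evalue <= eCutoff, , drop = FALSE]

  bestOf <- function(df, by, partner) {
    df <- df[order(df[[by]], -df$score, df[[partner]]), , drop = FALSE]
    df[!duplicated(df[[by]]), , drop = FALSE]
  }
  bestA <- bestOf(sig, "id_A", "id_B")   # best B partner per A
  bestB <- bestOf(sig, "id_B", "id_A")   # best A partner per B
  keyA <- paste(bestA$id_A, bestA$id_B)
  keyB <- paste(bestB$id_A, bestB$id_B)
  rbh <- bestA[keyA %in% keyB, , drop = FALSE]
  rbh <- rbh[order(rbh$id_A), , drop = FALSE]

  paired <- c(rbh$id_A, rbh$id_B)
  hadSig <- unique(c(sig$id_A, sig$id_B))
  noSig <- setdiff(c(idsA, idsB), hadSig)
  noRbh <- setdiff(hadSig, paired)
  excl <- data.frame(
    id = c(noSig, noRbh),
    reason = c(rep("no_significant_match", length(noSig)),
               rep("not_reciprocal_best", length(noRbh))),
    stringsAsFactors = FALSE)
  out <- data.frame(id_A = rbh$id_A, id_B = rbh$id_B,
                    qs = rbh$qs, qe = rbh$qe, ts = rbh$ts, te = rbh$te,
                    strand = rbh$strand, score = rbh$score,
                    bit_score = rbh$bit_score, evalue = rbh$evalue,
                    identity = rbh$identity, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Highest-scoring window among hits for one transcript pair
#'
#' When more than one conserved region links two transcripts, only the
#' highest-scoring window is used for comparison. Ties go to the longer
#' query interval, then to the smaller query start.
#'
#' @param hits data.frame of hits with `score`, `qs`, `qe` columns.
#' @return the selected row.
#' @export
highestScoringWindow <- function(hits) {
  if (is.null(hits) || !nrow(hits)) stop("no hits to select from")
  o <- order(-hits$score, -(hits$qe - hits$qs), hits$qs)
  hits[o[1], , drop = FALSE]
}

#' Extract the paired consensus transcriptomes
#'
#' For each conversion-table pair, cuts the aligned window's region from
#' the population-A transcript and from the population-B transcript. The
#' extracted region is the contiguous source substring spanned by the
#' alignment (gapped columns do not split the window). Minus-strand B
#' regions are reverse-complemented so both members of a pair read on the
#' A-relative forward strand.
#'
#' @param conversionTable output of [buildConversionTable()].
#' @param transcriptsA,transcriptsB the source transcriptomes.
#' @return a [ConsensusPairs-class] object.
#' @export
extractConsensus <- function(conversionTable, transcriptsA, transcriptsB) {
  ct <- conversionTable
  n <- nrow(ct)
  pairIds <- sprintf("pair%06d", seq_len(n))
  if (n == 0) {
    return(new("ConsensusPairs", seqA = DNAStringSet(), seqB = DNAStringSet(),
               pairInfo = cbind(data.frame(pair_id = character(0)),
                                ct[, c("id_A", "id_B", "qs", "qe", "ts", "te",
                                       "strand", "score", "identity")])))
  }
  seqA <- subseq(transcriptsA[ct$id_A], start = ct$qs + 1L, end = ct$qe)
  seqB <- subseq(transcriptsB[ct$id_B], start = ct$ts + 1L, end = ct$te)
  minus <- ct$strand == "-"
  if (any(minus)) seqB[minus] <- reverseComplement(seqB[minus])
  names(seqA) <- pairIds
  names(seqB) <- pairIds
  info <- cbind(data.frame(pair_id = pairIds, stringsAsFactors = FALSE),
                ct[, c("id_A", "id_B", "qs", "qe", "ts", "te", "strand",
                       "score", "identity")])
  rownames(info) <- NULL
  new("ConsensusPairs", seqA = DNAStringSet(seqA), seqB = DNAStringSet(seqB),
      pairInfo = info)
}

#' Write a conversion table as TSV
#'
#' Tabular-alignment-style layout: qid, tid, qs, qe, ts, te, strand, score,
#' bitscore, evalue, identity.
#'
#' @param conversionTable output of [buildConversionTable()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeConversionTable <- function(conversionTable, path) {
  out <- conversionTable
  colnames(out)[colnames(out) == "id_A"] <- "qid"
  colnames(out)[colnames(out) == "id_B"] <- "tid"
  colnames(out)[colnames(out) == "bit_score"] <- "bitscore"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the two consensus transcriptomes as FASTA
#'
#' Headers follow `pair000017|A|src=<id>|<qs>-<qe>`.
#'
#' @param pairs a [ConsensusPairs-class] object.
#' @param pathA,pathB output FASTA files for the A and B members.
#' @return `c(pathA, pathB)`, invisibly.
#' @export
writeConsensus <- function(pairs, pathA, pathB) {
  info <- pairInfo(pairs)
  a <- consensusA(pairs)
  names(a) <- sprintf("%s|A|src=%s|%d-%d", info$pair_id, info$id_A,
                      info$qs, info$qe)
  b <- consensusB(pairs)
  names(b) <- sprintf("%s|B|src=%s|%d-%d", info$pair_id, info$id_B,
                      info$ts, info$te)
  writeXStringSet(a, pathA, width = 80L)
  writeXStringSet(b, pathB, width = 80L)
  invisible(c(pathA, pathB))
}
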