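## Read fragmentation and mismatch-tolerant ungapped fragment mapping.

#' Construct a mapping policy
#'
#' Defaults emulate a Bowtie-1 style `-n 1 -5 5 -3 5` invocation: 5 bases
#' trimmed from each fragment end, at most one mismatch in the first 28
#' post-trim bases, and a Phred quality budget of 70 summed over all
#' mismatched positions.
#'
#' @param trim5,trim3 bases trimmed from the fragment ends.
#' @param seedLen seed length in bases.
#' @param maxSeedMismatches maximum mismatches in the seed (0 or 1).
#' @param maxQualMismatchSum maximum summed Phred quality at mismatches.
#' @return a [MappingPolicy-class] object.
#' @export
mappingPolicy <- function(trim5 = 5L, trim3 = 5L, seedLen = 28L,
                          maxSeedMismatches = 1L, maxQualMismatchSum = 70L) {
  new("MappingPolicy", trim5 = as.integer(trim5), trim3 = as.integer(trim3),
      seedLen = as.integer(seedLen),
      maxSeedMismatches = as.integer(maxSeedMismatches),
      maxQualMismatchSum = as.integer(maxQualMismatchSum))
}

#' Split reads into 40-60 nt fragments
#'
#' Each read is cut left to right into consecutive `maxLen`-sized pieces;
#' a final remainder of at least `minLen` bases is kept, a shorter one is
#' dropped. Reads shorter than `minLen` yield nothing. Qualities are cut in
#' register. Fragment ids are `<read id>/<ordinal>`.
#'
#' @param reads quality-trimmed reads
#'   ([Biostrings::QualityScaledDNAStringSet]).
#' @param maxLen,minLen fragment length bounds (defaults 60 and 40 nt).
#' @return a [Biostrings::QualityScaledDNAStringSet] of fragments.
#' @export
fragmentReads <- function(reads, maxLen = 60L, minLen = 40L) {
  L <- width(reads)
  nFull <- L %/% maxLen
  rem <- L - nFull * maxLen
  counts <- nFull + (rem >= minLen)
  keep <- counts > 0L
  readIdx <- rep(which(keep), counts[keep])
  ord <- sequence(counts[keep])
  starts <- (ord - 1L) * maxLen + 1L
  ends <- pmin(starts + maxLen - 1L, L[readIdx])
  sq <- substring(as.character(reads)[readIdx], starts, ends)
  qu <- substring(as.character(quality(reads))[readIdx], starts, ends)
  out <- QualityScaledDNAStringSet(DNAStringSet(sq),
                                   PhredQuality(BStringSet(qu)))
  names(out) <- paste0(names(reads)[readIdx], "/", ord)
  out
}

#' Build a seed index over a reference set
#'
#' Exact-substring candidate lookup over both strands: the mapper's seed is
#' split into two half-length blocks, and any ungapped placement with at
#' most one seed mismatch leaves at least one block exact, so exact block
#' lookup enumerates every admissible candidate. Rebuilding from the same
#' reference is deterministic.
#'
#' @param refs a named [Biostrings::DNAStringSet].
#' @param seedLen seed length the index serves (default 28).
#' @return a [SeedIndex-class] object.
#' @export
buildSeedIndex <- function(refs, seedLen = 28L) {
  stopifnot(length(refs) > 0)
  ptr <- cpp_index_build(as.character(refs), names(refs), as.integer(seedLen))
  new("SeedIndex", refs = refs, seedLen = as.integer(seedLen), ptr = ptr)
}

#' Exact-occurrence candidate lookup
#'
#' All exact full-length occurrences of `query` in the indexed references,
#' on either strand (a query containing N matches nowhere).
#'
#' @param index a [buildSeedIndex()] result.
#' @param query a nucleotide string.
#' @return data.frame with `transcript_id`, `position` (0-based) and
#'   `strand`.
#' @export
lookupCandidates <- function(index, query) {
  hits <- cpp_index_lookup(index@ptr, .normalizeSeq(as.character(query)))
  data.frame(transcript_id = names(index@refs)[hits$ref],
             position = hits$pos, strand = hits$strand,
             stringsAsFactors = FALSE)
}

#' Map fragments to an indexed reference
#'
#' Ungapped end-to-end placement of each trimmed fragment on either strand
#' under the [mappingPolicy()]: at most `maxSeedMismatches` mismatches in
#' the seed (the first `seedLen` bases of the trimmed fragment, read in
#' read orientation) and summed Phred quality over all mismatches at most
#' `maxQualMismatchSum`. Among admissible placements the one with fewest
#' total mismatches wins; ties go to the lowest quality-mismatch sum, then
#' the lexicographically smallest transcript id, the smallest position,
#' and the + strand, so output is fully deterministic. A fragment shorter
#' than `trim5 + trim3 + 1` is unmapped.
#'
#' @param fragments a [Biostrings::QualityScaledDNAStringSet] from
#'   [fragmentReads()].
#' @param index a [buildSeedIndex()] result.
#' @param policy a [mappingPolicy()].
#' @return data.frame with one row per fragment: `fragment_id`,
#'   `transcript_id` (NA when unmapped), `position` (0-based offset of the
#'   trimmed fragment), `strand`, `n_mismatches`, `qual_mismatch_sum`,
#'   `n_ties`.
#' @export
mapFragments <- function(fragments, index, policy = mappingPolicy()) {
  nm <- names(index@refs)
  rank <- match(nm, sort(nm, method = "radix"))
  hits <- cpp_map_fragments(index@ptr, as.character(fragments),
                            as.character(quality(fragments)),
                            policy@trim5, policy@trim3, index@seedLen,
                            policy@maxSeedMismatches,
                            policy@maxQualMismatchSum, rank)
  tid <- rep(NA_character_, nrow(hits))
  mapped <- hits$ref > 0L
  tid[mapped] <- nm[hits$ref[mapped]]
  data.frame(fragment_id = names(fragments),
             transcript_id = tid,
             position = hits$pos, strand = hits$strand,
             n_mismatches = hits$n_mismatch,
             qual_mismatch_sum = hits$qual_mismatch_sum,
             n_ties = hits$n_ties, stringsAsFactors = FALSE)
}

# Per-reference mapped-fragment counts for one round, keyed like `ids`.
.countByRef <- function(hits, ids) {
  tab <- table(factor(hits$transcript_id[!is.na(hits$transcript_id)],
                      levels = ids))
  as.integer(tab)
}

#' Run the four mapping rounds
#'
#' Rounds: (1) population-A fragments on the A consensus, (2) A fragments
#' on the B consensus, (3) B fragments on the B consensus, (4) B fragments
#' on the A consensus. Population A plays the sGSL role. Both consensus
#' sets are keyed by `pair_id`, so per-pair counts from different rounds
#' are commensurable.
#'
#' @param fragmentsA,fragmentsB fragment sets from [fragmentReads()].
#' @param pairs a [ConsensusPairs-class] object.
#' @param policy a [mappingPolicy()].
#' @param keepHits also return the per-fragment hit tables.
#' @return list with `counts` (integer matrix, pairs x rounds),
#'   `round_totals`, `n_fragments` (per population), `remap_fraction`
#'   (per round), and optionally `hits`.
#' @export
runFourRounds <- function(fragmentsA, fragmentsB, pairs,
                          policy = mappingPolicy(), keepHits = FALSE) {
  ids <- names(pairs)
  idxA <- buildSeedIndex(consensusA(pairs), policy@seedLen)
  idxB <- buildSeedIndex(consensusB(pairs), policy@seedLen)
  h <- list(round1 = mapFragments(fragmentsA, idxA, policy),
            round2 = mapFragments(fragmentsA, idxB, policy),
            round3 = mapFragments(fragmentsB, idxB, policy),
            round4 = mapFragments(fragmentsB, idxA, policy))
  counts <- vapply(h, .countByRef, integer(length(ids)), ids = ids)
  if (length(ids) == 1L) counts <- matrix(counts, nrow = 1L,
                                          dimnames = list(ids, names(h)))
  rownames(counts) <- ids
  totals <- as.integer(colSums(counts))
  names(totals) <- colnames(counts)
  nFrag <- c(A = length(fragmentsA), B = length(fragmentsB))
  denom <- c(nFrag["A"], nFrag["A"], nFrag["B"], nFrag["B"])
  out <- list(counts = counts, round_totals = totals, n_fragments = nFrag,
              remap_fraction = ifelse(denom > 0, totals / denom, NA_real_))
  if (keepHits) out$hits <- h
  out
}

#' Write mapped fragments as SAM
#'
#' Ungapped alignments of the trimmed fragments: CIGAR `<n>M`, `NM` tag =
#' mismatches, FLAG 0/16 by strand, unmapped fragments as FLAG 4 records.
#'
#' @param hits a [mapFragments()] result.
#' @param fragments the fragment set that produced `hits`.
#' @param index the [buildSeedIndex()] used.
#' @param policy the [mappingPolicy()] used.
#' @param path output SAM file.
#' @return `path`, invisibly.
#' @export
writeSam <- function(hits, fragments, index, policy, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(index@refs),
                       width(index@refs))), con)
  sq <- substring(as.character(fragments), policy@trim5 + 1L,
                  width(fragments) - policy@trim3)
  qu <- substring(as.character(quality(fragments)), policy@trim5 + 1L,
                  width(fragments) - policy@trim3)
  minus <- !is.na(hits$strand) & hits$strand == "-"
  if (any(minus)) {
    sq[minus] <- as.character(reverseComplement(DNAStringSet(sq[minus])))
    qu[minus] <- vapply(strsplit(qu[minus], ""), function(x)
      paste(rev(x), collapse = ""), character(1))
  }
  mapped <- !is.na(hits$transcript_id)
  flag <- ifelse(mapped, ifelse(minus, 16L, 0L), 4L)
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                   hits$fragment_id, flag,
                   ifelse(mapped, hits$transcript_id, "*"),
                   ifelse(mapped, hits$position + 1L, 0L),
                   ifelse(mapped, 255L, 0L),
                   ifelse(mapped, sprintf("%dM", nchar(sq)), "*"),
                   sq, qu,
                   ifelse(mapped, sprintf("\tNM:i:%d", hits$n_mismatches), ""))
  writeLines(lines, con)
  invisible(path)
}

#' Write per-pair round counts as TSV
#'
#' Long format: pair_id, round, count.
#'
#' @param rounds a [runFourRounds()] result.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeRoundCounts <- function(rounds, path) {
  cn <- rounds$counts
  df <- data.frame(pair_id = rep(rownames(cn), ncol(cn)),
                   round = rep(colnames(cn), each = nrow(cn)),
                   count = as.vector(cn), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
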