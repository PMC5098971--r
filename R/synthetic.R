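## Synthetic two-population dataset: diverged transcriptome pair with known
## expression ratios, and 454-like single-end reads.

#' Construct a simulation configuration
#'
#' Defaults describe the emulated study system: a few hundred transcripts
#' of 500-1500 nt at balanced GC, two lineages diverged symmetrically
#' (each mutated at `divergence / 2` from a common ancestor) so that
#' homologous pairs share about `1 - divergence` nucleotide identity, and
#' single-end 454-titanium-like reads (~200-600 nt, homopolymer-biased
#' indel errors, Phred qualities decaying linearly toward the 3' end so
#' Q20 end-trimming is exercised).
#'
#' @param nTranscripts number of ancestral transcripts (homolog pairs).
#' @param lenRange transcript length range in nt, `(min, max)`.
#' @param gcFraction target GC content of ancestral sequences.
#' @param divergence expected pairwise nucleotide divergence between
#'   homologs (per-site substitution probability; each lineage receives
#'   half).
#' @param indelRate expected pairwise per-site indel probability (each
#'   lineage receives half).
#' @param exprLog2fc per-transcript true log2(B/A) expression ratios;
#'   empty (default) draws them from Normal(0, 1).
#' @param readsPerPopulation single-end reads simulated per population.
#' @param readLenMean,readLenSd read length distribution in nt (Normal,
#'   truncated to `[40, transcript length]`).
#' @param errorSubRate per-base substitution sequencing-error rate.
#' @param homopolymerIndelRate per homopolymer run (>= 3 identical bases)
#'   probability of a one-base expansion or contraction.
#' @param qualStart,qualEnd Phred quality at the 5' and 3' read ends
#'   (linear decay between them, with small jitter).
#' @param seed integer seed; fully determines all outputs.
#' @return a [SimConfig-class] object.
#' @export
simConfig <- function(nTranscripts = 200L, lenRange = c(500L, 1500L),
                      gcFraction = 0.5, divergence = 0.04,
                      indelRate = 0.001, exprLog2fc = numeric(0),
                      readsPerPopulation = 20000L,
                      readLenMean = 420, readLenSd = 80,
                      errorSubRate = 0.005, homopolymerIndelRate = 0.005,
                      qualStart = 38L, qualEnd = 15L, seed = 1L) {
  new("SimConfig", nTranscripts = as.integer(nTranscripts),
      lenRange = as.integer(lenRange), gcFraction = gcFraction,
      divergence = divergence, indelRate = indelRate,
      exprLog2fc = as.numeric(exprLog2fc),
      readsPerPopulation = as.integer(readsPerPopulation),
      readLenMean = readLenMean, readLenSd = readLenSd,
      errorSubRate = errorSubRate,
      homopolymerIndelRate = homopolymerIndelRate,
      qualStart = as.integer(qualStart), qualEnd = as.integer(qualEnd),
      seed = as.integer(seed))
}

# Random ancestral sequences at the target GC (i.i.d. bases).
.randomSeqs <- function(n, lens, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  all <- sample(names(p), sum(lens), replace = TRUE, prob = p)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  vapply(seq_len(n), function(i)
    paste(all[starts[i]:ends[i]], collapse = ""), character(1))
}

#' Generate a diverged transcriptome pair with ground truth
#'
#' Draws ancestral sequences i.i.d. at the target GC, then mutates each
#' population's copy independently at `divergence / 2` substitutions and
#' `indelRate / 2` indels per site, so expected pairwise identity is about
#' `1 - divergence`. True expression log2 ratios are taken from the config
#' (or drawn); weights are split symmetrically,
#' `w_A = base * 2^(-fc/2)`, `w_B = base * 2^(+fc/2)`, with a shared
#' log-normal per-transcript baseline. Realized pairwise identity is
#' measured by local alignment of each homolog pair.
#'
#' @param config a [simConfig()]. The config seed is set on entry, so the
#'   output is fully determined by the config.
#' @return list with `transcriptsA`, `transcriptsB` (named
#'   [Biostrings::DNAStringSet]s) and `truth` (data.frame: `pair_id`,
#'   `id_A`, `id_B`, `true_log2fc`, `true_identity`, `weight_A`,
#'   `weight_B`).
#' @export
generateTranscriptomePair <- function(config) {
  validObject(config)
  set.seed(config@seed)
  n <- config@nTranscripts
  lens <- config@lenRange[1] +
    floor(runif(n) * (config@lenRange[2] - config@lenRange[1] + 1L))
  anc <- .randomSeqs(n, as.integer(lens), config@gcFraction)
  seqsA <- cpp_mutate_seqs(anc, config@divergence / 2,
                           config@indelRate / 2, 0)
  seqsB <- cpp_mutate_seqs(anc, config@divergence / 2,
                           config@indelRate / 2, 0)
  # a user-supplied fc design gets exactly those weights (unit baseline);
  # otherwise fc and a per-transcript log-normal baseline are drawn
  if (length(config@exprLog2fc)) {
    fc <- config@exprLog2fc
    base <- rep(1, n)
  } else {
    fc <- rnorm(n, 0, 1)
    base <- rlnorm(n, meanlog = 0, sdlog = 0.7)
  }
  idsA <- sprintf("A%05d", seq_len(n))
  idsB <- sprintf("B%05d", seq_len(n))
  tA <- DNAStringSet(seqsA); names(tA) <- idsA
  tB <- DNAStringSet(seqsB); names(tB) <- idsB
  sc <- scoringScheme()
  ident <- vapply(seq_len(n), function(i)
    .bestStrand(localAlign(seqsA[i], seqsB[i], sc))$identity, numeric(1))
  truth <- data.frame(pair_id = sprintf("anc%05d", seq_len(n)),
                      id_A = idsA, id_B = idsB, true_log2fc = fc,
                      true_identity = ident,
                      weight_A = base * 2^(-fc / 2),
                      weight_B = base * 2^(fc / 2),
                      stringsAsFactors = FALSE)
  list(transcriptsA = tA, transcriptsB = tB, truth = truth)
}

#' Simulate 454-like single-end reads
#'
#' Source transcripts are chosen with probability proportional to
#' `weight * length` (length-proportional sampling, which makes RPKM an
#' unbiased estimator of the weight ratio), start positions uniform,
#' lengths Normal truncated to `[40, transcript length]`, strand uniform.
#' Substitution errors are uniform; homopolymer runs of three or more
#' identical bases expand or contract by one base at
#' `homopolymerIndelRate` (the dominant 454 error mode). Qualities decay
#' linearly from `qualStart` at the 5' end to `qualEnd` at the 3' end with
#' small jitter.
#'
#' All randomness comes from R's single RNG stream: pass `seed` to start a
#' reproducible stream here, or leave it NULL to continue the caller's
#' stream (as [simulateDataset()] does).
#'
#' @param transcripts a named [Biostrings::DNAStringSet].
#' @param weights strictly positive expression weights, one per transcript.
#' @param config a [simConfig()] (read-geometry and error fields used).
#' @param population label used in read ids.
#' @param seed optional integer seed.
#' @return list with `reads` ([Biostrings::QualityScaledDNAStringSet]) and
#'   `truth` (data.frame: `read_id`, `transcript_id`, `start` 0-based,
#'   `strand`, `length`).
#' @export
simulateReads <- function(transcripts, weights, config, population = "A",
                          seed = NULL) {
  if (!length(transcripts)) stop("empty transcript set")
  stopifnot(length(weights) == length(transcripts), all(weights > 0))
  if (!is.null(seed)) set.seed(seed)
  n <- config@readsPerPopulation
  tseq <- as.character(transcripts)
  tlen <- width(transcripts)
  idx <- sample(length(transcripts), n, replace = TRUE,
                prob = weights * tlen)
  rlen <- as.integer(round(rnorm(n, config@readLenMean, config@readLenSd)))
  rlen <- pmin(pmax(rlen, 40L), tlen[idx])
  start <- 1L + as.integer(floor(runif(n) * (tlen[idx] - rlen + 1L)))
  minus <- runif(n) < 0.5
  raw <- substring(tseq[idx], start, start + rlen - 1L)
  if (any(minus))
    raw[minus] <- as.character(reverseComplement(DNAStringSet(raw[minus])))
  mut <- cpp_mutate_seqs(raw, config@errorSubRate, 0,
                         config@homopolymerIndelRate)
  L <- nchar(mut)
  readIdx <- rep.int(seq_len(n), L)
  posInRead <- sequence(L)
  den <- L[readIdx] - 1L
  den[den < 1L] <- 1L
  frac <- (posInRead - 1L) / den
  q <- config@qualStart + (config@qualEnd - config@qualStart) * frac +
    (runif(length(frac)) * 6 - 3)   # small uniform jitter, +/- 3

  q <- as.integer(q + 0.5)   # round half up; jitter makes ties measure-zero
  q[q < 2L] <- 2L
  q[q > 40L] <- 40L
  qstr <- substring(intToUtf8(q + 33L), cumsum(L) - L + 1L, cumsum(L))
  ids <- sprintf("%s_r%06d", population, seq_len(n))
  reads <- QualityScaledDNAStringSet(DNAStringSet(mut),
                                     PhredQuality(BStringSet(qstr)))
  names(reads) <- ids
  truth <- data.frame(read_id = ids, transcript_id = names(transcripts)[idx],
                      start = start - 1L,
                      strand = ifelse(minus, "-", "+"),
                      length = L, stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Write a complete synthetic dataset to disk
#'
#' Generates the transcriptome pair and one read set per population under
#' a single RNG stream seeded from the config, and writes two FASTA
#' transcriptomes, two FASTQ read sets, and the pair- and read-level truth
#' tables as TSV. Deterministic per seed.
#'
#' @param config a [simConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the list of generated objects.
#' @export
simulateDataset <- function(config, outDir) {
  validObject(config)
  if (config@nTranscripts < 1L) stop("nTranscripts must be >= 1")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pair <- generateTranscriptomePair(config)   # sets the seed
  rdA <- simulateReads(pair$transcriptsA, pair$truth$weight_A, config, "A")
  rdB <- simulateReads(pair$transcriptsB, pair$truth$weight_B, config, "B")
  writeTranscripts(pair$transcriptsA, file.path(outDir, "transcriptsA.fasta"))
  writeTranscripts(pair$transcriptsB, file.path(outDir, "transcriptsB.fasta"))
  writeReads(rdA$reads, file.path(outDir, "readsA.fastq"))
  writeReads(rdB$reads, file.path(outDir, "readsB.fastq"))
  write.table(pair$truth, file.path(outDir, "truth_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(rbind(rdA$truth, rdB$truth), file.path(outDir, "truth_reads.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(pair = pair, readsA = rdA, readsB = rdB))
}
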