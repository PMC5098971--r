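#' Nucleotide alignment scoring scheme with Karlin-Altschul statistics
#'
#' Holds match/mismatch scores, affine gap costs (a gap of length L costs
#' `gapOpen + L * gapExtend`), the assumed background base composition, and
#' the Karlin-Altschul parameters lambda, K and H derived from the ungapped
#' score distribution at that composition. Use [scoringScheme()] to
#' construct one; lambda and K are solved numerically there so that any
#' match/mismatch combination stays self-consistent.
#'
#' @slot match positive match score.
#' @slot mismatch negative mismatch score (also applied to any column
#'   involving N, which never matches).
#' @slot gapOpen,gapExtend positive affine gap costs.
#' @slot baseFreqs background frequencies of A, C, G, T (sums to 1).
#' @slot lambda,K,H Karlin-Altschul scale, constant, and relative entropy
#'   (nats per aligned column) for the ungapped score distribution.
#' @export
setClass("ScoringScheme",
  representation(match = "integer", mismatch = "integer",
                 gapOpen = "integer", gapExtend = "integer",
                 baseFreqs = "numeric",
                 lambda = "numeric", K = "numeric", H = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@match > 0L && object@mismatch < 0L))
      msg <- c(msg, "need match > 0 > mismatch")
    if (!(object@gapOpen > 0L && object@gapExtend > 0L))
      msg <- c(msg, "gap costs must be positive")
    if (length(object@baseFreqs) != 4L ||
        abs(sum(object@baseFreqs) - 1) > 1e-8 || any(object@baseFreqs <= 0))
      msg <- c(msg, "baseFreqs must be 4 positive values summing to 1")
    if (!(object@lambda > 0 && object@K > 0))
      msg <- c(msg, "lambda and K must be positive")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme: match %+d mismatch %+d gap %d/%d\n",
              object@match, object@mismatch, object@gapOpen, object@gapExtend))
  cat(sprintf("  lambda = %.6f  K = %.4f  H = %.4f nats/col\n",
              object@lambda, object@K, object@H))
})

#' Fragment mapping policy
#'
#' Emulates a Bowtie-1 style `-n 1 -5 5 -3 5` invocation: `trim5`/`trim3`
#' bases are removed from the fragment ends, placements are ungapped and
#' end-to-end for the trimmed fragment, at most `maxSeedMismatches`
#' mismatches are allowed in the first `seedLen` bases of the (trimmed)
#' fragment, and the Phred qualities at all mismatched positions must sum to
#' at most `maxQualMismatchSum`.
#'
#' @slot trim5,trim3 bases trimmed from the fragment ends before mapping.
#' @slot seedLen seed length in bases (the fragment itself if shorter).
#' @slot maxSeedMismatches maximum mismatches inside the seed (0 or 1).
#' @slot maxQualMismatchSum maximum sum of Phred qualities at mismatches.
#' @export
setClass("MappingPolicy",
  representation(trim5 = "integer", trim3 = "integer", seedLen = "integer",
                 maxSeedMismatches = "integer", maxQualMismatchSum = "integer"),
  validity = function(object) {
    v <- c(object@trim5, object@trim3, object@seedLen,
           object@maxSeedMismatches, object@maxQualMismatchSum)
    if (any(v < 0L)) return("policy fields must be non-negative")
    if (object@maxSeedMismatches > 1L)
      return("maxSeedMismatches > 1 is not supported")
    TRUE
  })

setMethod("show", "MappingPolicy", function(object) {
  cat(sprintf(
    "MappingPolicy: trim 5'/3' = %d/%d, seed %d nt (<= %d mismatch), qual budget %d\n",
    object@trim5, object@trim3, object@seedLen,
    object@maxSeedMismatches, object@maxQualMismatchSum))
})

#' Simulation configuration for the synthetic two-population dataset
#'
#' Parameters of the generator that emulates two transcriptomes diverged
#' from a common ancestor with known per-transcript expression ratios, and
#' 454-titanium-like single-end reads (homopolymer-biased indels, qualities
#' decaying toward the 3' end). See [simConfig()] for defaults and units.
#'
#' @export
setClass("SimConfig",
  representation(nTranscripts = "integer", lenRange = "integer",
                 gcFraction = "numeric", divergence = "numeric",
                 indelRate = "numeric", exprLog2fc = "numeric",
                 readsPerPopulation = "integer",
                 readLenMean = "numeric", readLenSd = "numeric",
                 errorSubRate = "numeric", homopolymerIndelRate = "numeric",
                 qualStart = "integer", qualEnd = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    rates <- c(object@gcFraction, object@divergence, object@indelRate,
               object@errorSubRate, object@homopolymerIndelRate)
    if (any(rates < 0) || any(rates > 1))
      msg <- c(msg, "all rates must be in [0, 1]")
    if (object@nTranscripts < 1L) msg <- c(msg, "nTranscripts must be >= 1")
    if (length(object@lenRange) != 2L || object@lenRange[1] > object@lenRange[2])
      msg <- c(msg, "lenRange must be (min, max) with min <= max")
    if (length(object@exprLog2fc) &&
        length(object@exprLog2fc) != object@nTranscripts)
      msg <- c(msg, "exprLog2fc must be empty or one value per transcript")
    if (object@readsPerPopulation < 0L) msg <- c(msg, "readsPerPopulation < 0")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d transcripts (%d-%d nt, GC %.2f), divergence %.3f, %d reads/pop, seed %d\n",
    object@nTranscripts, object@lenRange[1], object@lenRange[2],
    object@gcFraction, object@divergence, object@readsPerPopulation,
    object@seed))
})

#' Paired consensus transcriptomes
#'
#' The unit of cross-population quantification: for every reciprocal-best
#' homolog pair, the highest-scoring local-alignment window cut from the
#' population-A transcript (`consensusA`) and from the population-B
#' transcript (`consensusB`), both stored on the A-relative forward strand
#' and sharing a `pair_id`. `pairInfo()` gives source ids, 0-based half-open
#' window coordinates, strand, score and identity per pair.
#'
#' @export
setClass("ConsensusPairs",
  representation(seqA = "DNAStringSet", seqB = "DNAStringSet",
                 pairInfo = "data.frame"),
  validity = function(object) {
    msg <- NULL
    n <- nrow(object@pairInfo)
    if (length(object@seqA) != n || length(object@seqB) != n)
      msg <- c(msg, "seqA, seqB and pairInfo must have one entry per pair")
    need <- c("pair_id", "id_A", "id_B", "qs", "qe", "ts", "te",
              "strand", "score", "identity")
    if (!all(need %in% colnames(object@pairInfo)))
      msg <- c(msg, paste("pairInfo lacks columns:",
                          paste(setdiff(need, colnames(object@pairInfo)),
                                collapse = ", ")))
    else {
      if (anyDuplicated(object@pairInfo$pair_id))
        msg <- c(msg, "pair_id values must be unique")
      if (n && (!identical(names(object@seqA), object@pairInfo$pair_id) ||
                !identical(names(object@seqB), object@pairInfo$pair_id)))
        msg <- c(msg, "sequence names must equal pair_id")
      if (n && (any(width(object@seqA) == 0L) || any(width(object@seqB) == 0L)))
        msg <- c(msg, "consensus sequences must be non-empty")
      if (n && any(width(object@seqA) !=
                   object@pairInfo$qe - object@pairInfo$qs))
        msg <- c(msg, "seqA widths must equal their window lengths")
      if (n && any(width(object@seqB) !=
                   object@pairInfo$te - object@pairInfo$ts))
        msg <- c(msg, "seqB widths must equal their window lengths")
    }
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn ConsensusPairs-class number of consensus pairs.
#' @export
setMethod("length", "ConsensusPairs", function(x) length(x@seqA))

#' @describeIn ConsensusPairs-class pair identifiers.
#' @export
setMethod("names", "ConsensusPairs", function(x) x@pairInfo$pair_id)

#' @describeIn ConsensusPairs-class consensus regions from population A.
#' @export
setMethod("consensusA", "ConsensusPairs", function(x) x@seqA)

#' @describeIn ConsensusPairs-class consensus regions from population B.
#' @export
setMethod("consensusB", "ConsensusPairs", function(x) x@seqB)

#' @describeIn ConsensusPairs-class per-pair window coordinates and scores.
#' @export
setMethod("pairInfo", "ConsensusPairs", function(x) x@pairInfo)

setMethod("show", "ConsensusPairs", function(object) {
  cat(sprintf("ConsensusPairs with %d homolog pairs\n", length(object)))
  if (length(object)) {
    cat(sprintf("  window lengths: %d-%d nt (A), median identity %.3f\n",
                min(width(object@seqA)), max(width(object@seqA)),
                median(object@pairInfo$identity)))
  }
})

#' Seed index over a consensus transcriptome
#'
#' Exact-substring candidate lookup structure over both strands of a
#' reference set, backing the fragment mapper. The seed is split into two
#' half-length blocks so that any ungapped placement with at most one seed
#' mismatch is guaranteed to be enumerated by exact lookup of one block.
#'
#' @export
setClass("SeedIndex",
  representation(refs = "DNAStringSet", seedLen = "integer", ptr = "externalptr"))

setMethod("show", "SeedIndex", function(object) {
  cat(sprintf("SeedIndex: %d sequences, %d bases, seed %d nt (blocks %d+%d)\n",
              length(object@refs), sum(width(object@refs)), object@seedLen,
              object@seedLen %/% 2L, object@seedLen - object@seedLen %/% 2L))
})

#' Per-pair expression results container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one row per consensus
#' pair and one column per mapping round (round1..round4). Assays: `counts`
#' (mapped fragments) and `rpkm`. Row metadata carries the per-population
#' averaged RPKMs, the log2 fold-change `fc` (Scotian-Shelf-role B over
#' sGSL-role A) and the DE `class`. `metadata()` stores per-round totals,
#' thresholds and the zero-handling policy.
#'
#' @export
setClass("CeactResults", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!all(c("counts", "rpkm") %in% names(assays(object))))
      msg <- c(msg, "assays must include 'counts' and 'rpkm'")
    need <- c("len_A", "len_B", "rpkm_A", "rpkm_B", "fc", "class")
    if (!all(need %in% colnames(rowData(object))))
      msg <- c(msg, "rowData must carry len_A, len_B, rpkm_A, rpkm_B, fc, class")
    if (ncol(object) != 4L)
      msg <- c(msg, "expected exactly four mapping rounds")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn CeactResults-class named vector of log2 fold-changes (NA where
#'   undefined under the zero-handling policy).
#' @export
setMethod("foldChanges", "CeactResults", function(x)
  setNames(rowData(x)$fc, rownames(x)))

#' @describeIn CeactResults-class per-pair DE class
#'   (up_in_A / down_in_A / unchanged / undefined).
#' @export
setMethod("deClass", "CeactResults", function(x)
  setNames(rowData(x)$class, rownames(x)))

#' @describeIn CeactResults-class summary counts over classes.
#' @export
setMethod("deSummary", "CeactResults", function(x) {
  cl <- rowData(x)$class
  c(n_up = sum(cl == "up_in_A"), n_down = sum(cl == "down_in_A"),
    n_unchanged = sum(cl == "unchanged"), n_undefined = sum(cl == "undefined"))
})

#' @describeIn CeactResults-class total mapped fragments per round.
#' @export
setMethod("roundTotals", "CeactResults", function(x)
  metadata(x)$round_totals)

setMethod("show", "CeactResults", function(object) {
  callNextMethod()
  s <- deSummary(object)
  cat(sprintf("DE summary: %d up_in_A, %d down_in_A, %d unchanged, %d undefined\n",
              s["n_up"], s["n_down"], s["n_unchanged"], s["n_undefined"]))
})
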