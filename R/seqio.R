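## Sequence I/O, quality trimming, contig filtering and assembly QC.

# Normalize to uppercase A/C/G/T/N; anything else (IUPAC ambiguity codes,
# gaps) becomes N. N never matches in alignment or mapping.
.normalizeSeq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x, perl = TRUE)
}

#' Read a transcriptome from FASTA
#'
#' Sequences are normalized to uppercase A/C/G/T/N on read (any other
#' letter becomes N). Records must have a non-empty header and sequence, and
#' ids must be unique within the file.
#'
#' @param path FASTA file (line-wrapped or not).
#' @return A [Biostrings::DNAStringSet] named by the first whitespace-free
#'   token of each header.
#' @export
readTranscripts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(readDNAStringSet(path, format = "fasta"),
                error = function(e) stop("malformed FASTA in '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  nm <- sub("\\s.*$", "", names(x))
  if (any(!nzchar(nm)))
    stop("malformed FASTA in '", path, "': record ",
         which(!nzchar(nm))[1], " has an empty header")
  if (any(width(x) == 0L))
    stop("malformed FASTA in '", path, "': record '",
         nm[width(x) == 0L][1], "' has an empty sequence")
  if (anyDuplicated(nm))
    stop("duplicate sequence id in '", path, "': ", nm[duplicated(nm)][1])
  out <- DNAStringSet(.normalizeSeq(as.character(x)))
  names(out) <- nm
  out
}

#' Write a transcriptome to FASTA
#'
#' @param transcripts a named [Biostrings::DNAStringSet].
#' @param path output file; lines wrapped at 80 columns.
#' @return `path`, invisibly.
#' @export
writeTranscripts <- function(transcripts, path) {
  writeXStringSet(transcripts, path, width = 80L)
  invisible(path)
}

#' Read single-end reads from FASTQ (Phred+33)
#'
#' Four-line records only; the quality string must match the sequence
#' length (the underlying parser enforces this). Sequences are normalized
#' to uppercase A/C/G/T/N.
#'
#' @param path FASTQ file.
#' @return A [Biostrings::QualityScaledDNAStringSet] with Phred qualities.
#' @export
readReads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(
    suppressWarnings(readQualityScaledDNAStringSet(path,
                                                   quality.scoring = "phred")),
    error = function(e) stop("malformed FASTQ in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm))
    stop("duplicate read id in '", path, "': ", nm[duplicated(nm)][1])
  out <- QualityScaledDNAStringSet(
    DNAStringSet(.normalizeSeq(as.character(x))),
    PhredQuality(BStringSet(as.character(quality(x)))))
  names(out) <- nm
  out
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReads <- function(reads, path) {
  writeXStringSet(reads, path, format = "fastq", qualities = quality(reads))
  invisible(path)
}

#' Phred qualities as an integer list
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @return list of integer vectors, one per read.
#' @export
phredValues <- function(reads) {
  lapply(as.character(quality(reads)), function(q)
    as.integer(charToRaw(q)) - 33L)
}

#' Trim low-quality read ends
#'
#' Scans inward from the 5' end removing bases with quality below
#' `qThreshold` until the first base at or above it is met, and likewise
#' from the 3' end. Interior low-quality bases are retained. A read whose
#' bases are all below the threshold becomes empty.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param qThreshold Phred threshold (default 20, i.e. 1% error).
#' @param dropEmpty drop fully trimmed (empty) reads from the result.
#' @return the trimmed [Biostrings::QualityScaledDNAStringSet].
#' @export
trimReadEnds <- function(reads, qThreshold = 20L, dropEmpty = FALSE) {
  if (!length(reads)) return(reads)
  b <- cpp_trim_bounds(as.character(quality(reads)), as.integer(qThreshold))
  sq <- substring(as.character(reads), b[, 1], b[, 2])
  qu <- substring(as.character(quality(reads)), b[, 1], b[, 2])
  out <- QualityScaledDNAStringSet(DNAStringSet(sq), PhredQuality(BStringSet(qu)))
  names(out) <- names(reads)
  if (dropEmpty) out <- out[width(out) > 0L]
  out
}

#' Drop contigs shorter than a minimum length
#'
#' Keeps exactly the transcripts of length at least `minLen` (a contig of
#' exactly `minLen` is retained), preserving order.
#'
#' @param transcripts a [Biostrings::DNAStringSet].
#' @param minLen minimum contig length in nt (default 200).
#' @return the filtered set.
#' @export
filterMinLength <- function(transcripts, minLen = 200L) {
  transcripts[width(transcripts) >= minLen]
}

#' N50 of a set of contig lengths
#'
#' Sort lengths in decreasing order and accumulate until the running sum
#' first reaches at least half the total; the length at which this occurs
#' is the N50. A running sum exactly equal to half the total counts as
#' reached.
#'
#' @param lengths positive contig lengths.
#' @return the N50 length.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("n50 is undefined for an empty set")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  idx <- which(cumsum(s) >= sum(s) / 2)[1]
  as.integer(s[idx])
}

#' Fraction of fragments mapped back to the assembly
#'
#' @param fragmentsMapped,fragmentsTotal mapped and total fragment counts
#'   (`fragmentsTotal >= fragmentsMapped >= 0`).
#' @return `fragmentsMapped / fragmentsTotal`.
#' @export
remapFraction <- function(fragmentsMapped, fragmentsTotal) {
  if (fragmentsTotal == 0) stop("remap fraction is undefined with no fragments")
  if (fragmentsMapped < 0 || fragmentsMapped > fragmentsTotal)
    stop("need 0 <= fragmentsMapped <= fragmentsTotal")
  fragmentsMapped / fragmentsTotal
}

#' Assembly QC report
#'
#' Standard assembly statistics plus the remap fraction: how many of the
#' 40-60 nt read fragments map back to the assembled transcriptome. Both
#' fragment-level and whole-read-level mapped counts can be supplied; the
#' reported `remap_fraction` is fragment-level (mapping operates on
#' fragments), with the read-level fraction emitted alongside when
#' available.
#'
#' @param transcripts the assembled transcriptome ([Biostrings::DNAStringSet]).
#' @param fragmentsMapped,fragmentsTotal fragment-level remap counts.
#' @param readsMapped,readsTotal optional whole-read remap counts (a read
#'   counts as mapped when at least one of its fragments maps).
#' @return a data.frame of metric/value pairs (class `QcReport`).
#' @export
qcReport <- function(transcripts, fragmentsMapped = NA_integer_,
                     fragmentsTotal = NA_integer_,
                     readsMapped = NA_integer_, readsTotal = NA_integer_) {
  gc <- sum(letterFrequency(transcripts, "GC"))
  tot <- sum(width(transcripts))
  frac <- if (!is.na(fragmentsMapped) && !is.na(fragmentsTotal))
    remapFraction(fragmentsMapped, fragmentsTotal) else NA_real_
  rfrac <- if (!is.na(readsMapped) && !is.na(readsTotal) && readsTotal > 0)
    readsMapped / readsTotal else NA_real_
  out <- data.frame(
    metric = c("n_contigs", "total_bases", "n50", "gc_fraction",
               "fragments_mapped", "fragments_total", "remap_fraction",
               "reads_mapped", "reads_total", "read_remap_fraction"),
    value = c(length(transcripts), tot,
              if (length(transcripts)) n50(width(transcripts)) else 0L,
              if (tot) gc / tot else NA_real_,
              fragmentsMapped, fragmentsTotal, frac,
              readsMapped, readsTotal, rfrac),
    stringsAsFactors = FALSE)
  class(out) <- c("QcReport", "data.frame")
  out
}

#' Write a QC report as TSV
#'
#' @param qc a report from [qcReport()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeQcReport <- function(qc, path) {
  write.table(qc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
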