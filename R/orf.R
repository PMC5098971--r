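## Six-frame translation and longest-ORF extraction.

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames (+1, +2, +3
#' on the forward strand; -1, -2, -3 on the reverse complement) under the
#' standard genetic code, keeping stop symbols (`*`). Trailing 1-2 nt that
#' do not fill a codon are ignored; codons containing N translate to `X`.
#'
#' @param seq a nucleotide sequence (character or [Biostrings::DNAString]).
#' @return an [Biostrings::AAStringSet] of six peptides named
#'   `+1, +2, +3, -1, -2, -3` (empty set for sequences shorter than 3 nt).
#' @examples
#' sixFrameTranslate("ATGGCC")[["+1"]]   # MA
#' @export
sixFrameTranslate <- function(seq) {
  s <- DNAString(.normalizeSeq(as.character(seq)))
  L <- length(s)
  if (L < 3L) return(AAStringSet())
  rc <- reverseComplement(s)
  one <- function(x, off) {
    n <- length(x) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(translate(subseq(x, off + 1L, off + n),
                           if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  peps <- c(one(s, 0L), one(s, 1L), one(s, 2L),
            one(rc, 0L), one(rc, 1L), one(rc, 2L))
  out <- AAStringSet(peps)
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# All maximal stop-free codon runs of one translated frame, as aa-coordinate
# (start, length) pairs. Sequence ends act as run boundaries.
.aaRuns <- function(pep) {
  m <- gregexpr("[^*]+", pep)[[1]]
  if (m[1] == -1L) return(NULL)
  data.frame(aa_start = as.integer(m), aa_len = attr(m, "match.length"))
}

#' Longest open reading frame
#'
#' Over all six frames, an ORF is a maximal run of non-stop codons
#' (stop-to-stop convention; no start codon is required, and sequence ends
#' bound runs). The longest run is returned, with ties broken by frame
#' order +1, +2, +3, -1, -2, -3 and then by leftmost position within the
#' frame; the result is dropped when shorter than `minAa` (a run of
#' exactly `minAa` amino acids is accepted).
#'
#' @param seq a nucleotide sequence.
#' @param minAa minimum ORF length in amino acids (default 80).
#' @return one-row data.frame with `frame`, `start`, `end` (0-based
#'   half-open on the forward strand), `length_aa` and `peptide`, or NULL
#'   when no frame holds an ORF of at least `minAa` amino acids.
#' @export
longestOrf <- function(seq, minAa = 80L) {
  L <- nchar(as.character(seq))
  peps <- sixFrameTranslate(seq)
  if (!length(peps)) return(NULL)
  frames <- names(peps)
  best <- NULL
  for (f in seq_along(frames)) {
    runs <- .aaRuns(as.character(peps[[f]]))
    if (is.null(runs)) next
    top <- runs[which.max(runs$aa_len), ]   # which.max is leftmost on ties
    if (is.null(best) || top$aa_len > best$aa_len) {
      best <- top
      best$frame <- frames[f]
      best$fidx <- f
    }
  }
  if (is.null(best) || best$aa_len < minAa) return(NULL)
  off <- (best$fidx - 1L) %% 3L             # frame offset within its strand
  s0 <- off + (best$aa_start - 1L) * 3L     # 0-based on the translated strand
  e0 <- s0 + best$aa_len * 3L
  if (best$fidx > 3L) { tmp <- s0; s0 <- L - e0; e0 <- L - tmp }  # to forward
  pep <- as.character(subseq(peps[[best$fidx]], best$aa_start,
                             best$aa_start + best$aa_len - 1L))
  data.frame(frame = best$frame, start = s0, end = e0,
             length_aa = best$aa_len, peptide = pep, stringsAsFactors = FALSE)
}

#' Longest ORFs over a transcript set
#'
#' @param transcripts a named [Biostrings::DNAStringSet].
#' @param minAa minimum ORF length in amino acids (default 80).
#' @return data.frame with one row per transcript that holds a valid ORF:
#'   `transcript_id`, `frame`, `start`, `end`, `length_aa`, `peptide`.
#' @export
longestOrfs <- function(transcripts, minAa = 80L) {
  rows <- lapply(seq_along(transcripts), function(i) {
    r <- longestOrf(transcripts[[i]], minAa)
    if (!is.null(r)) cbind(transcript_id = names(transcripts)[i], r)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(transcript_id = character(0), frame = character(0),
                      start = integer(0), end = integer(0),
                      length_aa = integer(0), peptide = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write ORF results
#'
#' A TSV (transcript_id, frame, start, end, length_aa) and, optionally, a
#' peptide FASTA.
#'
#' @param orfs a [longestOrfs()] result.
#' @param path output TSV.
#' @param fastaPath optional peptide FASTA path.
#' @return `path`, invisibly.
#' @export
writeOrfs <- function(orfs, path, fastaPath = NULL) {
  write.table(orfs[, c("transcript_id", "frame", "start", "end", "length_aa")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fastaPath)) {
    aa <- AAStringSet(orfs$peptide)
    names(aa) <- sprintf("%s|%s|%d-%d", orfs$transcript_id, orfs$frame,
                         orfs$start, orfs$end)
    writeXStringSet(aa, fastaPath, width = 80L)
  }
  invisible(path)
}
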