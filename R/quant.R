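## RPKM quantification, round averaging, fold-change and DE classification.

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = 1e9 * count / (length * totalMapped)`; defined as 0 when
#' nothing mapped in the round. Scale-invariant: multiplying every count
#' in a round (hence the total) by a constant leaves RPKMs unchanged.
#'
#' @param count mapped-fragment count(s).
#' @param lengthNt reference sequence length(s) in nt.
#' @param totalMapped total mapped fragments in the round.
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 500, 1e6)   # 20
#' @export
rpkm <- function(count, lengthNt, totalMapped) {
  stopifnot(all(lengthNt >= 1), totalMapped >= 0)
  if (totalMapped == 0) return(rep(0, length(count)) + 0 * count)
  1e9 * count / (lengthNt * totalMapped)
}

#' Average per-round RPKMs into per-population values
#'
#' Rounds 1 and 2 quantify the sGSL-role population (A), rounds 3 and 4
#' the Scotian-Shelf-role population (B).
#'
#' @param rpkmR1,rpkmR2,rpkmR3,rpkmR4 per-round RPKM vectors.
#' @return data.frame with `rpkm_A` and `rpkm_B`.
#' @export
averagePopulationRpkm <- function(rpkmR1, rpkmR2, rpkmR3, rpkmR4) {
  data.frame(rpkm_A = (rpkmR1 + rpkmR2) / 2, rpkm_B = (rpkmR3 + rpkmR4) / 2)
}

#' Log2 fold-change of averaged RPKMs
#'
#' `fc = log2(rpkmB / rpkmA)` with B in the Scotian-Shelf role and A in the
#' sGSL role. When either side is zero the default policy marks the value
#' undefined (NA, excluded from classification); alternatively a
#' pseudocount is added to both sides.
#'
#' @param rpkmB,rpkmA averaged RPKMs (B = Scotian-Shelf role).
#' @param pseudocount NA for the exclude-as-undefined policy (default), or
#'   a positive epsilon added to both sides.
#' @return fold-change(s); NA where undefined.
#' @examples
#' foldChange(40, 10)   # 2
#' @export
foldChange <- function(rpkmB, rpkmA, pseudocount = NA_real_) {
  if (!is.na(pseudocount)) {
    stopifnot(pseudocount > 0)
    return(log2((rpkmB + pseudocount) / (rpkmA + pseudocount)))
  }
  ifelse(rpkmA > 0 & rpkmB > 0, log2(rpkmB / rpkmA), NA_real_)
}

#' Classify fold-changes
#'
#' Inclusive thresholds: `fc >= downCutoff` is downregulated in the
#' sGSL-role population A, `fc <= upCutoff` is upregulated in A, anything
#' between is unchanged; NA fold-changes are undefined.
#'
#' @param fc log2 fold-change(s), oriented B over A.
#' @param downCutoff threshold for down_in_A (default 1).
#' @param upCutoff threshold for up_in_A (default -1).
#' @return character vector over
#'   `{up_in_A, down_in_A, unchanged, undefined}`.
#' @export
classifyFoldChange <- function(fc, downCutoff = 1, upCutoff = -1) {
  stopifnot(downCutoff > 0, upCutoff < 0)
  ifelse(is.na(fc), "undefined",
         ifelse(fc >= downCutoff, "down_in_A",
                ifelse(fc <= upCutoff, "up_in_A", "unchanged")))
}

#' Build the per-pair expression table
#'
#' Computes per-round RPKMs (each round normalized by the length of the
#' reference actually mapped in that round: rounds 1 and 4 use the A-side
#' consensus length, rounds 2 and 3 the B-side length, which may differ by
#' indels), averages rounds 1-2 into `rpkm_A` and 3-4 into `rpkm_B`,
#' derives fold-changes and classes.
#'
#' @param rounds a [runFourRounds()] result.
#' @param pairs the [ConsensusPairs-class] the rounds were mapped against.
#' @param downCutoff,upCutoff classification thresholds (see
#'   [classifyFoldChange()]).
#' @param pseudocount zero-handling policy (see [foldChange()]).
#' @return a [CeactResults-class] object (one row per pair, one column per
#'   round).
#' @export
expressionTable <- function(rounds, pairs, downCutoff = 1, upCutoff = -1,
                            pseudocount = NA_real_) {
  counts <- rounds$counts
  ids <- names(pairs)
  if (!identical(sort(rownames(counts)), sort(ids)))
    stop("pair ids of the round counts do not match the consensus pairs")
  counts <- counts[ids, , drop = FALSE]
  lenA <- width(consensusA(pairs))
  lenB <- width(consensusB(pairs))
  roundLen <- cbind(round1 = lenA, round2 = lenB, round3 = lenB, round4 = lenA)
  totals <- rounds$round_totals
  rpkms <- vapply(1:4, function(k)
    rpkm(counts[, k], roundLen[, k], totals[k]), numeric(length(ids)))
  if (length(ids) == 1L) rpkms <- matrix(rpkms, nrow = 1L)
  dimnames(rpkms) <- dimnames(counts)
  avg <- averagePopulationRpkm(rpkms[, 1], rpkms[, 2], rpkms[, 3], rpkms[, 4])
  fc <- foldChange(avg$rpkm_B, avg$rpkm_A, pseudocount)
  cls <- classifyFoldChange(fc, downCutoff, upCutoff)
  rd <- DataFrame(pairInfo(pairs)[, c("id_A", "id_B")],
                  len_A = lenA, len_B = lenB,
                  rpkm_A = avg$rpkm_A, rpkm_B = avg$rpkm_B,
                  fc = fc, class = cls)
  rownames(rd) <- ids
  se <- SummarizedExperiment(
    assays = list(counts = counts, rpkm = rpkms), rowData = rd,
    colData = DataFrame(round = colnames(counts),
                        reads = c("A", "A", "B", "B"),
                        reference = c("A", "B", "B", "A"),
                        row.names = colnames(counts)))
  metadata(se) <- list(round_totals = totals,
                       thresholds = c(down = downCutoff, up = upCutoff),
                       pseudocount = pseudocount,
                       remap_fraction = rounds$remap_fraction,
                       n_fragments = rounds$n_fragments)
  new("CeactResults", se)
}

#' Write an expression table as TSV
#'
#' Columns: pair_id, len_A, len_B, c1..c4, rpkm1..rpkm4, rpkm_A, rpkm_B,
#' fc, class.
#'
#' @param results a [CeactResults-class] object.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(results, path) {
  rd <- rowData(results)
  cn <- assay(results, "counts")
  rp <- assay(results, "rpkm")
  df <- data.frame(pair_id = rownames(results), id_A = rd$id_A,
                   id_B = rd$id_B, len_A = rd$len_A, len_B = rd$len_B,
                   c1 = cn[, 1], c2 = cn[, 2], c3 = cn[, 3], c4 = cn[, 4],
                   rpkm1 = rp[, 1], rpkm2 = rp[, 2], rpkm3 = rp[, 3],
                   rpkm4 = rp[, 4], rpkm_A = rd$rpkm_A, rpkm_B = rd$rpkm_B,
                   fc = rd$fc, class = rd$class, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
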