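## End-to-end orchestration: config handling, the staged pipeline run,
## and ground-truth recovery evaluation.

#' Default run configuration
#'
#' All parameters at their study defaults: Q20 end trimming, 200 nt
#' minimum contig length, +1/-2 scoring with gap 5/2, e-value cutoff
#' 1e-20, 40-60 nt fragments, Bowtie-1-style `-n 1 -5 5 -3 5` mapping
#' emulation with a quality budget of 70, and inclusive fold-change
#' thresholds of +1/-1. Population A plays the sGSL role: fold-changes are
#' log2(B RPKM / A RPKM).
#'
#' @return nested configuration list (YAML-serializable).
#' @export
defaultRunConfig <- function() {
  list(
    inputs = list(transcripts_a = NULL, transcripts_b = NULL,
                  reads_a = NULL, reads_b = NULL),
    parameters = list(
      q_threshold = 20L, min_contig_len = 200L,
      match = 1L, mismatch = -2L, gap_open = 5L, gap_extend = 2L,
      e_cutoff = 1e-20, prefilter_k = 16L,
      fragment_min = 40L, fragment_max = 60L,
      trim5 = 5L, trim3 = 5L, seed_len = 28L,
      max_seed_mismatches = 1L, max_qual_mismatch_sum = 70L,
      fc_down = 1, fc_up = -1, pseudocount = NULL,
      sgsl_role = "A"),
    seed = 1L)
}

# Recursively overlay user values onto the defaults. NULL user values
# (YAML drops them on round trip) keep the default.
.mergeConfig <- function(base, user) {
  for (k in names(user)) {
    if (is.null(user[[k]])) next
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- .mergeConfig(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the [defaultRunConfig()] defaults;
#' everything else keeps its default, so a minimal config only lists the
#' four input paths.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  .mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
}

#' Write a run configuration as YAML
#'
#' Round-trips exactly through [readRunConfig()].
#'
#' @param config configuration list.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.log <- function(fmt, ...) message(sprintf(paste0("[ceact] ", fmt), ...))

#' Run the full analysis
#'
#' Executes trim, contig filter, conversion table, consensus extraction,
#' fragmentation, the four mapping rounds and the expression table,
#' writing every intermediate artifact plus per-population QC reports and
#' a machine-readable run manifest under a fixed directory schema
#' (`01_trim/`, `02_consensus/`, `03_map/`, `04_expression/`, `qc/`,
#' `manifest.json`). A rerun with an identical config and inputs is
#' byte-identical. If the config assigns the sGSL role to population B,
#' the populations are swapped on load so that fold-changes keep the
#' log2(Scotian-Shelf-role / sGSL-role) orientation.
#'
#' @param config configuration list (see [readRunConfig()]) or path to a
#'   YAML config.
#' @param outDir output directory.
#' @param seed optional override of the config seed.
#' @return the [CeactResults-class] object, invisibly.
#' @export
runCeact <- function(config, outDir, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  p <- config$parameters
  for (f in unlist(config$inputs))
    if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
  if (any(vapply(config$inputs, is.null, logical(1))))
    stop("config must name transcripts_a/b and reads_a/b")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("01_trim", "02_consensus", "03_map", "04_expression", "qc"))
    dir.create(file.path(outDir, d), showWarnings = FALSE)

  ins <- config$inputs
  if (identical(p$sgsl_role, "B")) {
    ins <- list(transcripts_a = ins$transcripts_b,
                transcripts_b = ins$transcripts_a,
                reads_a = ins$reads_b, reads_b = ins$reads_a)
    .log("sGSL role assigned to population B; populations swapped on load")
  }

  .log("stage trim: reading inputs")
  trA <- readTranscripts(ins$transcripts_a)
  trB <- readTranscripts(ins$transcripts_b)
  rdA <- readReads(ins$reads_a)
  rdB <- readReads(ins$reads_b)

  tmA <- trimReadEnds(rdA, p$q_threshold, dropEmpty = TRUE)
  tmB <- trimReadEnds(rdB, p$q_threshold, dropEmpty = TRUE)
  .log("trimmed reads: A %d -> %d, B %d -> %d (empties dropped)",
       length(rdA), length(tmA), length(rdB), length(tmB))
  writeReads(tmA, file.path(outDir, "01_trim", "trimmedA.fastq"))
  writeReads(tmB, file.path(outDir, "01_trim", "trimmedB.fastq"))

  ftA <- filterMinLength(trA, p$min_contig_len)
  ftB <- filterMinLength(trB, p$min_contig_len)
  .log("contig filter (>= %d nt): A %d -> %d, B %d -> %d",
       p$min_contig_len, length(trA), length(ftA), length(trB), length(ftB))

  policy <- mappingPolicy(p$trim5, p$trim3, p$seed_len,
                          p$max_seed_mismatches, p$max_qual_mismatch_sum)
  frA <- fragmentReads(tmA, p$fragment_max, p$fragment_min)
  frB <- fragmentReads(tmB, p$fragment_max, p$fragment_min)
  .log("fragments: A %d, B %d", length(frA), length(frB))

  # Assembly QC: fragments mapped back to their own full transcriptome.
  for (pop in c("A", "B")) {
    tr <- if (pop == "A") ftA else ftB
    fr <- if (pop == "A") frA else frB
    hits <- mapFragments(fr, buildSeedIndex(tr, p$seed_len), policy)
    mapped <- !is.na(hits$transcript_id)
    readOf <- sub("/\\d+$", "", hits$fragment_id)
    qc <- qcReport(tr, sum(mapped), nrow(hits),
                   length(unique(readOf[mapped])), length(unique(readOf)))
    writeQcReport(qc, file.path(outDir, "qc", paste0("qc_", pop, ".tsv")))
    .log("QC %s: remap fraction %.3f (%d/%d fragments)", pop,
         sum(mapped) / nrow(hits), sum(mapped), nrow(hits))
  }

  .log("stage consensus: conversion table at e <= %g", p$e_cutoff)
  scoring <- scoringScheme(p$match, p$mismatch, p$gap_open, p$gap_extend)
  ct <- buildConversionTable(ftA, ftB, scoring, p$e_cutoff, p$prefilter_k)
  excl <- attr(ct, "exclusions")
  .log("conversion table: %d pairs; %d transcripts without significant match",
       nrow(ct), sum(excl$reason == "no_significant_match"))
  writeConversionTable(ct, file.path(outDir, "02_consensus",
                                     "conversion_table.tsv"))
  pairs <- extractConsensus(ct, ftA, ftB)
  writeConsensus(pairs, file.path(outDir, "02_consensus", "consensusA.fasta"),
                 file.path(outDir, "02_consensus", "consensusB.fasta"))

  .log("stage map: four rounds on %d consensus pairs", length(pairs))
  rounds <- runFourRounds(frA, frB, pairs, policy)
  .log("round totals: %s", paste(rounds$round_totals, collapse = " "))
  writeRoundCounts(rounds, file.path(outDir, "03_map", "counts.tsv"))

  .log("stage expression")
  pseudo <- if (is.null(p$pseudocount)) NA_real_ else as.numeric(p$pseudocount)
  res <- expressionTable(rounds, pairs, p$fc_down, p$fc_up, pseudo)
  writeExpressionTable(res, file.path(outDir, "04_expression",
                                      "expression.tsv"))
  s <- deSummary(res)
  jsonlite::write_json(as.list(s),
                       file.path(outDir, "04_expression", "summary.json"),
                       auto_unbox = TRUE)
  .log("DE summary: %d up_in_A, %d down_in_A, %d unchanged, %d undefined",
       s["n_up"], s["n_down"], s["n_unchanged"], s["n_undefined"])

  manifest <- list(
    package = "ceact",
    version = as.character(packageVersion("ceact")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    input_md5 = as.list(tools::md5sum(unlist(config$inputs))),
    counts = list(reads_in = c(A = length(rdA), B = length(rdB)),
                  reads_after_trim = c(A = length(tmA), B = length(tmB)),
                  contigs_in = c(A = length(trA), B = length(trB)),
                  contigs_after_filter = c(A = length(ftA), B = length(ftB)),
                  fragments = c(A = length(frA), B = length(frB)),
                  consensus_pairs = length(pairs),
                  fragments_mapped_per_round = as.list(rounds$round_totals),
                  de_summary = as.list(s)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Evaluate fold-change recovery against simulation ground truth
#'
#' Joins estimated per-pair fold-changes to the simulator's truth table
#' (via the consensus pairs' source ids), and reports the per-pair error,
#' the median absolute error, sign agreement at `|true| >= 1`, and a
#' confusion matrix of estimated versus true classes. Pairs can be
#' restricted to well-covered ones via `minCount` (minimum mapped-fragment
#' count across all four rounds).
#'
#' @param results a [CeactResults-class] object.
#' @param truth the `truth` data.frame from [generateTranscriptomePair()].
#' @param minCount restrict to pairs whose smallest per-round count is at
#'   least this (default 0 = all pairs).
#' @param downCutoff,upCutoff class thresholds applied to the true
#'   log2 fold-changes.
#' @return list with `per_pair` (data.frame), `median_abs_error`,
#'   `sign_agreement` (fraction, pairs with `|true| >= 1`), `confusion`
#'   (table), `n_evaluated`, and `unmatched` ids.
#' @export
evaluateRecovery <- function(results, truth, minCount = 0L,
                             downCutoff = 1, upCutoff = -1) {
  rd <- rowData(results)
  m <- match(rd$id_A, truth$id_A)
  unmatched <- rownames(results)[is.na(m)]
  keep <- !is.na(m)
  cn <- assay(results, "counts")
  covered <- apply(cn, 1, min) >= minCount
  use <- keep & covered
  per <- data.frame(pair_id = rownames(results)[use],
                    id_A = rd$id_A[use],
                    true_log2fc = truth$true_log2fc[m[use]],
                    fc = rd$fc[use],
                    class = rd$class[use], stringsAsFactors = FALSE)
  per$error <- per$fc - per$true_log2fc
  per$true_class <- classifyFoldChange(per$true_log2fc, downCutoff, upCutoff)
  defined <- !is.na(per$fc)
  strong <- defined & abs(per$true_log2fc) >= 1
  list(per_pair = per,
       median_abs_error = median(abs(per$error[defined])),
       sign_agreement = if (any(strong))
         mean(sign(per$fc[strong]) == sign(per$true_log2fc[strong]))
       else NA_real_,
       confusion = table(estimated = per$class, truth = per$true_class),
       n_evaluated = sum(use), unmatched = unmatched)
}

# Shared core of the ground-truth experiments: simulate, trim, fragment,
# pair, map, quantify, and evaluate against the known log2 ratios.
.groundTruthRun <- function(config, minCount) {
  pair <- generateTranscriptomePair(config)
  rdA <- simulateReads(pair$transcriptsA, pair$truth$weight_A, config, "A")
  rdB <- simulateReads(pair$transcriptsB, pair$truth$weight_B, config, "B")
  frA <- fragmentReads(trimReadEnds(rdA$reads, dropEmpty = TRUE))
  frB <- fragmentReads(trimReadEnds(rdB$reads, dropEmpty = TRUE))
  ct <- buildConversionTable(pair$transcriptsA, pair$transcriptsB)
  pairs <- extractConsensus(ct, pair$transcriptsA, pair$transcriptsB)
  rounds <- runFourRounds(frA, frB, pairs)
  results <- expressionTable(rounds, pairs)
  list(truth = pair$truth, conversion = ct, pairs = pairs, rounds = rounds,
       results = results,
       evaluation = evaluateRecovery(results, pair$truth, minCount = minCount))
}

#' Fold-change recovery experiment
#'
#' Ground-truth validation of the whole procedure: simulates homolog pairs
#' at low divergence with a fixed grid of true log2 fold-changes, runs the
#' complete analysis (trim, fragment, conversion table, consensus, four
#' mapping rounds, RPKM fold-changes), and evaluates recovery on
#' well-covered pairs (at least `minCount` mapped fragments in every
#' round). Defaults: 200 pairs at 2% divergence, true log2 ratios cycling
#' through {-3..3}, and enough reads that essentially every pair clears
#' the coverage bar.
#'
#' @param nPairs number of simulated homolog pairs.
#' @param divergence pairwise divergence between homologs.
#' @param log2fcGrid recycled over pairs as the true log2(B/A) ratios.
#' @param readsPerPopulation simulated reads per population.
#' @param minCount well-covered threshold (mapped fragments per round).
#' @param seed RNG seed.
#' @return list with `truth`, `conversion`, `pairs`, `rounds`, `results`
#'   (a [CeactResults-class]) and `evaluation` (see [evaluateRecovery()]).
#' @export
fcRecoveryExperiment <- function(nPairs = 200L, divergence = 0.02,
                                 log2fcGrid = -3:3,
                                 readsPerPopulation = 50000L,
                                 minCount = 100L, seed = 1L) {
  config <- simConfig(nTranscripts = nPairs, divergence = divergence,
                      exprLog2fc = rep_len(log2fcGrid, nPairs),
                      readsPerPopulation = readsPerPopulation, seed = seed)
  .groundTruthRun(config, minCount)
}

#' Null-control experiment
#'
#' As [fcRecoveryExperiment()] but with identical expression weights in
#' both populations and independent read draws: any pair classified as
#' differentially expressed (|fc| >= 1) among well-covered pairs is a
#' false positive.
#'
#' @inheritParams fcRecoveryExperiment
#' @return as [fcRecoveryExperiment()], plus `false_positive_rate`, the
#'   fraction of well-covered pairs called DE.
#' @export
nullControlExperiment <- function(nPairs = 200L, divergence = 0.04,
                                  readsPerPopulation = 20000L,
                                  minCount = 100L, seed = 1L) {
  config <- simConfig(nTranscripts = nPairs, divergence = divergence,
                      exprLog2fc = rep(0, nPairs),
                      readsPerPopulation = readsPerPopulation, seed = seed)
  out <- .groundTruthRun(config, minCount)
  cls <- out$evaluation$per_pair$class
  out$false_positive_rate <- mean(cls %in% c("up_in_A", "down_in_A"))
  out
}
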