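#' Remove transcripts with low average base coverage
#'
#' A transcript is removed when its average base coverage (total aligned
#' read bases divided by transcript length) is strictly less than
#' `minAvgCoverage`; a transcript at exactly the threshold is retained.
#'
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param txCounts A [TxCounts-class] covering every transcript.
#' @param minAvgCoverage Removal threshold (default 1.0).
#' @return List with `retained` (a `DNAStringSet`) and `removed` (character
#'   ids).
#' @export
coverageFilter <- function(transcripts, txCounts, minAvgCoverage = 1.0) {
  ids <- names(transcripts)
  avg <- avgCoverage(txCounts)
  missing <- setdiff(ids, names(avg))
  if (length(missing)) {
    stop(sprintf("no coverage entry for transcript '%s'", missing[1L]))
  }
  keep <- avg[ids] >= minAvgCoverage
  list(retained = transcripts[keep], removed = ids[!keep])
}

# N50: the largest length L such that contigs of length >= L together hold
# at least half of the assembly's bases.
n50 <- function(lengths) {
  if (length(lengths) == 0L) return(0L)
  s <- sort(as.integer(lengths), decreasing = TRUE)
  cum <- cumsum(as.numeric(s))
  s[which(cum >= sum(as.numeric(s)) / 2)[1L]]
}

#' Standard de novo assembly metrics
#'
#' Computes contig count, total base pairs, mean contig length, N50,
#' percentage of input reads used (mapped), and mean contig coverage.
#'
#' @param transcripts Named [Biostrings::DNAStringSet]; may be empty, in
#'   which case all metrics are zero.
#' @param txCounts Optional [TxCounts-class] for coverage / reads-used
#'   figures.
#' @param totalInputReads Total read pairs sequenced (>= mapped pairs).
#' @return One-row data.frame with columns `contig_count`, `total_bp`,
#'   `mean_contig_length`, `n50`, `pct_reads_used`, `mean_contig_coverage`.
#' @examples
#' tx <- Biostrings::DNAStringSet(setNames(
#'   strrep("A", c(5, 4, 3, 2, 1)), paste0("t", 1:5)))
#' computeMetrics(tx)$n50
#' @export
computeMetrics <- function(transcripts, txCounts = NULL,
                           totalInputReads = NA_real_) {
  lens <- Biostrings::width(transcripts)
  pctUsed <- NA_real_
  meanCov <- NA_real_
  if (!is.null(txCounts)) {
    rate <- mappingRate(txCounts)
    if (!is.na(totalInputReads)) {
      if (totalInputReads < rate[["mapped"]]) {
        stop("totalInputReads is smaller than the mapped pair count")
      }
      pctUsed <- 100 * rate[["mapped"]] / totalInputReads
    }
    meanCov <- mean(avgCoverage(txCounts)[names(transcripts)])
  }
  data.frame(
    contig_count = length(lens),
    total_bp = sum(as.numeric(lens)),
    mean_contig_length = if (length(lens)) mean(lens) else 0,
    n50 = n50(lens),
    pct_reads_used = pctUsed,
    mean_contig_coverage = if (length(lens)) meanCov else 0)
}

#' Assess recovery of a core gene set
#'
#' Aligns each core protein against the assembly's predicted peptides
#' (local alignment, BLOSUM62 scoring). A core gene counts as recovered when
#' some peptide reaches an e-value at or below `evalueCutoff` with an
#' alignment spanning more than `minAlnFraction` of the core gene's length.
#'
#' @param peptides Named [Biostrings::AAStringSet] of predicted peptides.
#' @param core Named `AAStringSet` of core proteins (non-empty).
#' @param evalueCutoff E-value cutoff (default 1.0e-6).
#' @param minAlnFraction Required alignment fraction of the core gene,
#'   exclusive bound (default 0.70).
#' @param config An [orthologyConfig()] supplying protein scoring and
#'   Karlin-Altschul constants.
#' @return List with `fraction` (recovered share), `meanEvalue` and
#'   `meanIdentity` over recovered genes, and `table`, a per-core-gene
#'   data.frame (`core_id`, `best_peptide`, `evalue`, `identity`,
#'   `aln_fraction`, `recovered`).
#' @export
coreGeneRecovery <- function(peptides, core, evalueCutoff = 1.0e-6,
                             minAlnFraction = 0.70,
                             config = orthologyConfig(protein = TRUE)) {
  if (length(core) == 0L) stop("core gene set must be non-empty")
  if (length(peptides) == 0L) stop("peptide set must be non-empty")
  rows <- lapply(names(core), function(cid) {
    best <- NULL
    for (pid in names(peptides)) {
      hit <- localAlign(core[[cid]], peptides[[pid]], config,
                        qid = cid, sid = pid)
      if (is.null(best) || hit$score > best$score) best <- hit
    }
    alnFrac <- best$qcov
    data.frame(core_id = cid, best_peptide = best$sid,
               evalue = best$evalue, identity = best$identity,
               aln_fraction = alnFrac,
               recovered = best$evalue <= evalueCutoff &&
                 alnFrac > minAlnFraction)
  })
  tab <- do.call(rbind, rows)
  rec <- tab[tab$recovered, , drop = FALSE]
  list(fraction = mean(tab$recovered),
       meanEvalue = if (nrow(rec)) mean(rec$evalue) else NA_real_,
       meanIdentity = if (nrow(rec)) mean(rec$identity) else NA_real_,
       table = tab)
}
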