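#' Simulation configuration for the two-species transcriptome generator
#'
#' Holds every tunable of the synthetic-data module: gene complement size and
#' length range, tissue structure, species divergence, and sequencing-layer
#' parameters (read length, insert size, base error rate, 3' quality decay,
#' coverage). Construct with [simConfig()].
#'
#' @slot nGenes Number of species-A genes.
#' @slot lengthRange Min/max transcript length (bp), inclusive.
#' @slot nTissues Number of tissues.
#' @slot tissueNames Tissue labels (length `nTissues`).
#' @slot tissueSpecificFraction Fraction of genes expressed exclusively in
#'   each single tissue.
#' @slot speciesAOnlyFraction Fraction of genes with no species-B ortholog.
#' @slot jcDistance Jukes-Cantor divergence between orthologs
#'   (substitutions/site).
#' @slot readLength Read length in bp.
#' @slot insertMean,insertSd Normal insert-size model (bp).
#' @slot baseErrorRate Per-base sequencing error probability.
#' @slot qualityStart,qualityFloor Linear Phred decay from `qualityStart` at
#'   the 5' end to `qualityFloor` at the 3' end.
#' @slot coverageTarget Expected fold coverage per expressed transcript.
#' @slot seed Integer seed driving all randomness.
#' @aliases SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nGenes = "integer",
  lengthRange = "integer",
  nTissues = "integer",
  tissueNames = "character",
  tissueSpecificFraction = "numeric",
  speciesAOnlyFraction = "numeric",
  jcDistance = "numeric",
  readLength = "integer",
  insertMean = "numeric",
  insertSd = "numeric",
  baseErrorRate = "numeric",
  qualityStart = "integer",
  qualityFloor = "integer",
  coverageTarget = "numeric",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  bad <- function(field) sprintf("invalid configuration field '%s'", field)
  if (length(object@nGenes) != 1L || is.na(object@nGenes) || object@nGenes < 0L)
    return(bad("nGenes"))
  if (length(object@lengthRange) != 2L || any(is.na(object@lengthRange)) ||
      object@lengthRange[1L] < 1L ||
      object@lengthRange[1L] > object@lengthRange[2L])
    return(bad("lengthRange"))
  if (length(object@nTissues) != 1L || is.na(object@nTissues) ||
      object@nTissues < 1L)
    return(bad("nTissues"))
  if (length(object@tissueNames) != object@nTissues ||
      anyDuplicated(object@tissueNames))
    return(bad("tissueNames"))
  for (f in c("tissueSpecificFraction", "speciesAOnlyFraction")) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) return(bad(f))
  }
  if (object@tissueSpecificFraction * object@nTissues > 1)
    return("sum of tissue-specific fractions exceeds 1")
  if (length(object@jcDistance) != 1L || is.na(object@jcDistance) ||
      object@jcDistance < 0)
    return(bad("jcDistance"))
  if (length(object@readLength) != 1L || is.na(object@readLength) ||
      object@readLength < 1L)
    return(bad("readLength"))
  if (object@readLength > object@insertMean)
    return("readLength must not exceed insertMean")
  if (length(object@insertSd) != 1L || is.na(object@insertSd) ||
      object@insertSd < 0)
    return(bad("insertSd"))
  if (length(object@baseErrorRate) != 1L || is.na(object@baseErrorRate) ||
      object@baseErrorRate < 0 || object@baseErrorRate > 1)
    return(bad("baseErrorRate"))
  if (object@qualityFloor < 2L || object@qualityStart < object@qualityFloor ||
      object@qualityStart > 41L)
    return(bad("qualityStart/qualityFloor"))
  if (length(object@coverageTarget) != 1L || is.na(object@coverageTarget) ||
      object@coverageTarget < 0)
    return(bad("coverageTarget"))
  if (length(object@seed) != 1L || is.na(object@seed))
    return(bad("seed"))
  TRUE
})

#' Ground truth of a simulated two-species transcriptome
#'
#' Records what the generator planted, so downstream stages can be scored
#' against it: the A-to-B ortholog map, which tissues each gene is expressed
#' in, expected expression levels, and the set of species-A-only genes.
#'
#' @slot orthologMap Named character vector, species-A id -> species-B id
#'   (A-only genes absent).
#' @slot tissueAssignment Named list, gene id -> character vector of
#'   expressing tissues.
#' @slot expressionLevel Numeric matrix, genes x tissues; zero where a gene is
#'   not expressed.
#' @slot aOnlySet Character vector of species-A-only gene ids.
#' @aliases TranscriptomeTruth-class
#' @exportClass TranscriptomeTruth
setClass("TranscriptomeTruth", representation(
  orthologMap = "character",
  tissueAssignment = "list",
  expressionLevel = "matrix",
  aOnlySet = "character"
))

setValidity("TranscriptomeTruth", function(object) {
  if (length(intersect(object@aOnlySet, names(object@orthologMap))) > 0L)
    return("aOnlySet and orthologMap domains must be disjoint")
  if (nrow(object@expressionLevel) > 0L &&
      any(rowSums(object@expressionLevel > 0) == 0L))
    return("every gene must be expressed in at least one tissue")
  TRUE
})

#' Per-transcript read counts and base coverage
#'
#' A count matrix (transcripts x samples) with companion per-base coverage
#' vectors accumulated over all counted samples. Produced by
#' [countAndCoverage()] and consumed by the coverage filter and the
#' enrichment rules.
#'
#' @slot counts Integer matrix, transcripts x samples.
#' @slot coverage Named list of integer vectors; one per transcript, length
#'   equal to the transcript length.
#' @slot txLengths Named integer vector of transcript lengths.
#' @aliases TxCounts-class
#' @exportClass TxCounts
setClass("TxCounts", representation(
  counts = "matrix",
  coverage = "list",
  txLengths = "integer"
))

setValidity("TxCounts", function(object) {
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!identical(rownames(object@counts), names(object@txLengths)))
    return("count rows and txLengths must share names")
  if (!identical(names(object@coverage), names(object@txLengths)))
    return("coverage and txLengths must share names")
  len <- lengths(object@coverage)
  if (length(len) && any(len != unname(object@txLengths)))
    return("coverage array length must equal transcript length")
  TRUE
})

#' K-mer seed index over a transcript set
#'
#' Maps every k-mer (windows containing N are skipped) to all its
#' (transcript, offset) occurrences; used by the read mapper to seed
#' candidate placements. Construct with [buildIndex()].
#'
#' @slot k Seed length.
#' @slot index Named list: k-mer -> integer indices into the occurrence
#'   table.
#' @slot occTx,occPos Parallel integer vectors: transcript index and 1-based
#'   offset of each occurrence.
#' @slot txIds Transcript identifiers.
#' @slot txSeqs Transcript sequences (character, same order as `txIds`).
#' @aliases KmerIndex-class
#' @exportClass KmerIndex
setClass("KmerIndex", representation(
  k = "integer",
  index = "list",
  occTx = "integer",
  occPos = "integer",
  txIds = "character",
  txSeqs = "character"
))

#' Hexamer Markov models for coding-potential scoring
#'
#' A pair of order-5 nucleotide Markov chains (coding, noncoding), each with
#' codon-phase-specific transition tables and an initial 5-mer distribution.
#' Log-likelihood ratios under the pair score open reading frames; see
#' [trainModels()] and [scoreOrf()].
#'
#' @slot codingTrans,noncodingTrans Numeric arrays `1024 x 4 x 3` of log
#'   transition probabilities: 5-base context x next base x codon phase of
#'   the predicted base.
#' @slot codingInit,noncodingInit Numeric vectors of 1024 log probabilities
#'   for the initial 5-mer.
#' @slot pseudocount Pseudocount applied to every cell during training.
#' @aliases HexamerModel-class
#' @exportClass HexamerModel
setClass("HexamerModel", representation(
  codingTrans = "array",
  noncodingTrans = "array",
  codingInit = "numeric",
  noncodingInit = "numeric",
  pseudocount = "numeric"
))

setValidity("HexamerModel", function(object) {
  for (nm in c("codingTrans", "noncodingTrans")) {
    a <- slot(object, nm)
    if (!identical(dim(a), c(1024L, 4L, 3L)))
      return(sprintf("%s must be a 1024 x 4 x 3 array", nm))
    s <- apply(exp(a), c(1L, 3L), sum)
    if (any(abs(s - 1) > 1e-6))
      return(sprintf("%s rows must be log-probabilities summing to 1", nm))
  }
  TRUE
})

#' Construct a TxCounts object
#'
#' @param counts Matrix (or vector, treated as a one-column matrix) of
#'   non-negative counts with transcript row names.
#' @param coverage Named list of per-base coverage vectors; defaults to
#'   all-zero vectors of the given transcript lengths.
#' @param lengths Named integer vector of transcript lengths.
#' @rdname TxCounts-class
#' @export
txCounts <- function(counts, lengths, coverage = NULL) {
  if (is.null(dim(counts))) {
    counts <- matrix(counts, ncol = 1,
                     dimnames = list(names(counts), "sample1"))
  }
  lengths <- setNames(as.integer(lengths), names(lengths))[rownames(counts)]
  if (is.null(coverage)) {
    coverage <- lapply(lengths, integer)
  }
  new("TxCounts", counts = counts, coverage = coverage[rownames(counts)],
      txLengths = lengths)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,",
      paste(object@lengthRange, collapse = "-"), "bp,",
      object@nTissues, "tissues\n")
  cat("  JC distance:", object@jcDistance,
      " A-only fraction:", object@speciesAOnlyFraction, "\n")
  cat("  reads:", object@readLength, "bp PE, insert",
      object@insertMean, "+/-", object@insertSd,
      "bp, error", object@baseErrorRate,
      ", coverage", object@coverageTarget, "x\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "TranscriptomeTruth", function(object) {
  cat("TranscriptomeTruth:", nrow(object@expressionLevel), "genes,",
      ncol(object@expressionLevel), "tissues;",
      length(object@orthologMap), "orthologs,",
      length(object@aOnlySet), "species-A-only\n")
})

setMethod("show", "TxCounts", function(object) {
  cat("TxCounts:", nrow(object@counts), "transcripts x",
      ncol(object@counts), "samples;",
      sum(object@counts), "assigned pairs\n")
})

setMethod("show", "KmerIndex", function(object) {
  cat("KmerIndex: k =", object@k, ";", length(object@txIds),
      "transcripts,", length(object@occTx), "indexed positions\n")
})

setMethod("show", "HexamerModel", function(object) {
  cat("HexamerModel: order-5, 3-phase coding/noncoding tables,",
      "pseudocount", object@pseudocount, "\n")
})
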