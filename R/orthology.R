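#' Orthology / alignment configuration
#'
#' Scoring defaults follow the classic nucleotide local-alignment scheme
#' (match +2, mismatch -3, gap open 5, gap extend 2); protein mode uses
#' BLOSUM62 with gap open 11 / extend 1. E-values use the Karlin-Altschul
#' formula `E = K * m * n * exp(-lambda * S)` with configurable ungapped
#' constants; `lambda` is solved from the nucleotide scoring scheme when not
#' supplied. E-values are comparable only within a run.
#'
#' @param match,mismatch Nucleotide scores (ignored in protein mode).
#' @param gapOpening,gapExtension Affine gap penalties (positive costs).
#' @param evalueCutoff Hit acceptance cutoff (default 1.0e-6).
#' @param minLengthFraction Subject-coverage fraction used by downstream
#'   filters (default 0.70).
#' @param karlinLambda,karlinK Karlin-Altschul constants.
#' @param protein Use protein scoring (BLOSUM62).
#' @return A list of class `OrthologyConfig`.
#' @export
orthologyConfig <- function(match = 2, mismatch = -3,
                            gapOpening = 5, gapExtension = 2,
                            evalueCutoff = 1.0e-6,
                            minLengthFraction = 0.70,
                            karlinLambda = NULL, karlinK = NULL,
                            protein = FALSE) {
  if (gapOpening < 0 || gapExtension < 0) stop("gap penalties must be >= 0")
  if (protein) {
    gapOpening <- 11
    gapExtension <- 1
    if (is.null(karlinLambda)) karlinLambda <- 0.267
    if (is.null(karlinK)) karlinK <- 0.041
    subMat <- NULL  # resolved lazily to BLOSUM62
  } else {
    if (is.null(karlinLambda)) {
      # solve sum_ij p_i p_j exp(lambda * s_ij) = 1 for uniform base
      # composition
      f <- function(l) 0.25 * exp(match * l) + 0.75 * exp(mismatch * l) - 1
      karlinLambda <- stats::uniroot(f, c(1e-6, 5))$root
    }
    if (is.null(karlinK)) karlinK <- 0.41
    letters <- c("A", "C", "G", "T", "N")
    subMat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
    diag(subMat) <- match
    subMat["N", ] <- mismatch
    subMat[, "N"] <- mismatch
  }
  structure(list(match = match, mismatch = mismatch,
                 gapOpening = gapOpening, gapExtension = gapExtension,
                 evalueCutoff = evalueCutoff,
                 minLengthFraction = minLengthFraction,
                 karlinLambda = karlinLambda, karlinK = karlinK,
                 protein = protein, subMat = subMat),
            class = "OrthologyConfig")
}

substitutionMatrixFor <- function(config) {
  if (!is.null(config$subMat)) return(config$subMat)
  get(utils::data("BLOSUM62", package = "Biostrings",
                  envir = environment())[1L], envir = environment())
}

#' Optimal local alignment with Karlin-Altschul e-value
#'
#' Smith-Waterman-class local alignment under affine-gap scoring (via
#' `Biostrings::pairwiseAlignment`). Identity is computed over aligned
#' columns; the e-value is `K * m * n * exp(-lambda * score)`.
#'
#' @param a,b Query and subject sequences (character or `XString`);
#'   non-empty.
#' @param config An [orthologyConfig()].
#' @param qid,sid Identifiers recorded in the hit.
#' @return A list (an alignment hit): `qid`, `sid`, `score`, `bitscore`,
#'   `evalue`, `identity`, `alnLen`, `qcov`, `scov`.
#' @examples
#' localAlign("ACGTACGT", "ACGTTCGT", qid = "q", sid = "s")$identity
#' @export
localAlign <- function(a, b, config = orthologyConfig(),
                       qid = "query", sid = "subject") {
  a <- as.character(a)
  b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = substitutionMatrixFor(config),
    gapOpening = config$gapOpening, gapExtension = config$gapExtension)
  s <- Biostrings::score(aln)
  m <- nchar(a)
  n <- nchar(b)
  alnLen <- Biostrings::nchar(aln)
  pr <- aln@pattern@range
  sr <- aln@subject@range
  list(qid = qid, sid = sid, score = s,
       bitscore = (config$karlinLambda * s - log(config$karlinK)) / log(2),
       evalue = config$karlinK * m * n * exp(-config$karlinLambda * s),
       identity = Biostrings::nmatch(aln) / alnLen,
       alnLen = alnLen,
       qcov = BiocGenerics::width(pr) / m,
       scov = BiocGenerics::width(sr) / n)
}

hitsToFrame <- function(hits) {
  if (length(hits) == 0L) {
    return(data.frame(qid = character(0), sid = character(0),
                      score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), identity = numeric(0),
                      alnLen = integer(0), qcov = numeric(0),
                      scov = numeric(0)))
  }
  do.call(rbind, lapply(hits, function(h) as.data.frame(h)))
}

#' Highest-scoring hit of a query against a subject set
#'
#' Aligns the query to every subject and returns the highest-scoring hit
#' whose e-value passes the cutoff; ties are broken by lower e-value, then
#' by lexicographically smallest subject id. Returns `NULL` when no hit
#' passes.
#'
#' @param query Query sequence (character or `XString`).
#' @param subjects Named list / `XStringSet` of subject sequences.
#' @param config An [orthologyConfig()].
#' @param qid Query identifier.
#' @return An alignment hit list (see [localAlign()]) or `NULL`.
#' @export
bestHit <- function(query, subjects, config = orthologyConfig(),
                    qid = "query") {
  if (length(subjects) == 0L) stop("subject set must be non-empty")
  best <- NULL
  for (sid in names(subjects)) {
    h <- localAlign(query, subjects[[sid]], config, qid = qid, sid = sid)
    if (h$evalue > config$evalueCutoff) next
    if (is.null(best) || h$score > best$score ||
        (h$score == best$score &&
         (h$evalue < best$evalue ||
          (h$evalue == best$evalue && h$sid < best$sid)))) {
      best <- h
    }
  }
  best
}

# All-vs-all hits between two sequence sets with a shared-k-mer prescreen.
# Pairs sharing fewer than minSharedKmers k-mers are skipped: at the e-value
# cutoff such pairs could not produce an accepted hit for realistic
# transcript lengths, and skipping them keeps the all-vs-all search at
# desk scale. Set minSharedKmers = 0 to align every pair.
allVsAllHits <- function(A, B, config, minSharedKmers = 5, prefilterK = 13) {
  aSeq <- as.character(A)
  bSeq <- as.character(B)
  hits <- list()
  if (minSharedKmers > 0) {
    bKmers <- lapply(bSeq, function(s) unique(seqKmers(s, prefilterK)))
    inv <- split(rep(seq_along(bSeq), lengths(bKmers)), unlist(bKmers))
  }
  for (i in seq_along(aSeq)) {
    if (minSharedKmers > 0) {
      ak <- unique(seqKmers(aSeq[[i]], prefilterK))
      occ <- unlist(inv[ak], use.names = FALSE)
      if (is.null(occ)) occ <- integer(0)
      counts <- tabulate(occ, nbins = length(bSeq))
      cand <- which(counts >= minSharedKmers)
    } else {
      cand <- seq_along(bSeq)
    }
    for (j in cand) {
      h <- localAlign(aSeq[[i]], bSeq[[j]], config,
                      qid = names(A)[i], sid = names(B)[j])
      if (h$evalue <= config$evalueCutoff) hits[[length(hits) + 1L]] <- h
    }
  }
  hitsToFrame(hits)
}

# Index of the best hit per group: max score, then min evalue, then
# lexicographically smallest partner id.
bestPerGroup <- function(hits, groupCol, partnerCol) {
  idx <- integer(0)
  for (g in unique(hits[[groupCol]])) {
    rows <- which(hits[[groupCol]] == g)
    sub <- hits[rows, ]
    o <- order(-sub$score, sub$evalue, sub[[partnerCol]])
    idx <- c(idx, rows[o[1L]])
  }
  idx
}

#' Reciprocal best hit ortholog detection
#'
#' Emits a pair `(a, b)` iff `b` is `a`'s highest-scoring accepted hit in
#' set B and `a` is `b`'s highest-scoring accepted hit in set A; each id
#' appears in at most one pair. Alignment scores are symmetric, so a single
#' all-vs-all pass supplies both directions. A shared-k-mer prescreen
#' (`minSharedKmers`) skips pairs that could not pass the e-value cutoff;
#' set it to 0 to force the exhaustive search.
#'
#' @param A,B Named `DNAStringSet` / character vectors; ids must be unique
#'   within each set and must not collide across sets.
#' @param config An [orthologyConfig()].
#' @param minLengthFraction Optional subject-coverage filter applied to the
#'   emitted pairs (`NULL`, the default, keeps all pairs).
#' @param minSharedKmers,prefilterK Prescreen parameters (see above).
#' @return Data.frame of RBH pairs with the [localAlign()] hit columns.
#' @export
reciprocalBestHits <- function(A, B, config = orthologyConfig(),
                               minLengthFraction = NULL,
                               minSharedKmers = 5, prefilterK = 13) {
  if (anyDuplicated(names(A)) || anyDuplicated(names(B))) {
    stop("ids must be unique within each set")
  }
  if (length(intersect(names(A), names(B)))) {
    stop("id collision across sets")
  }
  hits <- allVsAllHits(A, B, config, minSharedKmers, prefilterK)
  if (nrow(hits) == 0L) return(hits)
  bestA <- hits[bestPerGroup(hits, "qid", "sid"), ]
  bestB <- hits[bestPerGroup(hits, "sid", "qid"), ]
  key <- paste(bestA$qid, bestA$sid)
  mutual <- key %in% paste(bestB$qid, bestB$sid)
  out <- bestA[mutual, ]
  if (!is.null(minLengthFraction)) {
    out <- out[out$scov > minLengthFraction, ]
  }
  rownames(out) <- NULL
  out
}

#' Identity statistics over RBH ortholog pairs
#'
#' Summarizes alignment identity over pairs whose alignment covers more
#' than `minLengthFraction` of the subject sequence.
#'
#' @param pairs Data.frame of RBH pairs ([reciprocalBestHits()]).
#' @param minLengthFraction Exclusive subject-coverage bound (default 0.75).
#' @return List with `count`, `meanIdentity`, `medianIdentity` (the moments
#'   are `NA` when no pair passes).
#' @export
identityStats <- function(pairs, minLengthFraction = 0.75) {
  keep <- pairs[pairs$scov > minLengthFraction, , drop = FALSE]
  list(count = nrow(keep),
       meanIdentity = if (nrow(keep)) mean(keep$identity) else NA_real_,
       medianIdentity = if (nrow(keep)) stats::median(keep$identity)
                        else NA_real_)
}
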