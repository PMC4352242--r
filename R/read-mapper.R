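#' Read mapper configuration
#'
#' @param k Seed length (default 31).
#' @param maxMismatchRate Maximum tolerated mismatch fraction per mate
#'   (default 0.05).
#' @param countMode `"best-single"` (deterministic single assignment,
#'   lexicographic tie-break) or `"all-best"` (every tying transcript is
#'   credited).
#' @param strandSpecific If `TRUE` (default) mate 1 must align to the sense
#'   strand and mate 2 antisense; otherwise both orientations are checked.
#' @return A list of class `MapperConfig`.
#' @export
mapperConfig <- function(k = 31, maxMismatchRate = 0.05,
                         countMode = c("best-single", "all-best"),
                         strandSpecific = TRUE) {
  checkScalarNumber(k, "k", 1)
  checkScalarNumber(maxMismatchRate, "maxMismatchRate", 0, 1)
  structure(list(k = as.integer(k),
                 maxMismatchRate = maxMismatchRate,
                 countMode = match.arg(countMode),
                 strandSpecific = isTRUE(strandSpecific)),
            class = "MapperConfig")
}

#' Build a k-mer seed index over a transcript set
#'
#' Every k-mer of every transcript (windows containing N are skipped) is
#' recorded with all its (transcript, offset) occurrences.
#'
#' @param transcripts Named [Biostrings::DNAStringSet] (or named character
#'   vector).
#' @param k Seed length; must not exceed the length of every transcript
#'   combined (an index with no entries is an error).
#' @return A [KmerIndex-class] object.
#' @examples
#' idx <- buildIndex(Biostrings::DNAStringSet(c(t1 = "ACGTACGT")), k = 4)
#' idx
#' @export
buildIndex <- function(transcripts, k = 31) {
  if (length(transcripts) == 0L) stop("transcripts must be non-empty")
  ids <- names(transcripts)
  if (is.null(ids)) stop("transcripts must be named")
  seqs <- setNames(as.character(transcripts), ids)
  occTx <- integer(0)
  occPos <- integer(0)
  kms <- character(0)
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[[i]])
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    w <- substring(seqs[[i]], starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", w)
    occTx <- c(occTx, rep.int(i, sum(ok)))
    occPos <- c(occPos, starts[ok])
    kms <- c(kms, w[ok])
  }
  if (length(kms) == 0L) {
    stop("empty index: k exceeds the length of every transcript")
  }
  new("KmerIndex", k = as.integer(k),
      index = split(seq_along(kms), kms),
      occTx = occTx, occPos = occPos,
      txIds = ids, txSeqs = unname(seqs))
}

# Candidate (transcript, start) placements of a read (already oriented
# forward relative to the transcript), seeded at the read's two end k-mers.
seedPlacements <- function(read, index) {
  len <- nchar(read)
  k <- index@k
  if (len < k) return(list(tx = integer(0), start = integer(0)))
  offs <- unique(c(1L, len - k + 1L))
  tx <- integer(0)
  start <- integer(0)
  for (o in offs) {
    km <- substr(read, o, o + k - 1L)
    rows <- index@index[[km]]
    if (is.null(rows)) next
    tx <- c(tx, index@occTx[rows])
    start <- c(start, index@occPos[rows] - o + 1L)
  }
  if (length(tx) == 0L) return(list(tx = integer(0), start = integer(0)))
  keep <- !duplicated(paste0(tx, ":", start))
  list(tx = tx[keep], start = start[keep])
}

# Ungapped verification: mismatch count of read placed at start on
# transcript ti, or NA when out of bounds / above the rate cap.
verifyPlacement <- function(read, ti, start, index, maxRate) {
  len <- nchar(read)
  txSeq <- index@txSeqs[[ti]]
  if (start < 1L || start + len - 1L > nchar(txSeq)) return(NA_integer_)
  mm <- hammingMismatches(substr(txSeq, start, start + len - 1L), read)
  if (mm / len > maxRate) return(NA_integer_) else mm
}

#' Map one read pair to the indexed transcripts
#'
#' Seeds from both mates vote for candidate placements, which are verified
#' by ungapped extension. A candidate is accepted if both mates stay within
#' `maxMismatchRate` with consistent orientation (mate 1 sense, mate 2
#' antisense under the strand-specific contract) and a non-negative implied
#' insert. The best candidate has the fewest total mismatches; ties are
#' broken by the lexicographically smallest transcript id.
#'
#' @param mate1,mate2 Character scalars (read sequences).
#' @param index A [KmerIndex-class] built with the same `k`.
#' @param config A [mapperConfig()] list.
#' @return A list: `tx` (transcript id or `NA`), `mismatches`, `start1`,
#'   `start2` (1-based placements of mate 1 and of the reverse-complemented
#'   mate 2), and `txAll` (all transcripts tying the best score).
#' @export
mapPair <- function(mate1, mate2, index, config = mapperConfig()) {
  unmapped <- list(tx = NA_character_, mismatches = NA_integer_,
                   start1 = NA_integer_, start2 = NA_integer_,
                   txAll = character(0))
  orientations <- list(list(r1 = mate1, r2 = reverseComplement1(mate2)))
  if (!config$strandSpecific) {
    orientations <- c(orientations,
                      list(list(r1 = reverseComplement1(mate1), r2 = mate2,
                                swap = TRUE)))
  }
  best <- NULL
  for (ori in orientations) {
    p1 <- seedPlacements(ori$r1, index)
    p2 <- seedPlacements(ori$r2, index)
    common <- intersect(unique(p1$tx), unique(p2$tx))
    for (ti in common) {
      s1s <- p1$start[p1$tx == ti]
      s2s <- p2$start[p2$tx == ti]
      for (s1 in s1s) {
        mm1 <- verifyPlacement(ori$r1, ti, s1, index,
                               config$maxMismatchRate)
        if (is.na(mm1)) next
        for (s2 in s2s) {
          if (s2 < s1) next  # mate 2 fragment end lies downstream
          mm2 <- verifyPlacement(ori$r2, ti, s2, index,
                                 config$maxMismatchRate)
          if (is.na(mm2)) next
          cand <- list(ti = ti, mm = mm1 + mm2, s1 = s1, s2 = s2)
          if (is.null(best) || cand$mm < best$mm ||
              (cand$mm == best$mm &&
               index@txIds[cand$ti] < index@txIds[best$ti])) {
            tie <- if (!is.null(best) && cand$mm == best$mm)
              union(best$tie, index@txIds[cand$ti])
            else index@txIds[cand$ti]
            best <- c(cand, list(tie = tie))
          } else if (cand$mm == best$mm) {
            best$tie <- union(best$tie, index@txIds[cand$ti])
          }
        }
      }
    }
  }
  if (is.null(best)) return(unmapped)
  list(tx = index@txIds[best$ti], mismatches = best$mm,
       start1 = best$s1, start2 = best$s2, txAll = sort(best$tie))
}

#' Count read pairs per transcript and accumulate per-base coverage
#'
#' Maps every pair with [mapPair()] and builds a [TxCounts-class]: counts
#' are assigned pairs per transcript and `coverage[i]` is the number of read
#' bases aligned over transcript position `i`. In `"all-best"` mode every
#' tying transcript is credited; in `"best-single"` (default) the
#' deterministic single assignment is used, so counts are permutation
#' invariant to read order.
#'
#' @param mate1,mate2 `QualityScaledDNAStringSet`, `DNAStringSet`, or
#'   character vectors of mate sequences (equal length).
#' @param index A [KmerIndex-class].
#' @param config A [mapperConfig()] list.
#' @param sample Sample label for the count column.
#' @return A [TxCounts-class] with one sample column; `metadata`-like
#'   attributes `mappedPairs` and `totalPairs` are stored in the counts
#'   matrix's `dimnames`-independent attributes via [mappingRate()].
#' @export
countAndCoverage <- function(mate1, mate2, index, config = mapperConfig(),
                             sample = "sample1") {
  s1 <- as.character(mate1)
  s2 <- as.character(mate2)
  if (length(s1) != length(s2)) {
    stop("pairing error: mate vectors differ in length")
  }
  nTx <- length(index@txIds)
  cnt <- integer(nTx)
  lens <- nchar(index@txSeqs)
  cov <- lapply(lens, integer)
  mapped <- 0L
  for (i in seq_along(s1)) {
    hit <- mapPair(s1[[i]], s2[[i]], index, config)
    if (is.na(hit$tx)) next
    mapped <- mapped + 1L
    targets <- if (config$countMode == "all-best") hit$txAll else hit$tx
    for (id in targets) {
      ti <- match(id, index@txIds)
      cnt[ti] <- cnt[ti] + 1L
      if (id == hit$tx) {
        e1 <- hit$start1 + nchar(s1[[i]]) - 1L
        e2 <- hit$start2 + nchar(s2[[i]]) - 1L
        cov[[ti]][hit$start1:e1] <- cov[[ti]][hit$start1:e1] + 1L
        cov[[ti]][hit$start2:e2] <- cov[[ti]][hit$start2:e2] + 1L
      }
    }
  }
  m <- matrix(cnt, ncol = 1, dimnames = list(index@txIds, sample))
  obj <- new("TxCounts", counts = m,
             coverage = setNames(cov, index@txIds),
             txLengths = setNames(as.integer(lens), index@txIds))
  attr(obj@counts, "mappedPairs") <- mapped
  attr(obj@counts, "totalPairs") <- length(s1)
  obj
}

#' Mapping rate of a counted sample
#'
#' @param txCounts A [TxCounts-class] produced by [countAndCoverage()].
#' @return Named numeric vector with `mapped`, `total` and `rate`.
#' @export
mappingRate <- function(txCounts) {
  m <- attr(txCounts@counts, "mappedPairs")
  t <- attr(txCounts@counts, "totalPairs")
  c(mapped = m, total = t, rate = if (t > 0) m / t else 0)
}
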