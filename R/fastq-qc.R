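#' Trimming configuration
#'
#' @param qualityThreshold Phred threshold for the running-sum trimmer
#'   (default 30).
#' @param minRetainedLength Minimum trimmed length for a mate to survive pair
#'   synchronization (default 35 bp).
#' @param phredOffset FASTQ encoding offset (default 33).
#' @return A list of class `TrimConfig`.
#' @export
trimConfig <- function(qualityThreshold = 30, minRetainedLength = 35,
                       phredOffset = 33) {
  checkScalarNumber(qualityThreshold, "qualityThreshold", 0, 60)
  checkScalarNumber(minRetainedLength, "minRetainedLength", 1)
  structure(list(qualityThreshold = qualityThreshold,
                 minRetainedLength = as.integer(minRetainedLength),
                 phredOffset = as.integer(phredOffset)),
            class = "TrimConfig")
}

# Running-sum cut point: area(p) = sum_{i = p..L} (threshold - q_i), scanned
# from the 3' end. Returns the retained length (cut just before the
# area-maximizing position); ties keep the longest read. If no positive area
# exists the read is unchanged.
trimPoint <- function(q, threshold) {
  L <- length(q)
  if (L == 0L) return(0L)
  area <- rev(cumsum(rev(threshold - q)))
  m <- max(area)
  if (m <= 0) return(L)
  max(which(area == m)) - 1L
}

#' Trim one read with the running-sum 3' algorithm
#'
#' Computes, for every candidate cut position `p`, the area
#' `sum(threshold - q_i)` over the removed 3' suffix, and cuts where that
#' area is greatest (BWA's `-q` rule). If no suffix has positive area the
#' read is returned unchanged; a uniformly bad read can be trimmed to length
#' zero. When several positions tie, the 3'-most cut (longest read) is kept.
#'
#' @param bases Character scalar of bases.
#' @param qualities Integer vector of Phred scores (same length as `bases`).
#' @param config A [trimConfig()] list.
#' @return List with `bases` and `qualities` after trimming.
#' @examples
#' trimRead(strrep("A", 4), c(40, 40, 2, 2), trimConfig())
#' @export
trimRead <- function(bases, qualities, config = trimConfig()) {
  if (nchar(bases) != length(qualities)) {
    stop("malformed record: bases and qualities differ in length")
  }
  keep <- trimPoint(qualities, config$qualityThreshold)
  list(bases = substr(bases, 1L, keep), qualities = qualities[seq_len(keep)])
}

# Integer Phred matrix-free accessor for a QualityScaledDNAStringSet.
qualityInts <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}

#' Trim a set of quality-scaled reads
#'
#' Vectorized [trimRead()] over a [Biostrings::QualityScaledDNAStringSet];
#' bases and qualities are cut together.
#'
#' @param reads A `QualityScaledDNAStringSet`.
#' @param config A [trimConfig()] list.
#' @return A trimmed `QualityScaledDNAStringSet` (same order and names).
#' @export
trimReads <- function(reads, config = trimConfig()) {
  if (length(reads) == 0L) return(reads)
  q <- qualityInts(reads)
  keep <- vapply(q, trimPoint, integer(1),
                 threshold = config$qualityThreshold)
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::subseq(Biostrings::DNAStringSet(reads), 1L, keep),
    Biostrings::PhredQuality(
      Biostrings::subseq(Biostrings::BStringSet(
        as(Biostrings::quality(reads), "BStringSet")), 1L, keep)))
}

#' Quality-trim and synchronize read pairs
#'
#' Trims both mates with the running-sum rule and keeps a pair only if both
#' trimmed mates are at least `minRetainedLength` bp; no singleton reads are
#' emitted. Mates must arrive paired (equal count, matching names when
#' named).
#'
#' @param mate1,mate2 `QualityScaledDNAStringSet` objects of equal length.
#' @param config A [trimConfig()] list.
#' @return List with trimmed, synchronized `mate1` and `mate2`, and `report`,
#'   a one-row data.frame with `input_pairs`, `retained_pairs`,
#'   `bases_before`, `bases_after`.
#' @export
synchronizePairs <- function(mate1, mate2, config = trimConfig()) {
  if (length(mate1) != length(mate2)) {
    stop("pairing error: mate files differ in record count")
  }
  if (!is.null(names(mate1)) && !is.null(names(mate2))) {
    bad <- which(names(mate1) != names(mate2))
    if (length(bad)) {
      stop(sprintf("pairing error at record '%s'", names(mate1)[bad[1L]]))
    }
  }
  basesBefore <- sum(Biostrings::width(mate1)) +
    sum(Biostrings::width(mate2))
  t1 <- trimReads(mate1, config)
  t2 <- trimReads(mate2, config)
  ok <- Biostrings::width(t1) >= config$minRetainedLength &
    Biostrings::width(t2) >= config$minRetainedLength
  t1 <- t1[ok]
  t2 <- t2[ok]
  report <- data.frame(
    input_pairs = length(mate1),
    retained_pairs = sum(ok),
    bases_before = basesBefore,
    bases_after = sum(Biostrings::width(t1)) + sum(Biostrings::width(t2)))
  list(mate1 = t1, mate2 = t2, report = report)
}
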