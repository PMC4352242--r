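#' Clustering configuration
#'
#' @param identityThreshold Global identity required to join a cluster,
#'   inclusive (default 0.90).
#' @param denominator Identity denominator: `"shorter-sequence"` (the
#'   CD-HIT convention, default) or `"alignment-length"`.
#' @return A list of class `ClusterConfig`.
#' @export
clusterConfig <- function(identityThreshold = 0.90,
                          denominator = c("shorter-sequence",
                                          "alignment-length")) {
  if (!is.numeric(identityThreshold) || identityThreshold <= 0 ||
      identityThreshold > 1) {
    stop("identityThreshold must be in (0, 1]")
  }
  structure(list(identityThreshold = identityThreshold,
                 denominator = match.arg(denominator)),
            class = "ClusterConfig")
}

#' Global identity between two sequences
#'
#' Semi-global alignment: the shorter sequence is aligned end to end while
#' terminal gaps on the longer sequence are free. Identity is matches
#' divided by the shorter sequence's length (default) or by the alignment
#' length.
#'
#' @param a,b Sequences (character or `XString`); non-empty.
#' @param config A [clusterConfig()] list.
#' @return Identity in `[0, 1]`.
#' @examples
#' globalIdentity("ACGT", "ACGA")        # 0.75
#' @export
globalIdentity <- function(a, b, config = clusterConfig()) {
  a <- as.character(a)
  b <- as.character(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  if (nchar(a) <= nchar(b)) {
    shorter <- a
    longer <- b
  } else {
    shorter <- b
    longer <- a
  }
  letters <- c("A", "C", "G", "T", "N")
  subMat <- matrix(-1, 5, 5, dimnames = list(letters, letters))
  diag(subMat) <- 1
  subMat["N", ] <- -1
  subMat[, "N"] <- -1
  aln <- Biostrings::pairwiseAlignment(
    shorter, longer, type = "global-local",
    substitutionMatrix = subMat, gapOpening = 2, gapExtension = 1)
  denom <- switch(config$denominator,
                  "shorter-sequence" = nchar(shorter),
                  "alignment-length" = Biostrings::nchar(aln))
  Biostrings::nmatch(aln) / denom
}

#' Greedy incremental clustering of transcripts by global identity
#'
#' Reproduces the CD-HIT-EST procedure without its word-filter heuristics:
#' sequences are processed in order of decreasing length (ties by ascending
#' id); each is compared to the representatives of all existing clusters
#' and joins the cluster of highest identity when that identity reaches the
#' threshold, otherwise it founds a new cluster. Identity ties between
#' candidate clusters go to the earliest-founded cluster. The
#' representative of a cluster is its longest member (the founder).
#'
#' @param sequences Named `DNAStringSet` or character vector; ids must be
#'   unique.
#' @param config A [clusterConfig()] list.
#' @return Data.frame with columns `cluster` (integer, in founding order),
#'   `id`, `representative` (logical), `identity` (to the representative;
#'   1 for representatives).
#' @examples
#' seqs <- c(s1 = "ACGTACGTACGT", s2 = "ACGTACGTACGT", s3 = "TTTTGGGGCCCC")
#' clusterTranscripts(seqs, clusterConfig(0.9))
#' @export
clusterTranscripts <- function(sequences, config = clusterConfig()) {
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequences must carry unique ids")
  }
  seqs <- as.character(sequences)
  ord <- order(-nchar(seqs), ids)
  repIdx <- integer(0)     # index (into seqs) of each cluster representative
  member <- integer(length(seqs))   # cluster id per sequence
  identity <- numeric(length(seqs))
  for (i in ord) {
    bestC <- 0L
    bestId <- -Inf
    for (c in seq_along(repIdx)) {
      idn <- globalIdentity(seqs[[i]], seqs[[repIdx[c]]], config)
      if (idn > bestId) {  # strict: ties keep the earliest-founded cluster
        bestId <- idn
        bestC <- c
      }
    }
    if (bestC > 0L && bestId >= config$identityThreshold) {
      member[i] <- bestC
      identity[i] <- bestId
    } else {
      repIdx <- c(repIdx, i)
      member[i] <- length(repIdx)
      identity[i] <- 1
    }
  }
  out <- data.frame(cluster = member[ord], id = ids[ord],
                    representative = ord %in% repIdx,
                    identity = identity[ord])
  out <- out[order(out$cluster, -out$representative, out$id), ]
  rownames(out) <- NULL
  out
}

#' Representative sequences of a clustering
#'
#' @param sequences The clustered sequences.
#' @param clusters Output of [clusterTranscripts()].
#' @return The subset of `sequences` that are cluster representatives, in
#'   cluster order.
#' @export
clusterRepresentatives <- function(sequences, clusters) {
  reps <- clusters$id[clusters$representative]
  sequences[reps]
}
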