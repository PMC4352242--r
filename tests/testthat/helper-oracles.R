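# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results by brute force (exhaustive search, naive
# dynamic programming) so they stay independent of the package's code paths.

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force running-sum trimmer: evaluate the removed-suffix area at every
# kept length and take the maximum (ties -> longest read).
oracleTrimLength <- function(q, threshold) {
  L <- length(q)
  best <- L
  bestArea <- 0
  for (keep in seq(L, 0)) {   # longest first so ties keep the longest
    removed <- if (keep < L) q[(keep + 1):L] else numeric(0)
    area <- sum(threshold - removed)
    if (area > bestArea) {
      bestArea <- area
      best <- keep
    }
  }
  best
}

# Naive affine-gap Smith-Waterman score (three-matrix recursion, loops).
oracleLocalScore <- function(a, b, match = 2, mismatch = -3,
                             gapOpen = 5, gapExt = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in a (consuming b)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in b (consuming a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      E[i, j] <- max(H[i, j - 1] - gapOpen - gapExt, E[i, j - 1] - gapExt)
      F[i, j] <- max(H[i - 1, j] - gapOpen - gapExt, F[i - 1, j] - gapExt)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Exhaustive N50: try every observed length as the candidate L.
oracleN50 <- function(lengths) {
  if (length(lengths) == 0) return(0)
  half <- sum(lengths) / 2
  cands <- sort(unique(lengths), decreasing = TRUE)
  for (L in cands) {
    if (sum(lengths[lengths >= L]) >= half) return(L)
  }
  min(lengths)
}

# Heuristic-free re-execution of the greedy incremental clustering
# procedure: sort by decreasing length (ties ascending id), compare each
# sequence to every existing representative, join the most similar cluster
# at or above the threshold (ties -> earliest founded), else found a new
# cluster. Returns a named integer vector id -> cluster.
oracleClustering <- function(seqs, threshold,
                             identityFun = function(a, b)
                               globalIdentity(a, b)) {
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  reps <- character(0)
  assignment <- integer(length(seqs))
  names(assignment) <- ids
  for (i in ord) {
    idns <- vapply(reps, function(r) identityFun(seqs[[i]], seqs[[r]]),
                   numeric(1))
    pick <- 0
    if (length(idns)) {
      bestVal <- max(idns)
      if (bestVal >= threshold) pick <- which(idns == bestVal)[1]
    }
    if (pick > 0) {
      assignment[ids[i]] <- pick
    } else {
      reps <- c(reps, ids[i])
      assignment[ids[i]] <- length(reps)
    }
  }
  assignment
}

# Point-mutate a sequence at a fixed per-site rate (uniform other base).
mutateSeq <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Sample a coding-like ORF: ATG + codons drawn from a skewed codon usage
# (stop codons excluded) + TAA. Length in codons excludes the stop.
CODON_TABLE <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}
codingOrf <- function(nCodons, bias = 8) {
  w <- rep(1, length(CODON_TABLE))
  w[seq(1, length(CODON_TABLE), by = 3)] <- bias  # skewed codon usage
  body <- sample(CODON_TABLE, nCodons - 1, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

# Build a QualityScaledDNAStringSet from parallel base/quality vectors.
mkReads <- function(seqs, quals, ids = sprintf("r%03d", seq_along(seqs))) {
  q <- vapply(quals, function(v) intToUtf8(v + 33L), character(1))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(q))
}
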