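#' ORF-calling configuration
#'
#' @param trainingSetSize Number of longest candidate ORFs used to train the
#'   coding model (default 500).
#' @param minOrfLength Minimum ORF length in codons, excluding the stop
#'   (default 100).
#' @param requireComplete Only report complete (ATG-to-stop) ORFs (default
#'   `TRUE`); when `FALSE`, 5'- and 3'-partial ORFs are also extracted and
#'   scored identically.
#' @param pseudocount Pseudocount added to every transition cell during
#'   training (default 1.0).
#' @return A list of class `OrfConfig`.
#' @export
orfConfig <- function(trainingSetSize = 500, minOrfLength = 100,
                      requireComplete = TRUE, pseudocount = 1.0) {
  checkScalarNumber(trainingSetSize, "trainingSetSize", 1)
  checkScalarNumber(minOrfLength, "minOrfLength", 2)
  structure(list(trainingSetSize = as.integer(trainingSetSize),
                 minOrfLength = as.integer(minOrfLength),
                 requireComplete = isTRUE(requireComplete),
                 pseudocount = pseudocount),
            class = "OrfConfig")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Extract ORFs from one oriented strand; returns codon-index spans.
orfSpansOneStrand <- function(ss, frame, minCodons, requireComplete) {
  L <- nchar(ss)
  nCod <- (L - frame) %/% 3
  if (nCod < 2L) return(NULL)
  p <- frame + seq(1L, by = 3L, length.out = nCod)
  codons <- substring(ss, p, p + 2L)
  stops <- which(codons %in% STOP_CODONS)
  starts <- which(codons == "ATG")
  spans <- list()
  prev <- 0L
  for (s in stops) {
    a <- starts[starts > prev & starts < s]
    if (length(a)) {
      a <- a[1L]
      if (s - a >= minCodons) {
        spans[[length(spans) + 1L]] <-
          c(from = a, to = s, complete = 1L)
      }
    }
    if (!requireComplete && s - 1L >= minCodons && prev == 0L) {
      # 5'-partial: frame start to first stop (no ATG required)
      spans[[length(spans) + 1L]] <- c(from = 1L, to = s, complete = 0L)
    }
    prev <- s
  }
  if (!requireComplete) {
    a <- starts[starts > prev]
    if (length(a) && nCod - a[1L] + 1L >= minCodons) {
      # 3'-partial: ATG after the last stop, running off the end
      spans[[length(spans) + 1L]] <- c(from = a[1L], to = nCod,
                                       complete = 0L)
    }
  }
  spans
}

#' Extract candidate open reading frames in all six frames
#'
#' Complete ORFs run from the first ATG after the preceding in-frame stop
#' to that stop, in each of the three forward and three reverse-complement
#' frames. Coordinates are reported on the forward strand (1-based,
#' inclusive) and span a multiple of three bases including the stop codon.
#'
#' @param sequence Transcript sequence (character or `DNAString`) over
#'   `{A,C,G,T,N}`.
#' @param config An [orfConfig()] list.
#' @param txId Transcript id recorded in the output.
#' @return Data.frame with columns `transcript`, `start`, `end`, `strand`,
#'   `frame`, `codons` (peptide length), `complete`, `seq` (oriented
#'   nucleotide sequence including the stop), `peptide`. Zero rows when no
#'   ORF qualifies.
#' @export
extractOrfs <- function(sequence, config = orfConfig(), txId = "tx") {
  seqc <- toupper(as.character(sequence))
  L <- nchar(seqc)
  rows <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") seqc else reverseComplement1(seqc)
    for (f in 0:2) {
      spans <- orfSpansOneStrand(ss, f, config$minOrfLength,
                                 config$requireComplete)
      for (sp in spans) {
        sStart <- f + 3L * (sp[["from"]] - 1L) + 1L
        sEnd <- f + 3L * sp[["to"]]
        orfSeq <- substr(ss, sStart, sEnd)
        if (strand == "+") {
          start <- sStart
          end <- sEnd
        } else {
          start <- L - sEnd + 1L
          end <- L - sStart + 1L
        }
        nCodons <- (sEnd - sStart + 1L) %/% 3L
        hasStop <- substr(orfSeq, nchar(orfSeq) - 2L, nchar(orfSeq)) %in%
          STOP_CODONS
        pepSeq <- if (hasStop)
          substr(orfSeq, 1L, nchar(orfSeq) - 3L) else orfSeq
        pep <- if (nchar(pepSeq) >= 3L)
          as.character(Biostrings::translate(
            Biostrings::DNAString(pepSeq), no.init.codon = TRUE))
        else ""
        rows[[length(rows) + 1L]] <- data.frame(
          transcript = txId, start = start, end = end, strand = strand,
          frame = f, codons = nCodons - as.integer(hasStop),
          complete = sp[["complete"]] == 1L, seq = orfSeq, peptide = pep)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), codons = integer(0),
                      complete = logical(0), seq = character(0),
                      peptide = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand, out$frame), , drop = FALSE]
}

# Phase-specific hexamer transition counts of a set of sequences.
# Returns list(trans = 1024 x 4 x 3 counts, init = length-1024 counts).
hexamerCounts <- function(seqs) {
  trans <- array(0, dim = c(1024L, 4L, 3L))
  init <- numeric(1024L)
  for (s in seqs) {
    b <- baseCodes(s)
    L <- length(b)
    if (L < 6L) next
    i <- seq_len(L - 5L)
    ctx <- b[i] * 256L + b[i + 1L] * 64L + b[i + 2L] * 16L +
      b[i + 3L] * 4L + b[i + 4L]
    nxt <- b[i + 5L]
    phase <- (i + 4L) %% 3L    # 0-based codon phase of the predicted base
    ok <- !is.na(ctx) & !is.na(nxt)
    lin <- ctx[ok] + 1024L * nxt[ok] + 4096L * phase[ok] + 1L
    trans <- trans + array(tabulate(lin, nbins = 1024L * 4L * 3L),
                           dim = c(1024L, 4L, 3L))
    c0 <- ctx[1L]
    if (!is.na(c0)) init[c0 + 1L] <- init[c0 + 1L] + 1
  }
  list(trans = trans, init = init)
}

normalizeLog <- function(counts, pc) {
  counts <- counts + pc
  for (p in 1:3) {
    counts[, , p] <- counts[, , p] / rowSums(counts[, , p])
  }
  log(counts)
}

#' Train coding and noncoding hexamer Markov models
#'
#' The coding model is estimated from the `trainingSetSize` longest
#' candidate ORFs (all of them, with a warning, when fewer are available).
#' The noncoding model is estimated from per-sequence base-shuffled copies
#' of the same training sequences, which preserves composition while
#' destroying codon structure. Both chains are order-5 with
#' codon-phase-specific transition tables; pseudocounts are applied to
#' every context.
#'
#' @param candidates Data.frame from [extractOrfs()] (possibly concatenated
#'   over transcripts), or a character vector of ORF nucleotide sequences.
#' @param config An [orfConfig()] list.
#' @param seed Integer seed for the shuffling.
#' @return A [HexamerModel-class].
#' @export
trainModels <- function(candidates, config = orfConfig(), seed = 1) {
  seqs <- if (is.data.frame(candidates)) candidates$seq else candidates
  if (length(seqs) == 0L) stop("no candidate ORFs to train on")
  seqs <- seqs[order(-nchar(seqs))]
  if (length(seqs) < config$trainingSetSize) {
    warning(sprintf("only %d candidate ORFs available (requested %d)",
                    length(seqs), config$trainingSetSize))
  } else {
    seqs <- seqs[seq_len(config$trainingSetSize)]
  }
  shuffled <- withSeed(seed, {
    vapply(seqs, function(s) {
      paste(sample(strsplit(s, "")[[1L]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
  cod <- hexamerCounts(seqs)
  non <- hexamerCounts(shuffled)
  pc <- config$pseudocount
  new("HexamerModel",
      codingTrans = normalizeLog(cod$trans, pc),
      noncodingTrans = normalizeLog(non$trans, pc),
      codingInit = log((cod$init + pc) / sum(cod$init + pc)),
      noncodingInit = log((non$init + pc) / sum(non$init + pc)),
      pseudocount = pc)
}

#' Score a sequence's coding potential (log-likelihood ratio)
#'
#' Chain-rule log-likelihood ratio `log P(seq | coding) - log P(seq |
#' noncoding)` under the order-5 phase-aware models, including the initial
#' 5-mer term. The sequence is scored as a reading starting at codon phase
#' 0 of its first base. Positions whose 6-base window contains a non-ACGT
#' letter are skipped.
#'
#' @param sequence Character or `DNAString`, length >= 6.
#' @param model A [HexamerModel-class].
#' @return LLR in nats.
#' @export
scoreOrf <- function(sequence, model) {
  s <- toupper(as.character(sequence))
  b <- baseCodes(s)
  L <- length(b)
  if (L < 6L) stop("sequence must be at least 6 bases to score")
  i <- seq_len(L - 5L)
  ctx <- b[i] * 256L + b[i + 1L] * 64L + b[i + 2L] * 16L +
    b[i + 3L] * 4L + b[i + 4L]
  nxt <- b[i + 5L]
  phase <- (i + 4L) %% 3L
  ok <- !is.na(ctx) & !is.na(nxt)
  idx <- cbind(ctx[ok] + 1L, nxt[ok] + 1L, phase[ok] + 1L)
  llr <- sum(model@codingTrans[idx]) - sum(model@noncodingTrans[idx])
  c0 <- ctx[1L]
  if (!is.na(c0)) {
    llr <- llr + model@codingInit[c0 + 1L] - model@noncodingInit[c0 + 1L]
  }
  llr
}

# LLRs of the six readings of an oriented ORF sequence: the proper frame
# first, then forward offsets 1 and 2, then the reverse complement at
# offsets 0, 1, 2. Each reading is trimmed to whole codons.
sixFrameScores <- function(orfSeq, model) {
  rc <- reverseComplement1(orfSeq)
  readings <- character(6)
  k <- 0L
  for (s in list(orfSeq, rc)) {
    for (off in 0:2) {
      k <- k + 1L
      L <- nchar(s) - off
      readings[k] <- substr(s, off + 1L, off + 3L * (L %/% 3L))
    }
  }
  vapply(readings, function(r) {
    if (nchar(r) < 6L) -Inf else scoreOrf(r, model)
  }, numeric(1), USE.NAMES = FALSE)
}

# Eclipse rule: processing ORFs by decreasing span length then decreasing
# LLR, an ORF is dropped when fully contained within the span of an
# already-kept ORF in a different reading frame (different strand/frame
# combination). Input needs columns start, end, strand, frame, llr; returns
# a logical keep vector aligned to that processing order.
dropEclipsed <- function(orfs) {
  orfs <- orfs[order(-(orfs$end - orfs$start), -orfs$llr), , drop = FALSE]
  keep <- logical(nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    eclipsed <- FALSE
    for (j in which(keep)) {
      sameFrame <- orfs$strand[j] == orfs$strand[i] &&
        orfs$frame[j] == orfs$frame[i]
      if (!sameFrame && orfs$start[j] <= orfs$start[i] &&
          orfs$end[j] >= orfs$end[i]) {
        eclipsed <- TRUE
        break
      }
    }
    keep[i] <- !eclipsed
  }
  keep
}

#' Call coding regions on a transcript
#'
#' An ORF is reported iff (i) its log-likelihood ratio is positive, (ii)
#' the LLR in its proper frame is the strict maximum over the same region
#' read in each of the other five frames, and (iii) it is not fully
#' contained within the span of a longer reported ORF in a different
#' reading frame (the eclipse rule; containment is resolved processing
#' ORFs by decreasing length, then decreasing LLR).
#'
#' @param sequence Transcript sequence.
#' @param model A trained [HexamerModel-class].
#' @param config An [orfConfig()] list.
#' @param txId Transcript id for the output.
#' @return Data.frame of reported ORFs: `transcript`, `start`, `end`,
#'   `strand`, `frame`, `codons`, `peptide`, `llr`.
#' @export
callCoding <- function(sequence, model, config = orfConfig(), txId = "tx") {
  cand <- extractOrfs(sequence, config, txId)
  empty <- data.frame(transcript = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), codons = integer(0),
                      peptide = character(0), llr = numeric(0))
  if (nrow(cand) == 0L) return(empty)
  scores <- lapply(cand$seq, sixFrameScores, model = model)
  cand$llr <- vapply(scores, `[`, numeric(1), 1L)
  properMax <- vapply(scores, function(s) s[1L] > max(s[-1L]), logical(1))
  cand <- cand[cand$llr > 0 & properMax, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  keep <- dropEclipsed(cand)
  cand <- cand[order(-(cand$end - cand$start), -cand$llr), , drop = FALSE]
  out <- cand[keep, c("transcript", "start", "end", "strand", "frame",
                      "codons", "peptide")]
  out$llr <- cand$llr[keep]
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a transcript set: extract, train, and call coding regions
#'
#' Convenience wrapper over [extractOrfs()], [trainModels()] and
#' [callCoding()]: candidate ORFs are pooled over all transcripts, models
#' are trained on the longest candidates, and every transcript is then
#' scored.
#'
#' @param transcripts Named `DNAStringSet`.
#' @param config An [orfConfig()] list.
#' @param seed Seed for the noncoding shuffle.
#' @return List with `calls` (data.frame over all transcripts), `model`
#'   (the [HexamerModel-class]) and `peptides` (named
#'   [Biostrings::AAStringSet], names `<transcript>|<start>-<end>`).
#' @export
annotateCoding <- function(transcripts, config = orfConfig(), seed = 1) {
  cand <- do.call(rbind, lapply(names(transcripts), function(id) {
    extractOrfs(transcripts[[id]], config, id)
  }))
  if (is.null(cand) || nrow(cand) == 0L) {
    stop("no candidate ORFs found in the transcript set")
  }
  model <- trainModels(cand, config, seed)
  calls <- do.call(rbind, lapply(names(transcripts), function(id) {
    callCoding(transcripts[[id]], model, config, id)
  }))
  peptides <- Biostrings::AAStringSet(setNames(
    calls$peptide,
    sprintf("%s|%d-%d", calls$transcript, calls$start, calls$end)))
  list(calls = calls, model = model, peptides = peptides)
}
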