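#' Build a simulation configuration
#'
#' Defaults describe the emulated study design: a multi-tissue,
#' strand-specific paired-end RNA-seq experiment with 76-bp reads,
#' approximately 200-bp inserts, 3'-decaying base qualities, and two species
#' diverged under a Jukes-Cantor substitution process whose expected
#' ortholog identity is about 91.5%.
#'
#' @param nGenes Number of species-A genes.
#' @param lengthRange Length-2 numeric, inclusive transcript length range in
#'   bp.
#' @param nTissues Number of tissues.
#' @param tissueNames Tissue labels; defaults to brain/liver/ovary/testis for
#'   four tissues.
#' @param tissueSpecificFraction Fraction of genes restricted to each single
#'   tissue (so `nTissues * tissueSpecificFraction` of genes are
#'   tissue-specific in total).
#' @param speciesAOnlyFraction Fraction of genes with no species-B ortholog.
#' @param jcDistance Jukes-Cantor divergence (substitutions/site) between
#'   ortholog pairs.
#' @param readLength Read length (bp).
#' @param insertMean,insertSd Insert size model (bp); inserts are normal,
#'   truncated to `[readLength, transcript length]`.
#' @param baseErrorRate Per-base sequencing error probability.
#' @param qualityStart,qualityFloor Linear Phred decay from the 5' end to the
#'   3' end of each read.
#' @param coverageTarget Expected fold coverage of an expressed transcript of
#'   average expression.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 50, seed = 7)
#' cfg
#' @export
simConfig <- function(nGenes = 200,
                      lengthRange = c(300, 3000),
                      nTissues = 4,
                      tissueNames = NULL,
                      tissueSpecificFraction = 0.1,
                      speciesAOnlyFraction = 0.1,
                      jcDistance = 0.09,
                      readLength = 76,
                      insertMean = 200,
                      insertSd = 20,
                      baseErrorRate = 0.005,
                      qualityStart = 40,
                      qualityFloor = 12,
                      coverageTarget = 30,
                      seed = 1) {
  if (is.null(tissueNames)) {
    tissueNames <- if (nTissues == 4) c("brain", "liver", "ovary", "testis")
                   else paste0("tissue", seq_len(nTissues))
  }
  new("SimConfig",
      nGenes = as.integer(nGenes),
      lengthRange = as.integer(lengthRange),
      nTissues = as.integer(nTissues),
      tissueNames = tissueNames,
      tissueSpecificFraction = as.numeric(tissueSpecificFraction),
      speciesAOnlyFraction = as.numeric(speciesAOnlyFraction),
      jcDistance = as.numeric(jcDistance),
      readLength = as.integer(readLength),
      insertMean = as.numeric(insertMean),
      insertSd = as.numeric(insertSd),
      baseErrorRate = as.numeric(baseErrorRate),
      qualityStart = as.integer(qualityStart),
      qualityFloor = as.integer(qualityFloor),
      coverageTarget = as.numeric(coverageTarget),
      seed = as.integer(seed))
}

#' Generate a ground-truthed species-A transcriptome
#'
#' Draws `nGenes` transcripts with lengths uniform in `lengthRange` and
#' i.i.d. bases, assigns each gene either to a single tissue
#' (tissue-specific) or to all tissues, draws log-normal expression levels,
#' and marks a fraction of genes as species-A-only (no ortholog). Output is
#' deterministic for a fixed seed.
#'
#' @param config A [SimConfig-class] object.
#' @return A list with elements `transcripts` (a named
#'   [Biostrings::DNAStringSet]) and `truth` (a
#'   [TranscriptomeTruth-class]).
#' @examples
#' sim <- generateTranscriptome(simConfig(nGenes = 20, seed = 1))
#' sim$truth
#' @export
generateTranscriptome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  n <- config@nGenes
  tissues <- config@tissueNames
  if (n == 0L) {
    truth <- new("TranscriptomeTruth",
                 orthologMap = setNames(character(0), character(0)),
                 tissueAssignment = setNames(list(), character(0)),
                 expressionLevel = matrix(numeric(0), nrow = 0,
                                          ncol = length(tissues),
                                          dimnames = list(NULL, tissues)),
                 aOnlySet = character(0))
    return(list(transcripts = Biostrings::DNAStringSet(), truth = truth))
  }
  ids <- sprintf("txA_%05d", seq_len(n))
  withSeed(config@seed, {
    span <- config@lengthRange[2L] - config@lengthRange[1L] + 1L
    lens <- config@lengthRange[1L] + sample.int(span, n, replace = TRUE) - 1L
    allBases <- sample(DNA_BASES, sum(lens), replace = TRUE)
    ends <- cumsum(lens)
    seqs <- substring(paste(allBases, collapse = ""),
                      ends - lens + 1L, ends)

    # Tissue structure: the first blocks of a random permutation are
    # tissue-specific; the remainder is expressed everywhere.
    perm <- sample(n)
    nSpec <- floor(n * config@tissueSpecificFraction)
    assign <- rep(list(tissues), n)
    ptr <- 0L
    for (t in tissues) {
      if (nSpec > 0L) {
        assign[perm[(ptr + 1L):(ptr + nSpec)]] <- list(t)
        ptr <- ptr + nSpec
      }
    }
    names(assign) <- ids
    level <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
    expr <- matrix(0, nrow = n, ncol = length(tissues),
                   dimnames = list(ids, tissues))
    for (i in seq_len(n)) expr[i, assign[[i]]] <- level[i]

    nAOnly <- round(n * config@speciesAOnlyFraction)
    aOnly <- sort(sample(ids, nAOnly))
    shared <- setdiff(ids, aOnly)
    omap <- setNames(sprintf("txB_%05d", match(shared, ids)), shared)
  })
  tx <- Biostrings::DNAStringSet(setNames(seqs, ids))
  truth <- new("TranscriptomeTruth",
               orthologMap = omap,
               tissueAssignment = assign,
               expressionLevel = expr,
               aOnlySet = aOnly)
  list(transcripts = tx, truth = truth)
}

#' Evolve species-B orthologs under a Jukes-Cantor substitution process
#'
#' Mutates each retained transcript site-independently: a site changes with
#' probability `(3/4) * (1 - exp(-4 d / 3))` and, when it changes, becomes
#' one of the three other bases uniformly. No indels are introduced, so the
#' expected observed identity is `1/4 + 3/4 * exp(-4 d / 3)`.
#'
#' @param transcripts Named [Biostrings::DNAStringSet] of species-A
#'   transcripts.
#' @param jcDistance Evolutionary distance in substitutions/site (>= 0).
#' @param seed Integer seed.
#' @param exclude Character vector of transcript ids to skip (species-A-only
#'   genes).
#' @param idMap Optional named character vector renaming output sequences
#'   (A id -> B id), e.g. `orthologMap(truth)`.
#' @return A named `DNAStringSet` of species-B transcripts.
#' @examples
#' sim <- generateTranscriptome(simConfig(nGenes = 5, seed = 1))
#' b <- evolveOrthologs(sim$transcripts, 0.09, seed = 2,
#'                      exclude = aOnlySet(sim$truth),
#'                      idMap = orthologMap(sim$truth))
#' @export
evolveOrthologs <- function(transcripts, jcDistance, seed,
                            exclude = character(0), idMap = NULL) {
  if (!is.numeric(jcDistance) || length(jcDistance) != 1L ||
      is.na(jcDistance) || jcDistance < 0) {
    stop("'jcDistance' must be a non-negative number")
  }
  keep <- setdiff(names(transcripts), exclude)
  txs <- as.character(transcripts[keep])
  p <- 0.75 * (1 - exp(-4 * jcDistance / 3))
  withSeed(seed, {
    out <- vapply(txs, function(s) {
      codes <- baseCodes(s)
      hit <- which(stats::runif(length(codes)) < p)
      if (length(hit)) {
        codes[hit] <- (codes[hit] +
                       sample.int(3L, length(hit), replace = TRUE)) %% 4L
      }
      codesToBases(codes)
    }, character(1), USE.NAMES = FALSE)
  })
  names(out) <- if (!is.null(idMap)) unname(idMap[keep]) else keep
  Biostrings::DNAStringSet(out)
}

#' Simulate strand-specific paired-end reads for one tissue
#'
#' Fragments are drawn per gene with multinomial weights proportional to
#' `expression x length`; insert lengths are normal
#' (`insertMean`, `insertSd`) truncated to `[readLength, transcript
#' length]`. Mate 1 is taken from the sense strand and mate 2 is the reverse
#' complement of the fragment's 3' end, emulating a dUTP strand-specific
#' protocol. Base qualities decay linearly toward the 3' end (plus
#' per-read jitter) and sequencing errors flip bases uniformly at
#' `baseErrorRate`. Genes not expressed in the tissue yield zero reads;
#' expressed transcripts shorter than the read length are skipped with a
#' warning.
#'
#' @param transcripts Named [Biostrings::DNAStringSet].
#' @param truth A [TranscriptomeTruth-class]; supplies per-tissue expression
#'   unless `expression` is given.
#' @param tissue Tissue label (must be a configured tissue).
#' @param config A [SimConfig-class].
#' @param seed Integer seed; defaults to `config@seed` offset by the tissue
#'   index so tissues get distinct but reproducible streams.
#' @param expression Optional named numeric vector of expression levels per
#'   transcript id, overriding the truth table (used e.g. to sequence
#'   species-B transcripts).
#' @return A list with `mate1` and `mate2`
#'   ([Biostrings::QualityScaledDNAStringSet]); read names are
#'   `<gene>:<tissue>:<serial>`.
#' @export
simulateReads <- function(transcripts, truth, tissue, config, seed = NULL,
                          expression = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (is.null(expression)) {
    ex <- expressionLevel(truth)
    if (!tissue %in% colnames(ex)) stop(sprintf("unknown tissue '%s'", tissue))
    expression <- setNames(ex[, tissue], rownames(ex))
  }
  if (is.null(seed)) {
    seed <- config@seed + match(tissue, config@tissueNames, nomatch = 0L)
  }
  rl <- config@readLength
  ids <- names(transcripts)
  lens <- setNames(Biostrings::width(transcripts), ids)
  expr <- expression[ids]
  expr[is.na(expr)] <- 0
  tooShort <- ids[expr > 0 & lens < rl]
  if (length(tooShort)) {
    warning(sprintf("skipping %d transcript(s) shorter than the read length",
                    length(tooShort)))
    expr[tooShort] <- 0
  }
  use <- ids[expr > 0]
  emptyReads <- function() {
    q <- Biostrings::PhredQuality(character(0))
    r <- Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(), q)
    list(mate1 = r, mate2 = r)
  }
  if (length(use) == 0L) return(emptyReads())

  w <- expr[use] * lens[use]
  nPairs <- round(config@coverageTarget *
                  sum(lens[use] * expr[use] / mean(expr[use])) / (2 * rl))
  if (nPairs == 0L) return(emptyReads())

  # qualities stay at qualityStart over the 5' portion and decay linearly
  # to qualityFloor across the final 40% of the read
  flatLen <- floor(0.6 * rl)
  qProfile <- c(rep(config@qualityStart, flatLen),
                round(seq(config@qualityStart, config@qualityFloor,
                          length.out = rl - flatLen)))
  withSeed(seed, {
    perGene <- as.vector(stats::rmultinom(1, nPairs, w))
    s1 <- s2 <- n1 <- character(0)
    q1 <- q2 <- list()
    for (gi in seq_along(use)) {
      m <- perGene[gi]
      if (m == 0L) next
      id <- use[gi]
      L <- lens[[id]]
      seqc <- as.character(transcripts[[id]])
      ins <- pmin(pmax(round(stats::rnorm(m, config@insertMean,
                                          config@insertSd)), rl), L)
      start <- 1L + floor(stats::runif(m) * (L - ins + 1))
      m1 <- substring(seqc, start, start + rl - 1L)
      frag3 <- substring(seqc, start + ins - rl, start + ins - 1L)
      m2 <- vapply(frag3, reverseComplement1, character(1),
                   USE.NAMES = FALSE)
      s1 <- c(s1, m1)
      s2 <- c(s2, m2)
      n1 <- c(n1, sprintf("%s:%s:%06d", id, tissue,
                          seq.int(length(s1) - m + 1L, length(s1))))
    }
    nReads <- length(s1)
    # qualities: shared decay profile + per-read jitter
    jit1 <- stats::rnorm(nReads, 0, 2)
    jit2 <- stats::rnorm(nReads, 0, 2)
    mkq <- function(jit) {
      vapply(jit, function(j) {
        q <- pmin(pmax(round(qProfile + j), 2L), 41L)
        intToUtf8(q + 33L)
      }, character(1))
    }
    qs1 <- mkq(jit1)
    qs2 <- mkq(jit2)
    # sequencing errors
    addErrors <- function(s) {
      nerr <- stats::rbinom(length(s), rl, config@baseErrorRate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(rl, nerr[i])
        ch <- strsplit(s[i], "")[[1]]
        ch[pos] <- vapply(ch[pos],
                          function(b) sample(setdiff(DNA_BASES, b), 1L),
                          character(1))
        s[i] <- paste(ch, collapse = "")
      }
      s
    }
    s1 <- addErrors(s1)
    s2 <- addErrors(s2)
  })
  mk <- function(s, q, nm) {
    x <- Biostrings::DNAStringSet(setNames(s, nm))
    Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(q))
  }
  list(mate1 = mk(s1, qs1, n1), mate2 = mk(s2, qs2, n1))
}

#' Write truth tables as TSV files
#'
#' Writes `ortholog_map.tsv`, `tissue_assignment.tsv`,
#' `expression_level.tsv` and `a_only.tsv` with documented headers.
#'
#' @param truth A [TranscriptomeTruth-class].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeTruthTables <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("ortholog_map.tsv", "tissue_assignment.tsv",
                            "expression_level.tsv", "a_only.tsv"))
  utils::write.table(
    data.frame(gene_a = names(orthologMap(truth)),
               gene_b = unname(orthologMap(truth))),
    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  ta <- tissueAssignment(truth)
  utils::write.table(
    data.frame(gene = names(ta),
               tissues = vapply(ta, paste, character(1), collapse = ",")),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  ex <- expressionLevel(truth)
  utils::write.table(
    data.frame(gene = rownames(ex), ex, check.names = FALSE),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = aOnlySet(truth)),
                     paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write paired FASTQ files (Phred+33)
#'
#' @param reads A list with `mate1`/`mate2` as returned by
#'   [simulateReads()].
#' @param file1,file2 Output FASTQ paths.
#' @return Invisibly, the two paths.
#' @export
writePairedFastq <- function(reads, file1, file2) {
  Biostrings::writeQualityScaledXStringSet(reads$mate1, file1)
  Biostrings::writeQualityScaledXStringSet(reads$mate2, file2)
  invisible(c(file1, file2))
}
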