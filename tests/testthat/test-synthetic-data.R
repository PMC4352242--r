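test_that("transcriptome generation is deterministic, sized and bounded", {
  cfg <- simConfig(nGenes = 200, lengthRange = c(300, 3000), seed = 1)
  sim1 <- generateTranscriptome(cfg)
  sim2 <- generateTranscriptome(cfg)
  expect_identical(as.character(sim1$transcripts),
                   as.character(sim2$transcripts))
  expect_identical(orthologMap(sim1$truth), orthologMap(sim2$truth))
  expect_length(sim1$transcripts, 200)
  w <- Biostrings::width(sim1$transcripts)
  expect_true(all(w >= 300 & w <= 3000))
  # every gene expressed somewhere; A-only and ortholog domains disjoint
  expect_true(all(rowSums(expressionLevel(sim1$truth) > 0) >= 1))
  expect_length(intersect(aOnlySet(sim1$truth),
                          names(orthologMap(sim1$truth))), 0)
})

test_that("empty and invalid configurations are handled", {
  sim <- generateTranscriptome(simConfig(nGenes = 0))
  expect_length(sim$transcripts, 0)
  expect_length(orthologMap(sim$truth), 0)
  expect_error(simConfig(nGenes = -1), "nGenes")
  expect_error(simConfig(jcDistance = -0.1), "jcDistance")
  expect_error(simConfig(readLength = 300, insertMean = 200), "insertMean")
  expect_error(simConfig(nTissues = 4, tissueSpecificFraction = 0.3),
               "tissue-specific")
})

test_that("ortholog evolution matches the Jukes-Cantor closed form", {
  sim <- generateTranscriptome(simConfig(nGenes = 10,
                                         lengthRange = c(1000, 1000),
                                         seed = 11))
  # zero distance: species B identical to species A
  b0 <- evolveOrthologs(sim$transcripts, 0, seed = 1)
  expect_identical(as.character(b0), as.character(sim$transcripts))
  # d = 0.09 over 10 kb: identity near 1/4 + 3/4 exp(-0.12)
  b <- evolveOrthologs(sim$transcripts, 0.09, seed = 2)
  obs <- mean(mapply(function(x, y) {
    mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  }, as.character(sim$transcripts), as.character(b)))
  expected <- 0.25 + 0.75 * exp(-0.12)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(obs - expected), 4 * se)
  # saturation: identity approaches 1/4
  bInf <- evolveOrthologs(sim$transcripts, 30, seed = 3)
  obsInf <- mean(mapply(function(x, y) {
    mean(strsplit(x, "")[[1]] == strsplit(y, "")[[1]])
  }, as.character(sim$transcripts), as.character(bInf)))
  expect_lt(abs(obsInf - 0.25), 0.02)
  expect_error(evolveOrthologs(sim$transcripts, -1, seed = 1),
               "non-negative")
  # excluded (A-only) genes are skipped
  bx <- evolveOrthologs(sim$transcripts, 0.09, seed = 2,
                        exclude = names(sim$transcripts)[1:3])
  expect_length(bx, 7)
})

test_that("read simulation respects expression, coverage and determinism", {
  # a gene unexpressed in a tissue yields no reads from it
  cfg <- simConfig(nGenes = 20, lengthRange = c(500, 900),
                   tissueSpecificFraction = 0.25, seed = 4,
                   baseErrorRate = 0)
  sim <- generateTranscriptome(cfg)
  r <- simulateReads(sim$transcripts, sim$truth, "brain", cfg)
  srcGene <- sub(":.*", "", names(r$mate1))
  unexpressed <- rownames(expressionLevel(sim$truth))[
    expressionLevel(sim$truth)[, "brain"] == 0]
  expect_length(intersect(unique(srcGene), unexpressed), 0)

  # coverage arithmetic: 50x on a single 1 kb transcript -> about
  # 50 * 1000 / (2 * 76) = 329 pairs
  cfg1 <- simConfig(nGenes = 1, lengthRange = c(1000, 1000),
                    tissueSpecificFraction = 0, speciesAOnlyFraction = 0,
                    coverageTarget = 50, seed = 5)
  sim1 <- generateTranscriptome(cfg1)
  r1 <- simulateReads(sim1$transcripts, sim1$truth, "brain", cfg1)
  expect_equal(length(r1$mate1), 329, tolerance = 0.02)

  # byte-identical FASTQ across reruns with the same seed
  d1 <- tempfile(); d2 <- tempfile()
  writePairedFastq(simulateReads(sim$transcripts, sim$truth, "liver", cfg),
                   paste0(d1, "_1.fq"), paste0(d1, "_2.fq"))
  writePairedFastq(simulateReads(sim$transcripts, sim$truth, "liver", cfg),
                   paste0(d2, "_1.fq"), paste0(d2, "_2.fq"))
  expect_identical(readLines(paste0(d1, "_1.fq")),
                   readLines(paste0(d2, "_1.fq")))
  expect_identical(readLines(paste0(d1, "_2.fq")),
                   readLines(paste0(d2, "_2.fq")))

  # mate 1 comes from the sense strand (strand-specific contract)
  tx <- as.character(sim$transcripts[[srcGene[1]]])
  expect_true(grepl(as.character(r$mate1[[1]]), tx, fixed = TRUE))
  rc2 <- as.character(
    Biostrings::reverseComplement(r$mate2[[1]]))
  expect_true(grepl(rc2, tx, fixed = TRUE))
})

test_that("per-gene pair counts follow multinomial expression x length weights", {
  cfg <- simConfig(nGenes = 10, lengthRange = c(800, 1500),
                   tissueSpecificFraction = 0, speciesAOnlyFraction = 0,
                   coverageTarget = 150, seed = 6, baseErrorRate = 0)
  sim <- generateTranscriptome(cfg)
  r <- simulateReads(sim$transcripts, sim$truth, "brain", cfg)
  expect_gte(length(r$mate1), 1e4)
  obs <- table(factor(sub(":.*", "", names(r$mate1)),
                      levels = names(sim$transcripts)))
  w <- expressionLevel(sim$truth)[, "brain"] *
    Biostrings::width(sim$transcripts)
  expe <- sum(obs) * w / sum(w)
  chi2 <- sum((as.numeric(obs) - expe)^2 / expe)
  p <- pchisq(chi2, df = length(w) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("transcripts shorter than the read length are skipped with a warning", {
  cfg <- simConfig(nGenes = 2, lengthRange = c(500, 500), seed = 7,
                   tissueSpecificFraction = 0, speciesAOnlyFraction = 0)
  sim <- generateTranscriptome(cfg)
  short <- Biostrings::DNAStringSet(
    setNames(c(as.character(sim$transcripts[[1]]), strrep("ACGT", 10)),
             names(sim$transcripts)))
  expect_warning(r <- simulateReads(short, sim$truth, "brain", cfg),
                 "shorter than the read length")
  expect_false(names(short)[2] %in% sub(":.*", "", names(r$mate1)))
})
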