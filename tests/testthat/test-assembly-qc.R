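mkTx <- function(lengths) {
  Biostrings::DNAStringSet(setNames(
    vapply(lengths, function(L) randomSeq(L), character(1)),
    sprintf("t%02d", seq_along(lengths))))
}

test_that("N50 follows the cumulative-half definition and matches the oracle", {
  expect_equal(computeMetrics(mkTx(c(5, 4, 3, 2, 1)))$n50, 4)
  expect_equal(computeMetrics(mkTx(17))$n50, 17)
  expect_equal(computeMetrics(mkTx(c(2, 2, 2)))$n50, 2)
  expect_equal(computeMetrics(mkTx(integer(0)))$n50, 0)
  set.seed(3)
  for (i in 1:50) {
    lens <- sample(50:3000, sample(1:40, 1), replace = TRUE)
    expect_equal(computeMetrics(mkTx(lens))$n50, oracleN50(lens))
  }
})

test_that("coverage filtering removes strictly-below-threshold transcripts and is idempotent", {
  tx <- mkTx(c(100, 100, 100))
  cov <- list(t01 = rep(1L, 100),              # exactly 1.0: retained
              t02 = c(rep(1L, 50), rep(0L, 50)),  # 0.5: removed
              t03 = rep(0L, 100))              # unmapped: removed
  cc <- txCounts(setNames(c(50L, 25L, 0L), names(tx)),
                 lengths = setNames(c(100L, 100L, 100L), names(tx)),
                 coverage = cov)
  flt <- coverageFilter(tx, cc)
  expect_identical(names(flt$retained), "t01")
  expect_setequal(flt$removed, c("t02", "t03"))
  # idempotent on the retained set
  flt2 <- coverageFilter(flt$retained, cc)
  expect_identical(names(flt2$retained), "t01")
  expect_length(flt2$removed, 0)
  # missing coverage entry names the transcript
  extra <- mkTx(c(100, 100))
  names(extra) <- c("t01", "t99")
  expect_error(coverageFilter(extra, cc), "t99")
})

test_that("assembly metrics report reads used and bounds are enforced", {
  set.seed(4)
  tx <- mkTx(c(400, 600))
  idx <- buildIndex(tx, 31)
  s <- as.character(tx[[1]])
  m1 <- substr(s, 1, 76)
  m2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(s, 101, 176))))
  cc <- countAndCoverage(c(m1, randomSeq(76)),
                         c(m2, randomSeq(76)), idx)
  m <- computeMetrics(tx, cc, totalInputReads = 2)
  expect_equal(m$pct_reads_used, 50)
  expect_equal(m$contig_count, 2)
  expect_equal(m$total_bp, 1000)
  expect_error(computeMetrics(tx, cc, totalInputReads = 0), "smaller")
})

test_that("core gene recovery honors the e-value and alignment-fraction rules", {
  set.seed(5)
  # assembly peptides: translations of three planted ORFs + noise
  orfs <- vapply(c(120, 150, 180), function(n) codingOrf(n), character(1))
  peps <- vapply(orfs, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(s, 1, nchar(s) - 3))))
  }, character(1), USE.NAMES = FALSE)
  peptides <- Biostrings::AAStringSet(
    setNames(peps, paste0("p", 1:3)))
  core <- Biostrings::AAStringSet(setNames(peps, paste0("ceg", 1:3)))
  rec <- coreGeneRecovery(peptides, core)
  expect_equal(rec$fraction, 1.0)
  expect_true(all(rec$table$recovered))
  expect_equal(rec$meanIdentity, 1.0)

  # a core protein with no homolog in the assembly is not recovered
  alien <- Biostrings::AAStringSet(c(
    ceg1 = peps[1],
    orphan = paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                          120, replace = TRUE), collapse = "")))
  rec2 <- coreGeneRecovery(peptides, alien)
  expect_equal(rec2$fraction, 0.5)
  expect_false(rec2$table$recovered[rec2$table$core_id == "orphan"])

  # an alignment covering only ~69% of the core gene does not count
  partial <- Biostrings::AAStringSet(setNames(
    substr(peps[3], 1, round(0.69 * nchar(peps[3]))), "p3part"))
  rec3 <- coreGeneRecovery(partial,
                           Biostrings::AAStringSet(
                             setNames(peps[3], "ceg3")))
  expect_false(rec3$table$recovered[1])
  expect_lte(rec3$table$aln_fraction[1], 0.70)
  expect_error(coreGeneRecovery(peptides, Biostrings::AAStringSet()),
               "non-empty")
})

test_that("recovery is monotone in the cutoff and alignment-fraction knobs", {
  set.seed(6)
  orfs <- vapply(rep(100, 3), function(n) codingOrf(n), character(1))
  peps <- vapply(orfs, function(s) {
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(s, 1, nchar(s) - 3))))
  }, character(1), USE.NAMES = FALSE)
  # degrade one peptide so it aligns over only part of its core gene
  peptides <- Biostrings::AAStringSet(setNames(
    c(peps[1], substr(peps[2], 1, 60), peps[3]), paste0("p", 1:3)))
  core <- Biostrings::AAStringSet(setNames(peps, paste0("ceg", 1:3)))
  strict <- coreGeneRecovery(peptides, core, minAlnFraction = 0.70)
  lax <- coreGeneRecovery(peptides, core, minAlnFraction = 0.30)
  expect_gte(lax$fraction, strict$fraction)
  tight <- coreGeneRecovery(peptides, core, evalueCutoff = 1e-30)
  loose <- coreGeneRecovery(peptides, core, evalueCutoff = 1e-3)
  expect_gte(loose$fraction, tight$fraction)
})
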